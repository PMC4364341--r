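#' Construct a multi-echo spin-echo volume
#'
#' Container for a 4D magnitude image (x, y, z, echo) together with its echo
#' times, as produced by a CPMG multi-spin-echo T2 acquisition. Per-voxel
#' signal is modelled downstream as S(TE) = S0 * exp(-TE / T2).
#'
#' @param data 4D numeric array (x, y, z, echo), signal units.
#' @param echo_times numeric vector of echo times in ms, strictly increasing,
#'   length equal to the 4th dimension of `data`; at least 2 echoes.
#' @param voxel_size mm per axis, length 3.
#' @return an object of class `multi_echo_volume`.
#' @export
multi_echo_volume <- function(data, echo_times, voxel_size = c(1, 1, 1)) {
  if (length(dim(data)) != 4L)
    abort("multi_echo_volume: 'data' must be 4D (x, y, z, echo)")
  ne <- dim(data)[4]
  if (length(echo_times) != ne)
    abort("multi_echo_volume: length(echo_times) must equal dim(data)[4]")
  if (ne < 2L) abort("multi_echo_volume: need at least 2 echoes")
  if (any(echo_times <= 0) || any(diff(echo_times) <= 0))
    abort("multi_echo_volume: echo_times must be positive and strictly increasing")
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  structure(list(data = data, echo_times = as.numeric(echo_times),
                 voxel_size = as.numeric(voxel_size)),
            class = "multi_echo_volume")
}

#' @export
print.multi_echo_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<multi_echo_volume> %dx%dx%d voxels, %d echoes (TE %.4g..%.4g ms)\n",
              d[1], d[2], d[3], d[4], min(x$echo_times), max(x$echo_times)))
  invisible(x)
}

#' Fit a per-voxel T2 map from a multi-echo volume
#'
#' Fits the mono-exponential decay S(TE) = S0 * exp(-TE / T2) at every voxel.
#' `log_linear` performs ordinary least squares of log S against TE
#' (T2 = -1/slope, S0 = exp(intercept)); `nonlinear` refines that start with
#' Gauss-Newton least squares on the exponential model itself.
#'
#' Voxels are masked invalid when any echo signal is not above
#' `max(min_signal, 0)` (the log transform needs positive signal) or when the
#' fitted slope is nonnegative (non-decaying signal, e.g. constant or pure
#' noise). Negative signals additionally raise a counted warning.
#' `r2_of_fit` is the coefficient of determination in the space the model was
#' fitted in (log-signal for `log_linear`, signal for `nonlinear`).
#'
#' @param vol a [multi_echo_volume()].
#' @param method `"log_linear"` (default) or `"nonlinear"`.
#' @param min_signal voxels with any echo at or below this level are masked
#'   invalid. Default 0: only nonpositive signals are excluded.
#' @param drop_first_echo drop echo 1 before fitting; CPMG first echoes are
#'   often biased by imperfect refocusing, so this is offered as an option.
#' @return an object of class `t2_map`: list with 3D arrays `t2` (ms), `s0`,
#'   `r2_of_fit`, logical `valid_mask`, plus `voxel_size` and `method`.
#' @export
fit_t2 <- function(vol, method = c("log_linear", "nonlinear"),
                   min_signal = 0, drop_first_echo = FALSE) {
  stopifnot(inherits(vol, "multi_echo_volume"))
  method <- match.arg(method)
  if (min_signal < 0) abort("fit_t2: min_signal must be >= 0")

  te <- vol$echo_times
  d <- dim(vol$data)
  sig <- matrix(vol$data, nrow = prod(d[1:3]), ncol = d[4])
  if (drop_first_echo) {
    if (length(te) < 3L) abort("fit_t2: cannot drop first echo with only 2 echoes")
    te <- te[-1]
    sig <- sig[, -1, drop = FALSE]
  }

  n_neg <- sum(rowSums(sig < 0) > 0)
  if (n_neg > 0)
    warning(sprintf("fit_t2: %d voxel(s) with negative signal masked invalid", n_neg))
  thr <- max(min_signal, 0)
  valid <- rowSums(sig <= thr) == 0L

  nv <- nrow(sig)
  t2 <- s0 <- r2 <- rep(NA_real_, nv)

  if (any(valid)) {
    y <- log(sig[valid, , drop = FALSE])
    nE <- length(te)
    te_c <- te - mean(te)
    sxx <- sum(te_c^2)
    ybar <- rowMeans(y)
    num <- as.vector(y %*% te_c)
    slope <- num / sxx
    inter <- ybar - slope * mean(te)
    # a decaying fit needs a clearly negative slope; |num| at rounding-error
    # scale (e.g. constant signal) counts as zero slope -> invalid
    num_scale <- as.vector(abs(y) %*% abs(te_c))
    fit_ok <- num < -1e-12 * num_scale
    sse <- rowSums((y - outer(slope, te) - inter)^2)
    sst <- rowSums((y - ybar)^2)
    r2v <- ifelse(sst > 0, 1 - sse / sst, NA_real_)

    t2v <- -1 / slope
    s0v <- exp(inter)

    if (method == "nonlinear") {
      # Gauss-Newton on (S0, R = 1/T2), vectorized across voxels
      S <- sig[valid, , drop = FALSE]
      a <- s0v
      r <- ifelse(fit_ok, 1 / t2v, 1 / max(te))
      for (it in seq_len(60L)) {
        E <- exp(-outer(r, te))              # nvox x nE
        res <- a * E - S
        # Jacobian columns: dS/da = E ; dS/dr = -a * TE * E
        TEm <- matrix(te, nrow = nrow(E), ncol = length(te), byrow = TRUE)
        dr <- -a * TEm * E
        J11 <- rowSums(E * E)
        J12 <- rowSums(E * dr)
        J22 <- rowSums(dr * dr)
        g1 <- rowSums(E * res)
        g2 <- rowSums(dr * res)
        det <- J11 * J22 - J12^2
        det[det == 0 | !is.finite(det)] <- NA_real_
        da <- (J22 * g1 - J12 * g2) / det
        dr_step <- (J11 * g2 - J12 * g1) / det
        da[is.na(da)] <- 0; dr_step[is.na(dr_step)] <- 0
        a <- a - da
        r <- r - dr_step
        r <- pmax(r, 1e-8)
        a <- pmax(a, 1e-12)
        if (max(abs(da) / pmax(a, 1), abs(dr_step) / pmax(r, 1e-3)) < 1e-12) break
      }
      E <- exp(-outer(r, te))
      pred <- a * E
      sseN <- rowSums((pred - S)^2)
      sstN <- rowSums((S - rowMeans(S))^2)
      t2v <- 1 / r
      s0v <- a
      r2v <- ifelse(sstN > 0, 1 - sseN / sstN, NA_real_)
    }

    ok <- fit_ok
    t2[valid] <- ifelse(ok, t2v, NA_real_)
    s0[valid] <- ifelse(ok, s0v, NA_real_)
    r2[valid] <- ifelse(ok, r2v, NA_real_)
    valid[valid] <- ok
  }

  if (!any(valid)) abort("fit_t2: all voxels invalid; nothing to fit")

  dim3 <- d[1:3]
  structure(list(t2 = array(t2, dim3), s0 = array(s0, dim3),
                 r2_of_fit = array(r2, dim3),
                 valid_mask = array(valid, dim3),
                 voxel_size = vol$voxel_size, method = method),
            class = "t2_map")
}

#' @export
print.t2_map <- function(x, ...) {
  cat(sprintf("<t2_map> %s voxels, %.1f%% valid, median T2 %.2f ms (%s fit)\n",
              paste(dim(x$t2), collapse = "x"),
              100 * mean(x$valid_mask),
              stats::median(x$t2[x$valid_mask]), x$method))
  invisible(x)
}

#' Write a T2 map as NIfTI volumes
#'
#' Writes `<prefix>_t2.nii.gz`, `<prefix>_s0.nii.gz`, `<prefix>_r2.nii.gz`
#' (invalid voxels as 0).
#'
#' @param t2map a `t2_map`.
#' @param prefix output path prefix.
#' @return the three paths, invisibly.
#' @export
write_t2_map <- function(t2map, prefix) {
  stopifnot(inherits(t2map, "t2_map"))
  zero <- function(a) { a[!t2map$valid_mask] <- 0; a }
  paths <- paste0(prefix, c("_t2.nii.gz", "_s0.nii.gz", "_r2.nii.gz"))
  write_nifti(zero(t2map$t2), paths[1], t2map$voxel_size)
  write_nifti(zero(t2map$s0), paths[2], t2map$voxel_size)
  write_nifti(zero(t2map$r2_of_fit), paths[3], t2map$voxel_size)
  invisible(paths)
}
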
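# 3D gray-level run-length texture biomarkers.
#
# A gray-level "run" is a maximal set of consecutive voxels of equal
# quantized level along one direction, confined to an ROI mask. The paperless
# field names are short run emphasis (SRE, here Small Lesion Index, SLI) and
# run-length non-uniformity (RLN, here Heterogeneity Index, HI); both are
# averaged over the 13 unique 3D directions unless told otherwise.

#' Construct a label map of segmented muscles
#'
#' @param labels 3D integer array; 0 is background, each positive label is a
#'   muscle.
#' @param names named character vector or list mapping label id (as character)
#'   to muscle name; every label present must be named.
#' @param voxel_size mm per axis.
#' @return object of class `label_map`.
#' @export
label_map <- function(labels, names, voxel_size = c(1, 1, 1)) {
  if (length(dim(labels)) != 3L) abort("label_map: 'labels' must be 3D")
  if (any(labels < 0)) abort("label_map: labels must be >= 0")
  ids <- sort(unique(as.vector(labels)))
  ids <- ids[ids > 0]
  nm <- unlist(names)
  missing <- setdiff(as.character(ids), base::names(nm))
  if (length(missing))
    abort("label_map: unnamed label(s): ", paste(missing, collapse = ", "))
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, names = nm,
                 voxel_size = as.numeric(voxel_size)),
            class = "label_map")
}

#' The 13 unique directions of the 3D 26-neighborhood
#'
#' Offsets modulo sign: runs along d and -d are the same runs, so 13
#' directions cover all 26 neighbors.
#'
#' @return a 13 x 3 integer matrix of (dx, dy, dz) offsets.
#' @export
rlm_directions_13 <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- d[rowSums(abs(d)) > 0, ]
  # keep one of each +/- pair: first nonzero component positive
  keep <- apply(d, 1, function(v) v[match(TRUE, v != 0)] > 0)
  m <- unname(d[keep, , drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

#' Quantize an image to G gray levels over an ROI
#'
#' Equal-width binning realizes the "similarity range" of run-length texture
#' analysis: voxels falling in the same bin are treated as equal-intensity.
#'
#' @param x 3D numeric array, or a `t2_map` (its `t2` volume is used and the
#'   mask is intersected with its `valid_mask`).
#' @param mask 3D logical array, the ROI.
#' @param G number of gray levels, >= 2.
#' @param binning `"roi_minmax"` maps the ROI min..max to G equal bins (the
#'   max maps to level G); `"fixed_range"` uses `range` and clamps outside
#'   values to levels 1/G.
#' @param range numeric length-2 (lo, hi), required for `"fixed_range"`.
#' @return integer array of levels 1..G inside the mask, 0 outside.
#' @export
quantize <- function(x, mask, G = 16L, binning = c("roi_minmax", "fixed_range"),
                     range = NULL) {
  binning <- match.arg(binning)
  if (inherits(x, "t2_map")) {
    mask <- mask & x$valid_mask
    x <- x$t2
  }
  if (!is_count(G) || G < 2) abort("quantize: G must be an integer >= 2")
  if (!any(mask)) abort("quantize: empty mask")
  v <- x[mask]
  if (anyNA(v)) abort("quantize: NA values inside the mask")
  if (binning == "roi_minmax") {
    lo <- min(v); hi <- max(v)
  } else {
    if (is.null(range) || length(range) != 2L || range[2] <= range[1])
      abort("quantize: fixed_range binning needs range = c(lo, hi), hi > lo")
    lo <- range[1]; hi <- range[2]
  }
  q <- array(0L, dim(x))
  if (hi == lo) {
    warning("quantize: constant ROI; all voxels assigned level 1")
    q[mask] <- 1L
    return(q)
  }
  lev <- floor((v - lo) / (hi - lo) * G) + 1L
  lev <- pmin.int(pmax.int(lev, 1L), G)
  q[mask] <- as.integer(lev)
  q
}

#' Gray-level run-length matrix along one direction
#'
#' Counts maximal runs of consecutive equal levels along `direction`,
#' restricted to `mask`: runs break at mask and volume boundaries and never
#' bridge across background.
#'
#' @param q integer 3D array of quantized levels (>= 1 inside the ROI).
#' @param mask logical 3D array; defaults to `q > 0`.
#' @param direction integer offset triple with components in -1, 0, 1, not
#'   all zero.
#' @return object of class `run_length_matrix`: `counts` (G x Jmax matrix,
#'   rows = levels, cols = run lengths), `direction`, `n_runs`.
#' @export
run_length_matrix <- function(q, mask = q > 0, direction) {
  if (length(direction) != 3L || !all(direction %in% -1:1) ||
      all(direction == 0))
    abort("run_length_matrix: direction must be a nonzero triple in {-1,0,1}")
  if (!any(mask)) abort("run_length_matrix: empty mask")
  d <- dim(q)
  G <- max(q[mask])
  if (G < 1) abort("run_length_matrix: mask voxels must have level >= 1")

  # Parameterize each lattice line p0 + k*direction: k advances 1 per step
  # along the first nonzero axis; (line id, k) sorts voxels into line order.
  idx <- arrayInd(seq_len(prod(d)), d)
  u <- match(TRUE, direction != 0)
  k <- idx[, u] * sign(direction[u])
  base <- idx - outer(k, direction)       # constant along a line
  D <- sum(d)                             # |base_i| <= 2*D, encode base-3D+1
  M <- 4 * D + 2
  line_id <- (base[, 1] + D) + (base[, 2] + D) * M + (base[, 3] + D) * M^2
  ord <- order(line_id, k)

  lv <- as.vector(q)[ord]
  mk <- as.vector(mask)[ord]
  li <- line_id[ord]
  # run breaks: new line, mask off, or level change
  new_line <- c(TRUE, li[-1] != li[-length(li)])
  brk <- new_line | c(TRUE, lv[-1] != lv[-length(lv)]) |
    !mk | c(TRUE, !mk[-length(mk)])
  # segment voxels that are in-mask into runs
  seg <- cumsum(brk)
  seg_in <- seg[mk]
  lv_in <- lv[mk]
  if (!length(seg_in)) abort("run_length_matrix: empty mask")
  runs <- rle(seg_in)
  run_len <- runs$lengths
  run_lev <- lv_in[cumsum(runs$lengths)]

  jmax <- max(run_len)
  counts <- matrix(0L, nrow = G, ncol = jmax,
                   dimnames = list(level = seq_len(G), length = seq_len(jmax)))
  tab <- table(factor(run_lev, levels = seq_len(G)),
               factor(run_len, levels = seq_len(jmax)))
  counts[] <- as.integer(tab)
  structure(list(counts = counts, direction = as.integer(direction),
                 n_runs = sum(counts)),
            class = "run_length_matrix")
}

#' Compute run-length matrices over a direction set
#'
#' @inheritParams run_length_matrix
#' @param directions integer matrix of offsets, one per row; default the 13
#'   unique 3D directions.
#' @return list of `run_length_matrix`.
#' @export
run_length_matrices <- function(q, mask = q > 0,
                                directions = rlm_directions_13()) {
  lapply(seq_len(nrow(directions)), function(i)
    run_length_matrix(q, mask, directions[i, ]))
}

as_rlm_list <- function(rlms) {
  if (inherits(rlms, "run_length_matrix")) rlms <- list(rlms)
  if (!length(rlms) || !all(vapply(rlms, inherits, logical(1), "run_length_matrix")))
    abort("expected one or more run_length_matrix objects")
  if (any(vapply(rlms, function(m) m$n_runs, numeric(1)) < 1))
    abort("run-length matrix with zero runs")
  rlms
}

#' Small Lesion Index (short run emphasis)
#'
#' Per matrix SRE = (1/N_r) * sum_ij p(i, j) / j^2, then the unweighted mean
#' over the direction set. Lies in (0, 1]; equals 1 iff every run has
#' length 1, so values near 1 indicate fragmented, patchy texture.
#'
#' @param rlms a `run_length_matrix` or a list of them (one per direction).
#' @return scalar SLI.
#' @export
sli <- function(rlms) {
  rlms <- as_rlm_list(rlms)
  mean(vapply(rlms, function(m) {
    j <- seq_len(ncol(m$counts))
    sum(sweep(m$counts, 2, j^2, `/`)) / m$n_runs
  }, numeric(1)))
}

#' Heterogeneity Index (run-length non-uniformity)
#'
#' Per matrix RLN = (1/N_r) * sum_j (sum_i p(i, j))^2, then the unweighted
#' mean over directions. Lies in [1, N_r]; large when run counts concentrate
#' at few lengths.
#'
#' @inheritParams sli
#' @return scalar HI.
#' @export
hi <- function(rlms) {
  rlms <- as_rlm_list(rlms)
  mean(vapply(rlms, function(m) {
    sum(colSums(m$counts)^2) / m$n_runs
  }, numeric(1)))
}

#' First-order histogram entropy over an ROI
#'
#' Quantizes the ROI to G levels and returns
#' H = -sum_k f_k log2 f_k over occupied bins, in bits.
#'
#' @inheritParams quantize
#' @return entropy in bits.
#' @export
histogram_entropy <- function(x, mask, G = 16L,
                              binning = c("roi_minmax", "fixed_range"),
                              range = NULL) {
  binning <- match.arg(binning)
  q <- suppressWarnings(quantize(x, mask, G, binning, range))
  f <- tabulate(q[q > 0L], nbins = G)
  f <- f[f > 0] / sum(f)
  -sum(f * log2(f))
}

# central n_slices slab along `axis`, centered on the ROI centroid
slab_mask <- function(mask, n_slices, axis = 3L) {
  idx <- which(mask, arr.ind = TRUE)
  ctr <- round(mean(idx[, axis]))
  lo <- ctr - (n_slices - 1L) %/% 2L
  hi <- lo + n_slices - 1L
  lo <- max(1L, lo); hi <- min(dim(mask)[axis], hi)
  keep <- array(FALSE, dim(mask))
  sl <- lapply(dim(mask), seq_len)
  sl[[axis]] <- lo:hi
  keep[sl[[1]], sl[[2]], sl[[3]]] <- TRUE
  mask & keep
}

#' Per-muscle volume, T2 and texture biomarkers
#'
#' For every labelled muscle: volume (voxel count and mm^3), mean T2 over the
#' valid mask, and entropy / SLI / HI computed on a configurable slab (by
#' default the central `n_slices` slices along the through-plane axis,
#' centered on the muscle's centroid — an analysis-plane stand-in for a
#' mid-femur landmark).
#'
#' @param t2map a `t2_map`.
#' @param labelmap a [label_map()].
#' @param G gray levels for quantization (held fixed across groups).
#' @param directions direction set for the run-length features.
#' @param n_slices slab thickness in slices; `Inf` or `NA` = whole muscle.
#' @param slab_axis through-plane axis (default 3 = z).
#' @return a data.frame of class `muscle_feature_table` with one row per
#'   label: `label`, `muscle`, `n_voxels`, `volume_mm3`, `mean_t2`,
#'   `entropy`, `sli`, `hi`, `missing` (TRUE when the label has no voxels —
#'   flagged, never silently dropped).
#' @export
muscle_features <- function(t2map, labelmap, G = 16L,
                            directions = rlm_directions_13(),
                            n_slices = 5L, slab_axis = 3L) {
  stopifnot(inherits(t2map, "t2_map"), inherits(labelmap, "label_map"))
  vox_mm3 <- prod(labelmap$voxel_size)
  ids <- as.integer(names(labelmap$names))
  whole <- is.na(n_slices) || !is.finite(n_slices)

  rows <- lapply(ids, function(id) {
    m <- labelmap$labels == id & t2map$valid_mask
    nm <- labelmap$names[[as.character(id)]]
    if (!any(m)) {
      return(data.frame(label = id, muscle = nm, n_voxels = 0L,
                        volume_mm3 = 0, mean_t2 = NA_real_,
                        entropy = NA_real_, sli = NA_real_, hi = NA_real_,
                        missing = TRUE))
    }
    slab <- if (whole) m else slab_mask(m, as.integer(n_slices), slab_axis)
    q <- suppressWarnings(quantize(t2map$t2, slab, G))
    rl <- run_length_matrices(q, slab, directions)
    data.frame(label = id, muscle = nm,
               n_voxels = sum(m), volume_mm3 = sum(m) * vox_mm3,
               mean_t2 = mean(t2map$t2[m]),
               entropy = histogram_entropy(t2map$t2, slab, G),
               sli = sli(rl), hi = hi(rl), missing = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("muscle_feature_table", "data.frame")
  out
}

#' Proportional-volume-weighted composite of a per-muscle feature
#'
#' Weighted average sum_m w_m x_m with w_m = volume_m / sum(volume); rows
#' flagged missing (or with NA feature values) are excluded and the weights
#' renormalized over the remaining muscles.
#'
#' @param table a `muscle_feature_table` (or data.frame with `volume_mm3`).
#' @param feature column name, e.g. `"mean_t2"`, `"sli"`, `"hi"`, `"entropy"`.
#' @return the weighted composite, a scalar.
#' @export
weighted_composite <- function(table, feature) {
  if (!feature %in% names(table))
    abort("weighted_composite: unknown feature '", feature, "'")
  keep <- !is.na(table[[feature]]) & table$volume_mm3 > 0
  if (!is.null(table$missing)) keep <- keep & !table$missing
  if (!any(keep)) abort("weighted_composite: no muscle with positive volume")
  w <- table$volume_mm3[keep]
  sum(w / sum(w) * table[[feature]][keep])
}
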
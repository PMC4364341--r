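# Group-comparison layer: Welch's unequal-variance t-test (from summaries or
# raw samples), Benjamini-Hochberg FDR across an endpoint family, and the
# significance/trend flagging convention (P < 0.05 significant, P < 0.2
# trend).

#' Welch's two-sample t-test from summary statistics
#'
#' t = (mean1 - mean2) / sqrt(sd1^2/n1 + sd2^2/n2), with Welch-Satterthwaite
#' degrees of freedom and a two-sided p from the t distribution. Appropriate
#' when group sizes and variances are unequal. With `var_equal = TRUE` the
#' pooled-variance Student t-test is computed instead (used for
#' histopathology comparisons).
#'
#' @param mean1,sd1,n1 summary statistics of group 1 (n1 >= 2, sd1 >= 0).
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @param var_equal pooled-variance Student t instead of Welch.
#' @return object of class `stat_result`: list with `mean1`, `sd1`, `n1`,
#'   `mean2`, `sd2`, `n2`, `diff` (mean1 - mean2), `t`, `df`, `p`.
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2, var_equal = FALSE) {
  if (n1 < 2 || n2 < 2) abort("welch_t: both groups need n >= 2")
  if (sd1 < 0 || sd2 < 0) abort("welch_t: sds must be >= 0")
  if (sd1 == 0 && sd2 == 0)
    abort("welch_t: both sds are zero; test degenerate")
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tstat <- (mean1 - mean2) / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  structure(list(mean1 = mean1, sd1 = sd1, n1 = n1,
                 mean2 = mean2, sd2 = sd2, n2 = n2,
                 diff = mean1 - mean2, t = tstat, df = df, p = p,
                 var_equal = var_equal),
            class = "stat_result")
}

#' Welch's t-test from raw samples
#'
#' Computes the group summaries and delegates to [welch_t()], so the two
#' routes agree exactly.
#'
#' @param x,y numeric sample vectors (length >= 2 each).
#' @inheritParams welch_t
#' @return a `stat_result`; see [welch_t()].
#' @export
welch_t_samples <- function(x, y, var_equal = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  welch_t(mean(x), stats::sd(x), length(x),
          mean(y), stats::sd(y), length(y), var_equal = var_equal)
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s t-test: t = %.3f, df = %.2f, p = %.4g (diff = %.4g)\n",
              if (x$var_equal) "Student" else "Welch",
              x$t, x$df, x$p, x$diff))
  invisible(x)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Adjusted p_i = min over j >= i of (m * p_(j) / j), capped at 1, returned
#' in the input order. Implemented directly (and cross-checked against
#' `stats::p.adjust` in the test suite).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) abort("bh_fdr: empty p-value list")
  if (anyNA(p) || any(p < 0 | p > 1)) abort("bh_fdr: p-values must be in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  adj
}

#' Flag a p-value as significant, trend, or ns
#'
#' Significant when p < `alpha_sig` (default 0.05); a trend when
#' `alpha_sig` <= p < `alpha_trend` (default 0.2); otherwise `ns`.
#'
#' @param p p-value(s) in \[0, 1\].
#' @param alpha_sig significance threshold.
#' @param alpha_trend trend-reporting threshold.
#' @return character vector in `c("significant", "trend", "ns")`.
#' @export
flag_p <- function(p, alpha_sig = 0.05, alpha_trend = 0.2) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("flag_p: p must be in [0, 1]")
  ifelse(p < alpha_sig, "significant",
         ifelse(p < alpha_trend, "trend", "ns"))
}

#' Compare two groups across a family of endpoints
#'
#' Runs [welch_t_samples()] for each endpoint between two groups of a cohort
#' or feature table, optionally applies Benjamini-Hochberg FDR within the
#' endpoint family, and flags each (adjusted) p. Endpoints where either
#' group has n < 2 are skipped with a warning; flags use the adjusted p when
#' `adjust = TRUE`.
#'
#' @param data data.frame with a grouping column and numeric endpoint
#'   columns.
#' @param endpoints character vector of endpoint column names (the FDR
#'   family).
#' @param groups length-2 character vector: reference and comparison group
#'   labels.
#' @param group_col name of the grouping column (default `"group"`).
#' @param adjust apply BH FDR within the family.
#' @param var_equal pooled-variance Student t (histopathology convention).
#' @param alpha_sig,alpha_trend flagging thresholds.
#' @return data.frame with one row per endpoint: group means/sds/n, `diff`,
#'   `t`, `df`, `p`, `p_adj`, `flag`.
#' @export
compare_groups <- function(data, endpoints, groups, group_col = "group",
                           adjust = TRUE, var_equal = FALSE,
                           alpha_sig = 0.05, alpha_trend = 0.2) {
  stopifnot(group_col %in% names(data), length(groups) == 2L)
  g <- data[[group_col]]
  present <- groups %in% g
  if (!all(present))
    abort("compare_groups: group(s) absent: ",
          paste(groups[!present], collapse = ", "))
  rows <- lapply(endpoints, function(ep) {
    x <- data[[ep]][g == groups[1]]
    y <- data[[ep]][g == groups[2]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) {
      warning("compare_groups: endpoint '", ep, "' skipped (group with n < 2)")
      return(NULL)
    }
    r <- welch_t_samples(x, y, var_equal = var_equal)
    data.frame(endpoint = ep, mean1 = r$mean1, sd1 = r$sd1, n1 = r$n1,
               mean2 = r$mean2, sd2 = r$sd2, n2 = r$n2,
               diff = r$diff, t = r$t, df = r$df, p = r$p)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) abort("compare_groups: no testable endpoint")
  out <- do.call(rbind, rows)
  out$p_adj <- if (adjust) bh_fdr(out$p) else out$p
  out$flag <- flag_p(out$p_adj, alpha_sig, alpha_trend)
  rownames(out) <- NULL
  out
}
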
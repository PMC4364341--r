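# Histopathology percent-rescue scoring: per-muscle, per-marker rescue of a
# treated group relative to untreated, marker averages across muscles, and
# the final composite score of improvement.

HISTO_MUSCLES <- c("cranial_sartorius", "lateral_gastrocnemius",
                   "vastus_lateralis", "diaphragm")
HISTO_MARKERS <- c("inflammation", "necrotic_foci", "igg_fibers",
                   "regeneration")

#' Percent rescue of a histopathology marker
#'
#' R = 100 * (untreated - treated) / untreated, for markers where lower is
#' better (macrophage counts, necrotic foci, IgG+ fibers, centrally located
#' nuclei). R <= 100 whenever treated >= 0; R < 0 means worsening.
#'
#' @param untreated marker level in the untreated group; must be > 0.
#' @param treated marker level in the treated group; >= 0.
#' @return rescue in percent (vectorized).
#' @export
percent_rescue <- function(untreated, treated) {
  if (any(untreated <= 0))
    abort("percent_rescue: untreated level must be > 0 (rescue undefined)")
  if (any(treated < 0)) abort("percent_rescue: treated level must be >= 0")
  100 * (untreated - treated) / untreated
}

#' Average a marker's rescue values across muscles
#'
#' Arithmetic mean of the retained per-muscle rescue values, reported to one
#' decimal with ties rounded half away from zero. With
#' `exclusion = "drop_nonsignificant"`, muscles whose underlying group
#' comparison was not significant are dropped before averaging.
#'
#' @param rescues numeric vector of per-muscle rescue percentages.
#' @param significant logical vector parallel to `rescues`; required when
#'   dropping non-significant cells.
#' @param exclusion `"none"` or `"drop_nonsignificant"`.
#' @return the marker average, percent, one decimal.
#' @export
marker_average <- function(rescues, significant = NULL,
                           exclusion = c("none", "drop_nonsignificant")) {
  exclusion <- match.arg(exclusion)
  if (!length(rescues)) abort("marker_average: no rescue values")
  keep <- rep(TRUE, length(rescues))
  if (exclusion == "drop_nonsignificant") {
    if (is.null(significant) || length(significant) != length(rescues))
      abort("marker_average: 'significant' flags required to drop cells")
    keep <- significant
  }
  if (!any(keep)) abort("marker_average: all cells excluded")
  round_half_away(mean(rescues[keep]), 1L)
}

#' Final composite score of histological improvement
#'
#' Arithmetic mean of the marker averages (inflammation, necrotic foci,
#' IgG+ fibers, regeneration), one decimal, half away from zero.
#'
#' @param marker_averages numeric vector of marker averages, percent.
#' @return composite score, percent.
#' @export
composite_score <- function(marker_averages) {
  if (!length(marker_averages)) abort("composite_score: no marker averages")
  round_half_away(mean(marker_averages), 1L)
}

#' Full rescue table from untreated/treated marker matrices
#'
#' Computes per-muscle, per-marker percent rescue, per-marker averages, and
#' the final composite. The averaging convention is per-marker: by default
#' the necrotic-foci average drops non-significant muscles while all other
#' markers retain every muscle — the convention reverse-engineered from the
#' published composite table (see the methods vignette); both behaviors are
#' explicit configuration.
#'
#' @param untreated,treated numeric matrices, muscles x markers (same
#'   dimnames), marker levels per group.
#' @param significant logical matrix parallel to the rescue table; default
#'   all TRUE.
#' @param exclusion named character vector mapping marker -> `"none"` or
#'   `"drop_nonsignificant"`; unnamed scalar applies to all markers.
#' @return list of class `rescue_table`: `rescue` (matrix, percent),
#'   `marker_averages` (named, one decimal), `composite` (scalar),
#'   `significant`.
#' @export
rescue_table <- function(untreated, treated, significant = NULL,
                         exclusion = c(necrotic_foci = "drop_nonsignificant")) {
  stopifnot(is.matrix(untreated), is.matrix(treated),
            all(dim(untreated) == dim(treated)))
  markers <- colnames(untreated)
  if (is.null(markers)) markers <- paste0("marker", seq_len(ncol(untreated)))
  if (is.null(significant))
    significant <- matrix(TRUE, nrow(untreated), ncol(untreated),
                          dimnames = dimnames(untreated))
  excl_for <- function(mk) {
    if (length(exclusion) == 1L && is.null(names(exclusion))) return(exclusion)
    if (mk %in% names(exclusion)) exclusion[[mk]] else "none"
  }
  rescue <- percent_rescue(untreated, treated)
  avgs <- vapply(seq_along(markers), function(i)
    marker_average(rescue[, i], significant[, i], excl_for(markers[i])),
    numeric(1))
  names(avgs) <- markers
  structure(list(rescue = rescue, marker_averages = avgs,
                 composite = composite_score(avgs), significant = significant),
            class = "rescue_table")
}

#' @export
print.rescue_table <- function(x, ...) {
  cat("<rescue_table>\n")
  print(round(x$rescue, 1))
  cat("marker averages:",
      paste(sprintf("%s=%.1f", names(x$marker_averages), x$marker_averages),
            collapse = ", "), "\n")
  cat(sprintf("final composite score of improvement: %.1f%%\n", x$composite))
  invisible(x)
}

#' Write a rescue table as CSV (+ JSON summary)
#'
#' @param x a `rescue_table`.
#' @param csv_path output CSV path (muscle rows, marker columns, average and
#'   composite appended); a `.json` summary is written next to it.
#' @return `csv_path`, invisibly.
#' @export
write_rescue_table <- function(x, csv_path) {
  stopifnot(inherits(x, "rescue_table"))
  df <- as.data.frame(round_half_away(x$rescue, 1L))
  df <- cbind(muscle = rownames(x$rescue), df)
  avg <- c(muscle = "average_rescue", as.list(x$marker_averages))
  df <- rbind(df, as.data.frame(avg))
  utils::write.csv(df, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(marker_averages = as.list(x$marker_averages),
         final_composite_score = x$composite),
    sub("\\.csv$", ".json", csv_path), auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
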
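# Reduction of raw functional measurements to trial endpoints: isometric
# tibiotarsal joint (TTJ) torque -> force via the paw moment arm, body-mass
# correction, eccentric contraction force deficit, and group percent change.

#' Convert joint torque to force via the paw moment arm
#'
#' The lever contact point (moment arm) is taken as 75% of the hock-to-digit
#' distance; force = torque / (0.75 * distance).
#'
#' @param torque isometric torque, N·m (vectorized).
#' @param hock_to_digit_distance distance from the point of the hock to the
#'   distal digit, m; must be > 0.
#' @return force in N.
#' @export
torque_to_force <- function(torque, hock_to_digit_distance) {
  if (any(hock_to_digit_distance <= 0))
    abort("torque_to_force: hock_to_digit_distance must be > 0")
  torque / (0.75 * hock_to_digit_distance)
}

#' Body-mass correction of a force or torque
#'
#' @param value absolute value, N or N·m (vectorized).
#' @param body_mass kg; must be > 0.
#' @return value per kg.
#' @export
mass_correct <- function(value, body_mass) {
  if (any(body_mass <= 0)) abort("mass_correct: body_mass must be > 0")
  value / body_mass
}

#' Eccentric contraction force deficit
#'
#' Fd = 100 * (Po\[before\] - Po\[after\]) / Po\[before\], where Po is the
#' maximal isometric tetanic force (or torque — Fd is scale invariant) and
#' "after" is the value following `through_stretch` lengthening contractions.
#' A negative deficit (post-stretch potentiation) is returned as-is, not
#' clamped, so data pathologies stay visible.
#'
#' @param po numeric vector of Po values indexed stretch 0..k; `po[1]` is the
#'   pre-stretch value.
#' @param through_stretch stretch number after which the deficit is taken
#'   (default: the last available).
#' @return Fd in percent.
#' @export
force_deficit <- function(po, through_stretch = length(po) - 1L) {
  if (length(po) < 2L) abort("force_deficit: need at least pre and one post value")
  if (any(po < 0)) abort("force_deficit: Po values must be >= 0")
  if (po[1] == 0) abort("force_deficit: pre-stretch Po is 0; deficit undefined")
  if (through_stretch < 1L || through_stretch > length(po) - 1L)
    abort("force_deficit: through_stretch index not present in the series")
  100 * (po[1] - po[through_stretch + 1L]) / po[1]
}

#' Eccentric contraction decrement summary, ECD(1-10) and ECD(1-30)
#'
#' Convenience reduction of a 30-stretch protocol (3 sets of 10 lengthening
#' contractions): the force deficit after stretch 10 and after stretch 30.
#'
#' @param po Po series indexed 0..30 (length 31).
#' @return named numeric `c(ecd_1_10, ecd_1_30)` in percent.
#' @export
ecd_summary <- function(po) {
  if (length(po) < 31L)
    abort("ecd_summary: need Po at stretches 0..30 (length 31)")
  c(ecd_1_10 = force_deficit(po, 10L), ecd_1_30 = force_deficit(po, 30L))
}

#' Percent change of a comparison group relative to a reference
#'
#' 100 * (comparison - reference) / reference; e.g. treated vs untreated
#' group means.
#'
#' @param reference_mean reference (e.g. untreated) mean; nonzero.
#' @param comparison_mean comparison (e.g. treated) mean.
#' @return percent change.
#' @export
percent_change <- function(reference_mean, comparison_mean) {
  if (any(reference_mean == 0)) abort("percent_change: reference mean is 0")
  100 * (comparison_mean - reference_mean) / reference_mean
}

#' Cranial sartorius circumference index
#'
#' Mean of replicate suture-length measurements (mm) divided by body mass
#' (kg); a surrogate for CS hypertrophy.
#'
#' @param replicate_lengths numeric vector of circumference measurements, mm.
#' @param body_mass kg.
#' @return index in mm/kg.
#' @export
cs_circumference_index <- function(replicate_lengths, body_mass) {
  if (!length(replicate_lengths)) abort("cs_circumference_index: no replicates")
  if (any(replicate_lengths <= 0)) abort("cs_circumference_index: lengths must be > 0")
  if (any(body_mass <= 0)) abort("cs_circumference_index: body_mass must be > 0")
  mean(replicate_lengths) / body_mass
}

#' Average left/right limb measurements to one value per animal
#'
#' Group statistics assume one independent observation per animal, so limb
#' replicates are averaged first.
#'
#' @param df data.frame with an `animal_id` column, an optional `limb`
#'   column, and numeric measurement columns.
#' @return data.frame with one row per animal; non-numeric columns keep the
#'   first value seen.
#' @export
average_limbs <- function(df) {
  stopifnot("animal_id" %in% names(df))
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "animal_id"
  agg <- lapply(split(df, df$animal_id), function(g) {
    out <- g[1, setdiff(names(df), "limb"), drop = FALSE]
    out[names(df)[num]] <- lapply(g[names(df)[num]], mean)
    out
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Per-group endpoint summary (mean ± sd table)
#'
#' Reduces a cohort table to a per-group summary shaped like a trial
#' phenotype table: one row per endpoint, one mean/sd/n triple per group.
#'
#' @param cohort data.frame with a `group` column and numeric endpoint
#'   columns.
#' @param endpoints character vector of endpoint columns; default all
#'   numeric columns except `animal_id`.
#' @return data.frame with columns `endpoint`, `group`, `n`, `mean`, `sd`.
#' @export
summarize_cohort <- function(cohort, endpoints = NULL) {
  stopifnot("group" %in% names(cohort))
  if (is.null(endpoints)) {
    endpoints <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
    endpoints <- setdiff(endpoints, c("animal_id", "age_months"))
  }
  groups <- unique(cohort$group)
  out <- expand.grid(endpoint = endpoints, group = groups,
                     stringsAsFactors = FALSE)
  stats_for <- function(ep, g) {
    v <- cohort[[ep]][cohort$group == g]
    v <- v[!is.na(v)]
    c(n = length(v), mean = mean(v), sd = stats::sd(v))
  }
  m <- t(mapply(stats_for, out$endpoint, out$group))
  cbind(out, as.data.frame(m))
}
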
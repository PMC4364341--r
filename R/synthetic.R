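# Seeded synthetic-data generators: multi-echo MRI phantoms with patchy
# hyperintense lesions, trial cohort tables, and histology marker counts.
# These emulate the statistical structure the analysis assumes (two
# genotypes x two treatments with unequal group sizes, mono-exponential echo
# decay, lesion prevalence differing by group) so every downstream stage is
# testable without real data.

#' Specification of a synthetic multi-echo phantom
#'
#' Muscles are laid out as non-overlapping axis-aligned ellipsoids (one per
#' muscle, stacked along x); anatomical realism is out of scope. Each
#' muscle decays with its baseline T2; lesion voxels form connected
#' spherical patches with T2 shifted by `lesion_T2_shift` (positive =
#' hyperintense, emulating patchy necrosis). Signal follows
#' S(TE) = S0 exp(-TE/T2) plus additive Gaussian noise (a simplification of
#' Rician magnitude noise).
#'
#' @param grid_shape 3 positive integers, voxels.
#' @param voxel_size mm per axis.
#' @param muscles data.frame with columns `label` (positive int), `name`,
#'   `fraction` (target volume fraction of the grid), `baseline_t2` (ms).
#' @param lesion_fraction fraction in \[0,1\] of each muscle's voxels inside
#'   lesion patches.
#' @param lesion_t2_shift additive T2 shift in lesions, ms.
#' @param lesion_patch_radius patch radius, voxels.
#' @param echo_times ms, strictly increasing; default 10 evenly spaced
#'   echoes 10..100 ms (CPMG-like).
#' @param s0 proton-density signal, arbitrary units.
#' @param noise_sd additive Gaussian noise sd, signal units.
#' @param seed integer seed; all phantom randomness derives from it via
#'   named streams.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48L, 32L, 16L),
                         voxel_size = c(1.5, 1.5, 3),
                         muscles = data.frame(
                           label = 1:3,
                           name = c("biceps_femoris", "vastus_lateralis",
                                    "semitendinosus"),
                           fraction = c(0.10, 0.08, 0.06),
                           baseline_t2 = c(40.2, 40.7, 40.4)),
                         lesion_fraction = 0,
                         lesion_t2_shift = 30,
                         lesion_patch_radius = 2L,
                         echo_times = seq(10, 100, by = 10),
                         s0 = 1000,
                         noise_sd = 0,
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4))
  if (lesion_fraction < 0 || lesion_fraction > 1)
    abort("phantom_spec: lesion_fraction must be in [0, 1]")
  if (any(echo_times <= 0) || any(diff(echo_times) <= 0))
    abort("phantom_spec: echo_times must be positive and strictly increasing")
  if (any(muscles$baseline_t2 <= 0))
    abort("phantom_spec: baseline_t2 must be > 0")
  if (anyDuplicated(muscles$label) || any(muscles$label < 1))
    abort("phantom_spec: muscle labels must be distinct positive integers")
  if (noise_sd < 0) abort("phantom_spec: noise_sd must be >= 0")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = as.numeric(voxel_size), muscles = muscles,
                 lesion_fraction = lesion_fraction,
                 lesion_t2_shift = lesion_t2_shift,
                 lesion_patch_radius = as.integer(lesion_patch_radius),
                 echo_times = as.numeric(echo_times), s0 = s0,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# ellipsoid masks, one muscle per x-slab, widths proportional to fraction
phantom_muscle_masks <- function(spec) {
  d <- spec$grid_shape
  fr <- spec$muscles$fraction
  w <- d[1] * fr / sum(fr)
  x0 <- c(0, cumsum(w))
  ax <- seq_len(d[1]); ay <- seq_len(d[2]); az <- seq_len(d[3])
  masks <- list()
  for (i in seq_len(nrow(spec$muscles))) {
    cx <- (x0[i] + x0[i + 1]) / 2
    a <- 0.48 * w[i]; b <- 0.42 * d[2]; c_ <- 0.42 * d[3]
    dist2 <- outer(outer(((ax - cx) / a)^2, ((ay - d[2] / 2 - 0.5) / b)^2, `+`),
                   ((az - d[3] / 2 - 0.5) / c_)^2, `+`)
    masks[[as.character(spec$muscles$label[i])]] <- dist2 <= 1
  }
  masks
}

#' Generate a multi-echo phantom and its label map
#'
#' Lesion patches are spheres whose centers are sampled uniformly inside the
#' muscle mask, rejected when they overlap an existing patch, until each
#' muscle's voxel budget (`lesion_fraction` of its voxels) is met to within
#' one patch; the achieved fraction is reported. Identical spec + seed gives
#' bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` ([multi_echo_volume()]), `labels`
#'   ([label_map()]), `t2_true` (3D array, ms, NA outside muscle),
#'   `lesion_mask` (3D logical), `achieved_lesion_fraction` (named, per
#'   muscle).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  masks <- phantom_muscle_masks(spec)
  labels <- array(0L, d)
  t2 <- array(NA_real_, d)
  for (i in seq_len(nrow(spec$muscles))) {
    m <- masks[[i]]
    labels[m] <- spec$muscles$label[i]
    t2[m] <- spec$muscles$baseline_t2[i]
  }

  lesion <- array(FALSE, d)
  achieved <- numeric(nrow(spec$muscles))
  names(achieved) <- spec$muscles$name
  r <- spec$lesion_patch_radius
  if (spec$lesion_fraction > 0) {
    off <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
    off <- off[rowSums(off^2) <= r^2, , drop = FALSE]
    set.seed(sub_seed(spec$seed, "phantom/lesions"))
    for (i in seq_len(nrow(spec$muscles))) {
      m <- masks[[i]]
      vox <- which(m, arr.ind = TRUE)
      ext <- apply(vox, 2, function(v) diff(range(v)) + 1L)
      if (any(2L * r + 1L > ext))
        abort("generate_phantom: lesion_patch_radius ", r,
              " exceeds the extent of muscle '", spec$muscles$name[i], "'")
      target <- round(spec$lesion_fraction * nrow(vox))
      placed <- 0L
      attempts <- 0L
      while (placed < target && attempts < 200L * max(1L, target)) {
        attempts <- attempts + 1L
        ctr <- vox[sample.int(nrow(vox), 1L), ]
        pat <- sweep(off, 2, ctr, `+`)
        ok <- pat[, 1] >= 1 & pat[, 1] <= d[1] &
          pat[, 2] >= 1 & pat[, 2] <= d[2] &
          pat[, 3] >= 1 & pat[, 3] <= d[3]
        pat <- pat[ok, , drop = FALSE]
        pidx <- pat[, 1] + (pat[, 2] - 1L) * d[1] + (pat[, 3] - 1L) * d[1] * d[2]
        pidx <- pidx[m[pidx]]
        if (!length(pidx) || any(lesion[pidx])) next  # no overlapping patches
        lesion[pidx] <- TRUE
        placed <- placed + length(pidx)
      }
      achieved[i] <- placed / nrow(vox)
    }
    t2[lesion] <- t2[lesion] + spec$lesion_t2_shift
  }

  te <- spec$echo_times
  sig <- array(0, c(d, length(te)))
  inmask <- !is.na(t2)
  decay <- exp(outer(-1 / t2[inmask], te)) * spec$s0
  for (e in seq_along(te)) {
    sl <- array(0, d)
    sl[inmask] <- decay[, e]
    sig[, , , e] <- sl
  }
  if (spec$noise_sd > 0) {
    set.seed(sub_seed(spec$seed, "phantom/noise"))
    sig <- sig + array(stats::rnorm(length(sig), 0, spec$noise_sd), dim(sig))
  }

  nm <- stats::setNames(spec$muscles$name, as.character(spec$muscles$label))
  list(volume = multi_echo_volume(sig, te, spec$voxel_size),
       labels = label_map(labels, nm, spec$voxel_size),
       t2_true = t2, lesion_mask = lesion,
       achieved_lesion_fraction = achieved)
}

#' Write a phantom to disk (NIfTI + sidecars)
#'
#' Writes the 4D magnitude volume with a JSON echo-time sidecar, the integer
#' label map, and a label-name CSV.
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return named vector of paths, invisibly.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, paste0(prefix, c(".nii.gz", "_echoes.json",
                                       "_labels.nii.gz", "_labels.csv")))
  write_nifti(phantom$volume$data, p[1], phantom$volume$voxel_size)
  jsonlite::write_json(list(echo_times_ms = phantom$volume$echo_times),
                       p[2], digits = NA)
  write_nifti(phantom$labels$labels, p[3], phantom$labels$voxel_size,
              datatype = "int16")
  utils::write.csv(data.frame(label = names(phantom$labels$names),
                              name = unname(phantom$labels$names)),
                   p[4], row.names = FALSE)
  invisible(stats::setNames(p, c("volume", "echoes", "labels", "label_names")))
}

COHORT_GROUPS <- c("normal_untreated", "normal_nbd",
                   "grmd_untreated", "grmd_nbd")

#' Default cohort endpoint distributions
#'
#' Per-group means and sds for the measured endpoints at the 6-month
#' timepoint of a GRMD natural-history + treatment design, in group order
#' normal untreated / normal treated / GRMD untreated / GRMD treated.
#'
#' @return named list; each element has `means` and `sds` (length 4).
#' @export
default_cohort_variables <- function() {
  v <- function(m, s) list(means = m, sds = s)
  list(
    body_mass_kg = v(c(17.80, 21.10, 13.40, 12.70), c(0.44, 3.15, 2.20, 2.81)),
    flexion_force_n = v(c(23.19, 25.75, 7.85, 6.79), c(2.20, 2.18, 1.98, 1.13)),
    flexion_force_n_per_kg = v(c(1.30, 1.24, 0.62, 0.55), c(0.13, 0.19, 0.18, 0.13)),
    flexion_torque_nm = v(c(3.22, 3.65, 1.03, 0.89), c(0.35, 0.43, 0.23, 0.18)),
    extension_force_n = v(c(46.43, 42.17, 18.47, 34.30), c(8.44, 7.46, 10.11, 9.65)),
    extension_force_n_per_kg = v(c(2.61, 2.00, 1.56, 2.70), c(0.49, 0.22, 0.92, 0.65)),
    extension_torque_nm = v(c(6.44, 6.02, 2.46, 4.55), c(1.24, 1.38, 1.28, 1.49)),
    ecd_1_10_pct = v(c(8.29, 14.47, 28.96, 32.04), c(2.88, 7.31, 18.07, 13.46)),
    ecd_1_30_pct = v(c(17.86, 23.25, 54.30, 54.48), c(5.20, 17.40, 14.73, 13.64)),
    ttj_angle_deg = v(c(160.9, 158.3, 151.3, 160.17), c(3.40, 2.08, 10.19, 8.84)),
    hip_angle_deg = v(c(104.4, 103.0, 109.6, 100.2), c(5.76, 11.40, 8.02, 6.01)),
    pelvic_angle_deg = v(c(36.14, 40.33, 48.30, 36.83), c(5.98, 5.03, 5.54, 5.12)),
    cs_circumference_mm_per_kg = v(c(2.09, 2.30, 4.03, 3.67), c(0.40, 0.49, 1.04, 0.65))
  )
}

COHORT_POSITIVE <- c("body_mass_kg", "flexion_force_n", "flexion_force_n_per_kg",
                     "flexion_torque_nm", "extension_force_n",
                     "extension_force_n_per_kg", "extension_torque_nm",
                     "cs_circumference_mm_per_kg")

#' Specification of a synthetic trial cohort
#'
#' @param n_per_group 4 integers: normal untreated, normal treated, GRMD
#'   untreated, GRMD treated; default 8/3/10/6.
#' @param variables named list; each element `list(means =, sds =)` with one
#'   value per group; defaults from [default_cohort_variables()].
#' @param positive names of strictly positive variables (negative draws are
#'   redrawn and counted).
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(8L, 3L, 10L, 6L),
                        variables = default_cohort_variables(),
                        positive = COHORT_POSITIVE,
                        seed = 1L) {
  if (length(n_per_group) != 4L || any(n_per_group < 1))
    abort("cohort_spec: n_per_group must be 4 integers >= 1")
  for (nm in names(variables)) {
    v <- variables[[nm]]
    if (length(v$means) != 4L || length(v$sds) != 4L)
      abort("cohort_spec: variable '", nm, "' needs 4 means and 4 sds")
    if (any(v$sds < 0)) abort("cohort_spec: sds must be >= 0 ('", nm, "')")
  }
  structure(list(n_per_group = as.integer(n_per_group), variables = variables,
                 positive = positive, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort table
#'
#' One row per animal; every variable is drawn from its per-group normal
#' distribution using a named RNG stream per variable. Negative draws for
#' strictly positive variables are redrawn; the total redraw count is
#' attached as attribute `n_redraws`.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with `animal_id`, `genotype`, `treatment`, `group`,
#'   `age_months` and one column per variable; attribute `n_redraws`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_per_group
  group <- rep(COHORT_GROUPS, n)
  df <- data.frame(
    animal_id = sprintf("%s_%02d", group, unlist(lapply(n, seq_len))),
    genotype = rep(c("normal", "normal", "grmd", "grmd"), n),
    treatment = rep(c("untreated", "nbd", "untreated", "nbd"), n),
    group = group, age_months = 6,
    stringsAsFactors = FALSE)
  redraws <- 0L
  for (nm in names(spec$variables)) {
    v <- spec$variables[[nm]]
    set.seed(sub_seed(spec$seed, paste0("cohort/", nm)))
    draws <- stats::rnorm(sum(n), rep(v$means, n), rep(v$sds, n))
    if (nm %in% spec$positive) {
      bad <- which(draws < 0)
      guard <- 0L
      while (length(bad) && guard < 1000L) {
        guard <- guard + 1L
        redraws <- redraws + length(bad)
        draws[bad] <- stats::rnorm(length(bad), rep(v$means, n)[bad],
                                   rep(v$sds, n)[bad])
        bad <- which(draws < 0)
      }
      if (length(bad))
        abort("generate_cohort: could not draw positive values for '", nm, "'")
    }
    df[[nm]] <- draws
  }
  attr(df, "n_redraws") <- redraws
  df
}

#' Default untreated histology marker levels
#'
#' Plausible per-area quantitation levels (arbitrary units) for the four
#' assessed muscles and markers; magnitudes are free choices since marker
#' quantitation is an input to the analysis, not a claim.
#'
#' @return 4 x 4 numeric matrix, muscles x markers.
#' @export
default_histo_means <- function() {
  matrix(c(120, 90, 70, 80,    # inflammation (PM2K+ macrophages / area)
           30, 24, 20, 22,     # necrotic foci
           55, 40, 36, 30,     # IgG+ myofibers
           45, 32, 38, 30),    # regeneration (centrally located nuclei)
         nrow = 4,
         dimnames = list(HISTO_MUSCLES, HISTO_MARKERS))
}

#' Default per-muscle, per-marker rescue magnitudes (percent)
#'
#' The generator's default treatment effect: percent reduction of each
#' marker in the treated group.
#'
#' @return 4 x 4 numeric matrix, muscles x markers, percent.
#' @export
default_histo_rescue <- function() {
  matrix(c(34, 40, 31, 37,
           25, 34, 35, 37,
           22, 35, 32, 32,
           43, 35, 44, 41),
         nrow = 4,
         dimnames = list(HISTO_MUSCLES, HISTO_MARKERS))
}

#' Default significance pattern of the histology comparisons
#'
#' All cells significant except the cranial sartorius necrotic-foci and
#' IgG cells (trend only), matching the generator's stated world.
#'
#' @return 4 x 4 logical matrix.
#' @export
default_histo_significance <- function() {
  s <- matrix(TRUE, 4, 4, dimnames = list(HISTO_MUSCLES, HISTO_MARKERS))
  s["cranial_sartorius", c("necrotic_foci", "igg_fibers")] <- FALSE
  s
}

#' Generate untreated/treated histology marker matrices
#'
#' Treated means are `(1 - rescue/100) *` untreated means. With
#' `dispersion = 0` the matrices equal the means exactly; otherwise each
#' cell is drawn from a Gamma distribution with that mean and coefficient of
#' variation `dispersion` (keeps marker levels nonnegative).
#'
#' @param untreated_means muscles x markers matrix of nonnegative means.
#' @param rescue matrix of programmed percent rescue, same shape.
#' @param dispersion nonnegative coefficient of variation.
#' @param seed integer seed.
#' @return list with matrices `untreated` and `treated`.
#' @export
generate_histo_counts <- function(untreated_means = default_histo_means(),
                                  rescue = default_histo_rescue(),
                                  dispersion = 0, seed = 1L) {
  if (any(untreated_means < 0))
    abort("generate_histo_counts: means must be >= 0")
  if (dispersion < 0) abort("generate_histo_counts: dispersion must be >= 0")
  stopifnot(all(dim(untreated_means) == dim(rescue)))
  treated_means <- untreated_means * (1 - rescue / 100)
  if (dispersion == 0)
    return(list(untreated = untreated_means, treated = treated_means))
  draw <- function(mu, stream) {
    set.seed(sub_seed(seed, stream))
    shape <- 1 / dispersion^2
    out <- mu
    pos <- mu > 0
    out[pos] <- stats::rgamma(sum(pos), shape = shape,
                              scale = mu[pos] / shape)
    out
  }
  list(untreated = draw(untreated_means, "histo/untreated"),
       treated = draw(treated_means, "histo/treated"))
}
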
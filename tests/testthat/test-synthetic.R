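test_that("generate_phantom is deterministic for identical spec and seed", {
  sp <- phantom_spec(lesion_fraction = 0.15, noise_sd = 10, seed = 42)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$labels$labels, b$labels$labels)
  expect_identical(a$lesion_mask, b$lesion_mask)
  c <- generate_phantom(phantom_spec(lesion_fraction = 0.15, noise_sd = 10,
                                     seed = 43))
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("noiseless homogeneous phantom decays exactly at baseline T2", {
  sp <- phantom_spec(lesion_fraction = 0, noise_sd = 0)
  ph <- generate_phantom(sp)
  te <- ph$volume$echo_times
  for (i in seq_len(nrow(sp$muscles))) {
    m <- ph$labels$labels == sp$muscles$label[i]
    v <- matrix(ph$volume$data, ncol = length(te))[m, , drop = FALSE]
    expected <- sp$s0 * exp(-te / sp$muscles$baseline_t2[i])
    expect_equal(v, matrix(expected, nrow(v), length(te), byrow = TRUE),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # fitted T2 equals programmed T2 at machine precision
  fit <- fit_t2(ph$volume)
  inm <- ph$labels$labels > 0
  expect_equal(fit$t2[inm], ph$t2_true[inm], tolerance = 1e-12)
})

test_that("lesion fraction is achieved within tolerance (fit_t2 as oracle)", {
  sp <- phantom_spec(lesion_fraction = 0.2, lesion_t2_shift = 30,
                     noise_sd = 0, seed = 42)
  ph <- generate_phantom(sp)
  fit <- fit_t2(ph$volume)
  for (i in seq_len(nrow(sp$muscles))) {
    m <- ph$labels$labels == sp$muscles$label[i]
    frac_elevated <- mean(fit$t2[m] > sp$muscles$baseline_t2[i] + 1)
    granularity <- 33 / sum(m)   # one radius-2 patch
    expect_lt(abs(frac_elevated - 0.2), 0.02 + granularity)
    expect_lt(abs(ph$achieved_lesion_fraction[i] - 0.2), 0.02 + granularity)
    expect_equal(frac_elevated, unname(ph$achieved_lesion_fraction[i]),
                 tolerance = 1e-12)
  }
})

test_that("oversized lesion patches error naming the muscle", {
  sp <- phantom_spec(lesion_fraction = 0.1, lesion_patch_radius = 50)
  expect_error(generate_phantom(sp), "biceps_femoris")
})

test_that("phantom spec invariants are enforced", {
  expect_error(phantom_spec(lesion_fraction = -0.1), "lesion_fraction")
  expect_error(phantom_spec(lesion_fraction = 1.2), "lesion_fraction")
  expect_error(phantom_spec(echo_times = c(10, 5)), "increasing")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
})

test_that("volume-weighted mean T2 is monotone in lesion fraction (5 seeds)", {
  t2_at <- function(lf, s) {
    ph <- generate_phantom(phantom_spec(lesion_fraction = lf, seed = s))
    fit <- fit_t2(ph$volume)
    weighted_composite(muscle_features(fit, ph$labels), "mean_t2")
  }
  lo <- mean(vapply(1:5, function(s) t2_at(0.05, s), 0))
  hiv <- mean(vapply(1:5, function(s) t2_at(0.25, s), 0))
  expect_gt(hiv, lo)
})

test_that("generate_cohort: determinism, degenerate sds, redraw accounting", {
  sp <- cohort_spec(seed = 42)
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(a, b)
  expect_equal(nrow(a), 8 + 3 + 10 + 6)
  expect_equal(unname(table(a$group)[["grmd_nbd"]]), 6L)

  c2 <- generate_cohort(cohort_spec(seed = 43))
  expect_false(identical(a, c2))
  expect_identical(names(a), names(c2))   # same schema, different draws

  # sd = 0 -> every animal equals its group mean
  vars0 <- default_cohort_variables()
  for (nm in names(vars0)) vars0[[nm]]$sds <- rep(0, 4)
  z <- generate_cohort(cohort_spec(variables = vars0, seed = 42))
  expect_equal(unique(z$extension_force_n_per_kg[z$group == "grmd_untreated"]),
               1.56)
  expect_equal(unique(z$extension_force_n_per_kg[z$group == "grmd_nbd"]), 2.70)
  expect_equal(attr(z, "n_redraws"), 0)

  # strictly positive variables never negative, redraws counted
  spw <- cohort_spec(variables = list(
    body_mass_kg = list(means = rep(0.5, 4), sds = rep(2, 4))), seed = 42)
  w <- generate_cohort(spw)
  expect_true(all(w$body_mass_kg >= 0))
  expect_gt(attr(w, "n_redraws"), 0)
})

test_that("percent_change recovers the programmed force effect at sd -> 0", {
  vars0 <- default_cohort_variables()
  for (nm in names(vars0)) vars0[[nm]]$sds <- rep(0, 4)
  z <- generate_cohort(cohort_spec(variables = vars0, seed = 42))
  untr <- mean(z$extension_force_n_per_kg[z$group == "grmd_untreated"])
  trt <- mean(z$extension_force_n_per_kg[z$group == "grmd_nbd"])
  expect_equal(round(percent_change(untr, trt)), 73)
})

test_that("generate_histo_counts: exact means at dispersion 0, MC mean at 0.1", {
  g0 <- generate_histo_counts(dispersion = 0, seed = 42)
  expect_equal(g0$untreated, default_histo_means())
  expect_equal(g0$treated,
               default_histo_means() * (1 - default_histo_rescue() / 100))
  expect_error(generate_histo_counts(untreated_means = matrix(-1, 4, 4),
                                     rescue = default_histo_rescue()),
               "means")

  # Monte-Carlo: mean per-replicate rescue approaches the programmed R.
  # With Gamma noise at CV = 0.1 the ratio estimator has bias of order
  # (100 - R) * CV^2 ~ 0.7 points; tolerance = bias bound + 3 MC se.
  disp <- 0.1
  B <- 1000
  cell_rescue <- sapply(seq_len(B), function(b) {
    g <- generate_histo_counts(dispersion = disp, seed = b)
    percent_rescue(g$untreated["cranial_sartorius", "regeneration"],
                   g$treated["cranial_sartorius", "regeneration"])
  })
  programmed <- default_histo_rescue()["cranial_sartorius", "regeneration"]
  mc_se <- sd(cell_rescue) / sqrt(B)
  bias_bound <- (100 - programmed) * disp^2
  expect_lt(abs(mean(cell_rescue) - programmed), bias_bound + 3 * mc_se)
})

test_that("phantom NIfTI export round-trips", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(8, 8, 6), seed = 42))
  d <- tempfile()
  paths <- write_phantom(ph, d)
  vol <- read_nifti(paths["volume"])
  expect_equal(dim(vol$data), dim(ph$volume$data))
  lab <- read_nifti(paths["labels"])
  expect_identical(array(as.integer(lab$data), dim(lab$data)),
                   ph$labels$labels)
  te <- jsonlite::read_json(paths["echoes"], simplifyVector = TRUE)
  expect_equal(te$echo_times_ms, ph$volume$echo_times)
  unlink(d, recursive = TRUE)
})
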
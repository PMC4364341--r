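as_vol <- function(v) array(v, c(length(v), 1, 1))

test_that("quantize: equal-width bins, constant ROI, fixed range", {
  x <- as_vol(c(10, 20, 30, 40))
  q <- quantize(x, array(TRUE, dim(x)), G = 2)
  expect_identical(as.vector(q), c(1L, 1L, 2L, 2L))

  expect_warning(qc <- quantize(as_vol(rep(7, 5)), array(TRUE, c(5, 1, 1)), G = 4),
                 "constant ROI")
  expect_identical(as.vector(qc), rep(1L, 5))

  xf <- as_vol(c(-5, 0.1, 0.9, 99))
  qf <- quantize(xf, array(TRUE, dim(xf)), G = 4, binning = "fixed_range",
                 range = c(0, 1))
  expect_identical(as.vector(qf), c(1L, 1L, 4L, 4L))  # clamped outside

  m <- array(c(TRUE, FALSE, TRUE, TRUE), c(4, 1, 1))
  expect_identical(as.vector(quantize(as_vol(c(1, 99, 2, 3)), m, G = 2))[2], 0L)
  expect_error(quantize(x, array(FALSE, dim(x))), "empty mask")
  expect_error(quantize(x, array(TRUE, dim(x)), G = 1), "G must be")
})

test_that("quantize spreads a uniform ROI evenly across levels", {
  set.seed(42)
  n <- 1e5
  x <- as_vol(runif(n))
  q <- quantize(x, array(TRUE, dim(x)), G = 16)
  freq <- tabulate(q, 16) / n
  expect_true(all(abs(freq - 1 / 16) < 4 * sqrt((1 / 16) * (15 / 16) / n) + 1e-4))
})

test_that("run_length_matrix: hand-enumerated cases", {
  m <- run_length_matrix(as_vol(c(1L, 1L, 2L)), direction = c(1, 0, 0))
  expect_equal(m$n_runs, 2)
  expect_equal(m$counts[1, 2], 1L)   # level 1, length 2
  expect_equal(m$counts[2, 1], 1L)   # level 2, length 1

  # checkerboard along x: all runs length 1
  cb <- array(rep(c(1L, 2L), 8), c(4, 2, 2))
  mcb <- run_length_matrix(cb, direction = c(1, 0, 0))
  expect_equal(mcb$n_runs, 16)
  expect_equal(ncol(mcb$counts), 1L)

  expect_error(run_length_matrix(cb, direction = c(0, 0, 0)), "direction")
  expect_error(run_length_matrix(cb, array(FALSE, dim(cb)), c(1, 0, 0)),
               "empty mask")
})

test_that("run_length_matrix matches the brute-force walker", {
  set.seed(42)
  dirs <- rlm_directions_13()
  for (rep in 1:6) {
    d <- sample(2:5, 3, replace = TRUE)
    q <- array(sample.int(3, prod(d), TRUE), d)
    mask <- array(runif(prod(d)) > 0.25, d)
    if (!any(mask)) next
    for (i in seq_len(nrow(dirs)))
      expect_rlm_matches_oracle(q, mask, dirs[i, ])
  }
})

test_that("RLM conservation: sum_ij j * p(i,j) equals mask voxel count", {
  set.seed(42)
  q <- array(sample.int(4, 6 * 5 * 4, TRUE), c(6, 5, 4))
  mask <- array(runif(120) > 0.3, c(6, 5, 4))
  for (i in seq_len(nrow(rlm_directions_13()))) {
    m <- run_length_matrix(q, mask, rlm_directions_13()[i, ])
    expect_equal(sum(sweep(m$counts, 2, seq_len(ncol(m$counts)), `*`)),
                 sum(mask))
  }
})

test_that("SLI and HI closed forms", {
  # all runs length 1 -> SRE 1; single run length 2 -> 1/4
  all1 <- run_length_matrix(as_vol(c(1L, 2L, 1L, 2L)), direction = c(1, 0, 0))
  expect_equal(sli(all1), 1)
  one2 <- run_length_matrix(as_vol(c(3L, 3L)), direction = c(1, 0, 0))
  expect_equal(sli(one2), 0.25)
  # {3 x len1, 1 x len2}: SRE = (3 + 1/4)/4, RLN = (3^2 + 1^2)/4
  mixed <- run_length_matrix(as_vol(c(1L, 2L, 1L, 2L, 2L)), direction = c(1, 0, 0))
  expect_equal(mixed$n_runs, 4)
  expect_equal(sli(mixed), 0.8125)
  expect_equal(hi(mixed), 2.5)
  # N runs all same length -> RLN = N; one run per distinct length -> RLN = 1
  expect_equal(hi(all1), 4)
  perlen <- run_length_matrix(as_vol(c(1L, 2L, 2L, 1L, 1L, 1L)),
                              direction = c(1, 0, 0))
  expect_equal(hi(perlen), 1)
})

test_that("SLI in (0,1] and HI in [1, N_r] on random volumes", {
  set.seed(42)
  for (rep in 1:5) {
    q <- array(sample.int(4, 4^3, TRUE), c(4, 4, 4))
    rl <- run_length_matrices(q)
    s <- sli(rl); h <- hi(rl)
    expect_gt(s, 0); expect_lte(s, 1)
    expect_gte(h, 1)
    expect_lte(h, max(vapply(rl, function(m) m$n_runs, 0)))
  }
})

test_that("13-direction features are invariant to axis permutation", {
  set.seed(42)
  q <- array(sample.int(4, 5 * 5 * 5, TRUE), c(5, 5, 5))
  rl <- run_length_matrices(q)
  qp <- aperm(q, c(3, 1, 2))
  rlp <- run_length_matrices(qp)
  expect_equal(sli(rlp), sli(rl), tolerance = 1e-12)
  expect_equal(hi(rlp), hi(rl), tolerance = 1e-12)
})

test_that("histogram entropy closed forms", {
  m <- array(TRUE, c(4, 1, 1))
  expect_equal(histogram_entropy(as_vol(rep(3, 4)), m, G = 8), 0)
  # exactly uniform over 16 bins
  x <- as_vol((0:15) + 0.5)
  expect_equal(histogram_entropy(x, array(TRUE, c(16, 1, 1)), G = 16), 4)
  # two bins, f = (0.75, 0.25)
  x2 <- as_vol(c(0, 0, 0, 1))
  expect_equal(histogram_entropy(x2, m, G = 2),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)),
               tolerance = 1e-12)
  expect_equal(round(histogram_entropy(x2, m, G = 2), 4), 0.8113)
})

test_that("muscle_features: volumes, missing labels, slab selection", {
  sp <- phantom_spec(seed = 42)
  ph <- generate_phantom(sp)
  tm <- fit_t2(ph$volume)
  ft <- muscle_features(tm, ph$labels)
  expect_s3_class(ft, "muscle_feature_table")
  for (i in seq_len(nrow(ft))) {
    expect_equal(ft$volume_mm3[i], ft$n_voxels[i] * prod(sp$voxel_size))
    expect_equal(ft$n_voxels[i], sum(ph$labels$labels == ft$label[i]))
  }
  expect_false(any(ft$missing))
  expect_equal(ft$mean_t2, sp$muscles$baseline_t2, tolerance = 1e-10)

  # a named label with no voxels is flagged, not dropped
  lm2 <- ph$labels
  lm2$names <- c(lm2$names, "99" = "phantom_muscle")
  ft2 <- muscle_features(tm, lm2)
  expect_true(ft2$missing[ft2$label == 99])
  expect_equal(nrow(ft2), 4)

  # whole-muscle vs 5-slice slab differ for a z-extended muscle
  ftw <- muscle_features(tm, ph$labels, n_slices = NA)
  expect_false(isTRUE(all.equal(ftw$hi, ft$hi)))
})

test_that("weighted_composite: means, bounds, renormalization", {
  tb <- data.frame(volume_mm3 = c(2, 1), sli = c(0.6, 0.9),
                   missing = c(FALSE, FALSE))
  expect_equal(weighted_composite(tb, "sli"), 0.7)
  tb$volume_mm3 <- c(5, 5)
  expect_equal(weighted_composite(tb, "sli"), 0.75)  # equal volumes -> mean
  one <- data.frame(volume_mm3 = 3, sli = 0.42, missing = FALSE)
  expect_equal(weighted_composite(one, "sli"), 0.42)
  # missing muscles excluded with weight renormalization
  tb3 <- data.frame(volume_mm3 = c(2, 1, 10), sli = c(0.6, 0.9, NA),
                    missing = c(FALSE, FALSE, TRUE))
  expect_equal(weighted_composite(tb3, "sli"), 0.7)
  expect_true(weighted_composite(tb3, "sli") >= min(0.6, 0.9))
  expect_true(weighted_composite(tb3, "sli") <= max(0.6, 0.9))
  expect_error(weighted_composite(data.frame(volume_mm3 = 0, sli = 1,
                                             missing = FALSE), "sli"),
               "no muscle")
})
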
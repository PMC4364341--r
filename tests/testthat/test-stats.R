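test_that("welch_t from summaries matches stats::t.test on raw samples", {
  set.seed(42)
  for (rep in 1:5) {
    x <- rnorm(8, 10, 2); y <- rnorm(5, 8, 3)
    ours <- welch_t_samples(x, y)
    ref <- t.test(x, y)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    refp <- t.test(x, y, var.equal = TRUE)
    oursp <- welch_t_samples(x, y, var_equal = TRUE)
    expect_equal(oursp$p, refp$p.value, tolerance = 1e-12)
  }
})

test_that("welch_t summary route equals raw route exactly", {
  set.seed(42)
  x <- rnorm(10, 52.28, 4.52); y <- rnorm(6, 47.34, 3.10)
  a <- welch_t_samples(x, y)
  b <- welch_t(mean(x), sd(x), 10, mean(y), sd(y), 6)
  expect_identical(a$t, b$t)
  expect_identical(a$df, b$df)
  expect_identical(a$p, b$p)
})

test_that("welch_t degenerate and symmetry cases", {
  r0 <- welch_t(5, 1, 8, 5, 1, 8)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  a <- welch_t(10, 2, 8, 8, 3, 5)
  b <- welch_t(8, 3, 5, 10, 2, 8)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  expect_error(welch_t(1, 0, 5, 2, 0, 5), "both sds")
  expect_error(welch_t(1, 1, 1, 2, 1, 5), "n >= 2")
  # equal sds and ns: Welch t equals pooled t with df = n1 + n2 - 2
  w <- welch_t(10, 2, 6, 8, 2, 6)
  p <- welch_t(10, 2, 6, 8, 2, 6, var_equal = TRUE)
  expect_equal(w$t, p$t, tolerance = 1e-12)
  expect_equal(w$df, 10, tolerance = 1e-12)
})

test_that("welch_t on the published composite summaries gives t near 2.59", {
  r <- welch_t(52.28, 4.52, 10, 47.34, 3.10, 6)
  expect_equal(round(r$t, 2), 2.59)
})

test_that("bh_fdr matches hand computation and stats::p.adjust", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.123), 0.123)             # m = 1 unchanged
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5)) # equal ps unchanged
  set.seed(42)
  for (rep in 1:5) {
    p <- runif(sample(2:20, 1))
    expect_equal(bh_fdr(p), p.adjust(p, "BH"), tolerance = 1e-14)
    expect_true(all(bh_fdr(p) >= p))
    expect_true(all(bh_fdr(p) <= 1))
    o <- sample(length(p))                        # order equivariance
    expect_equal(bh_fdr(p[o]), bh_fdr(p)[o], tolerance = 1e-14)
  }
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("flag_p implements the significance/trend reporting rule", {
  expect_equal(flag_p(0.038), "significant")
  expect_equal(flag_p(0.092), "trend")
  expect_equal(flag_p(0.5), "ns")
  expect_equal(flag_p(c(0.049999, 0.05, 0.19999, 0.2)),
               c("significant", "trend", "trend", "ns"))
  expect_equal(flag_p(0.092, alpha_sig = 0.1), "significant")
  expect_error(flag_p(1.5), "\\[0, 1\\]")
})

test_that("compare_groups tests a family with FDR and flags", {
  set.seed(42)
  df <- data.frame(group = rep(c("a", "b"), c(10, 6)),
                   v1 = c(rnorm(10, 5), rnorm(6, 5)),
                   v2 = c(rnorm(10, 5), rnorm(6, 9)),
                   v3 = c(rnorm(10, 5), rnorm(6, 5.2)))
  out <- compare_groups(df, c("v1", "v2", "v3"), c("a", "b"))
  expect_equal(nrow(out), 3)
  expect_equal(out$p_adj, bh_fdr(out$p))
  expect_true(all(out$p_adj >= out$p))
  expect_equal(out$flag, flag_p(out$p_adj))
  # raw equality to direct welch on one endpoint
  r <- welch_t_samples(df$v2[df$group == "a"], df$v2[df$group == "b"])
  expect_equal(out$p[out$endpoint == "v2"], r$p)

  expect_error(compare_groups(df, "v1", c("a", "zzz")), "absent")
  df$v4 <- c(rnorm(10), rep(NA, 6))
  expect_warning(out2 <- compare_groups(df, c("v1", "v4"), c("a", "b")),
                 "skipped")
  expect_equal(nrow(out2), 1)
  expect_warning(expect_error(
    compare_groups(df, "v4", c("a", "b")), "no testable"), "skipped")
})
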
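# ECDF, empirical percentiles, overlays, normality and K-S machinery,
# bootstrap.

test_that("ECDF places p_i = i/n at order statistics on the log10 scale", {
  e <- ttc_ecdf(c(1, 10, 100))
  expect_equal(e$x, c(0, 1, 2))
  expect_equal(e$p, c(1, 2, 3) / 3)

  expect_equal(ttc_ecdf(5)$p, 1)

  e <- ttc_ecdf(c(2, 2, 4))
  expect_equal(e$p, c(1, 2, 3) / 3)
  expect_equal(e$x, log10(c(2, 2, 4)))

  expect_error(ttc_ecdf(c(1, 0)), "positive")
})

test_that("empirical percentile matches closed forms and trivial cases", {
  expect_equal(empirical_percentile(1:100, 5)$value, 5.95)
  expect_equal(empirical_percentile(rep(3.2, 7), 5)$value, 3.2)
  expect_equal(empirical_percentile(c(1, 2, 3), 50)$value, 2)
  expect_equal(empirical_percentile(1:100, 5)$method, "linear")
  expect_error(empirical_percentile(1:10, 0), "p must")
})

test_that("percentile is monotone in p and scale-equivariant", {
  set.seed(1)
  v <- 10^rnorm(37)
  ps <- c(1, 5, 25, 50, 75, 95, 99)
  qs <- sapply(ps, function(p) empirical_percentile(v, p)$value)
  expect_true(all(diff(qs) >= 0))
  cc <- 3.7
  expect_equal(sapply(ps, function(p) empirical_percentile(v * cc, p)$value),
               qs * cc, tolerance = 1e-12)
})

test_that("nearest-rank percentile equals order statistics (oracle over short lists)", {
  sets <- all_multisets(c(0.5, 1, 2, 8), 5)
  for (v in sets) {
    n <- length(v)
    for (i in seq_len(n)) {
      p <- 100 * i / n
      if (p <= 0 || p >= 100) next
      expect_equal(empirical_percentile(v, p, method = "nearest")$value,
                   sort(v)[i], info = paste(paste(v, collapse = ","), p))
    }
    # and the linear method against its own oracle
    expect_equal(empirical_percentile(v, 5, "linear")$value,
                 oracle_quantile_linear(v, 0.05))
  }
})

test_that("normal overlay is a CDF matching the moment fit", {
  set.seed(2)
  v <- 10^rnorm(400, mean = 1, sd = 0.5)  # log10 values ~ N(1, 0.5)
  ov <- normal_overlay(v)
  expect_equal(nrow(ov), 1000)
  expect_true(all(diff(ov$cdf) >= 0))
  m <- mean(log10(v)); s <- sd(log10(v))
  at <- function(x) ov$cdf[which.min(abs(ov$x - x))]
  expect_lt(abs(at(m) - 0.5), 0.01)
  expect_lt(abs(at(m + 1.645 * s) - 0.95), 0.01)
  expect_warning(normal_overlay(rep(2, 5)), "variance")
})

test_that("qq points line up for normal data and reject degenerate input", {
  set.seed(3)
  v <- rnorm(500)
  qq <- qq_points(v)
  expect_equal(nrow(qq), 500)
  expect_gt(summary(lm(sample ~ theoretical, qq))$r.squared, 0.99)
  expect_error(qq_points(rep(1, 10)), "variance")
  expect_equal(nrow(qq_points(c(1, 2, 4))), 3)
  expect_error(qq_points(c(1, 2)), "n >= 3")
})

test_that("Shapiro-Wilk bounds, range guard and power on lognormal data", {
  set.seed(4)
  sw <- shapiro_wilk(rnorm(200))
  expect_lte(sw$W, 1)
  expect_gt(sw$W, 0)
  expect_error(shapiro_wilk(rnorm(2)), "3 <= n")
  # heavily lognormal raw data is rejected decisively
  raw <- 10^rnorm(200, sd = 1)
  expect_lt(shapiro_wilk(raw)$p_value, 0.01)
})

test_that("two-sample K-S matches enumeration and its stated examples", {
  x <- c(1, 2, 3)
  expect_equal(ks_two_sample(x, x)$D, 0)
  expect_equal(ks_two_sample(c(0, 1, 2), c(10, 11, 12))$D, 1)
  r <- ks_two_sample(c(1, 2), 1.5)
  expect_equal(r$D, 0.5)
  expect_equal(r$method, "exact")

  set.seed(5)
  for (i in 1:25) {
    a <- rnorm(sample(2:40, 1))
    b <- rnorm(sample(2:40, 1), mean = runif(1, -1, 1))
    got <- ks_two_sample(a, b)
    expect_equal(got$D, oracle_ks_D(a, b), tolerance = 1e-12)
    expect_true(got$D >= 0 && got$D <= 1)
    # symmetry
    expect_equal(got$D, ks_two_sample(b, a)$D)
    expect_equal(got$p_value, ks_two_sample(b, a)$p_value)
  }
})

test_that("bootstrap percentile is reproducible and degenerate-safe", {
  b1 <- bootstrap_percentile(c(4, 4, 4, 4), seed = 10, n_replicates = 200)
  expect_equal(b1$median, 4)
  expect_equal(unname(diff(b1$ci)), 0)
  expect_length(b1$replicates, 200)

  set.seed(6)
  v <- 10^rnorm(50)
  b2 <- bootstrap_percentile(v, seed = 99, n_replicates = 500)
  b3 <- bootstrap_percentile(v, seed = 99, n_replicates = 500)
  expect_identical(b2$replicates, b3$replicates)
  b4 <- bootstrap_percentile(v, seed = 100, n_replicates = 500)
  expect_false(identical(b2$replicates, b4$replicates))
  # median lies inside the central interval
  expect_true(b2$median >= b2$ci[1] && b2$median <= b2$ci[2])
})

test_that("bootstrap median approaches the sample percentile as replicates grow", {
  set.seed(7)
  v <- 10^rnorm(120)
  p5 <- empirical_percentile(v, 5)$value
  err <- sapply(c(100, 10000), function(reps) {
    abs(bootstrap_percentile(v, n_replicates = reps, seed = 8)$median - p5)
  })
  expect_lte(err[2], err[1] + 1e-9)
})

test_that("group summary reports n, percentiles and normality per group", {
  set.seed(9)
  vals <- c(10^rnorm(60, 0, 0.3), 10^rnorm(40, 1, 0.3))
  grp <- rep(c("lo", "hi"), c(60, 40))
  gs <- group_distribution_summary(vals, grp, bootstrap = TRUE,
                                   n_replicates = 300, seed = 2)
  expect_setequal(gs$group, c("lo", "hi"))
  expect_equal(gs$n[gs$group == "lo"], 60)
  expect_true(all(is.finite(gs$boot_median)))
  expect_true(all(gs$shapiro_W <= 1))
})
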
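test_that("choose_resampling maps rates to integer lattices", {
  rc <- choose_resampling(1000, 4, 10001)
  expect_equal(rc$m, 250L); expect_equal(rc$M, 41L)
  rc2 <- choose_resampling(10000, 4, 100001)
  expect_equal(rc2$m, 2500L); expect_equal(rc2$M, 41L)
  expect_equal(rc$f_r_realized, 4)
  expect_error(choose_resampling(1000, 600, 1000), "f_r")
  expect_error(choose_resampling(1000, 0, 1000), "f_r")
})

test_that("spline detrending preserves out-of-band content and its own range", {
  t <- seq(0, 4, by = 1 / 1000)
  # member of the coarse space passes through as pure trend
  member <- lsq_project(cos(2 * pi * 0.7 * t), 3, 250)
  r <- spline_detrend(member, 1000, 4)
  expect_lt(sum(r$residual^2), 1e-16 * sum(member^2))
  # a 50 Hz sinusoid (>= 10 x f_r) is altered by < 5% away from the ends
  s50 <- sin(2 * pi * 50 * t)
  r50 <- spline_detrend(s50, 1000, 4)
  interior <- seq(1000, length(t) - 1000)
  expect_lt(max(abs(r50$residual[interior] - s50[interior])), 0.05)
  # zero in, zero out
  z <- spline_detrend(rep(0, 2000), 1000, 4)
  expect_identical(z$trend, rep(0, 2000))
  expect_identical(z$residual, rep(0, 2000))
})

test_that("every method reconstructs the input additively", {
  withr::with_seed(4, {
    x <- cumsum(rnorm(4000)) / 30 + rnorm(4000)
    fits <- list(spline_detrend(x, 1000, 4),
                 spm_detrend(x, spm_lambda(1000, 4), 100),
                 ppf_detrend(x, 500, 2),
                 emd_detrend(x, 1000, 2))
    for (f in fits) {
      expect_lt(max(abs(f$trend + f$residual - x)), 1e-12)
      expect_length(f$trend, length(x))
    }
  })
})

test_that("spline detrending is linear", {
  withr::with_seed(6, {
    x <- rnorm(1500); y <- rnorm(1500)
    lhs <- spline_detrend(2 * x - 3 * y, 500, 4)$trend
    rhs <- 2 * spline_detrend(x, 500, 4)$trend - 3 * spline_detrend(y, 500, 4)$trend
    expect_equal(lhs, rhs, tolerance = 1e-10)
  })
})

test_that("smoothness priors limits: interpolation at small lambda, lines at large", {
  withr::with_seed(10, {
    x <- rnorm(400)
    lo <- spm_detrend(x, 1e-8, 10)
    expect_equal(lo$trend, x, tolerance = 1e-5)
    hi <- spm_detrend(x, 1e5, 10)
    for (b in 0:9) {
      idx <- b * 40 + 1:40
      line <- stats::lm.fit(cbind(1, 1:40), x[idx])$fitted.values
      expect_equal(hi$trend[idx], unname(line), tolerance = 1e-3)
    }
    cst <- spm_detrend(rep(3, 100), 5, 4)
    expect_equal(cst$trend, rep(3, 100), tolerance = 1e-10)
  })
})

test_that("piecewise polynomial fitting reproduces per-block OLS polynomials", {
  withr::with_seed(12, {
    t <- seq_len(600)
    quad <- 0.3 + 0.01 * t - 2e-5 * t^2
    f <- ppf_detrend(quad, 10, 2)
    expect_lt(max(abs(f$residual)), 1e-10)
    expect_equal(ppf_detrend(rep(1.5, 100), 5, 2)$residual, rep(0, 100),
                 tolerance = 1e-12)
    # generic least-squares oracle on one block
    x <- rnorm(120)
    f2 <- ppf_detrend(x, 4, 2)
    blk <- 31:60
    X <- stats::poly(seq_along(blk), 2, raw = TRUE)
    expect_equal(f2$trend[blk],
                 unname(stats::lm(x[blk] ~ X)$fitted.values),
                 tolerance = 1e-8)
    expect_error(ppf_detrend(rnorm(10), 5, 2), "subinterval")
  })
})

test_that("EMD handles degenerate inputs and separates a fast sinusoid", {
  mono <- emd_detrend(seq(0, 1, length.out = 64), 100, 2)
  expect_equal(mono$trend, seq(0, 1, length.out = 64))
  expect_equal(mono$residual, rep(0, 64))
  t <- seq(0, 2, by = 1 / 1000)
  s <- sin(2 * pi * 50 * t)
  f <- emd_detrend(s, 1000, 4)
  expect_lt(sum(f$trend^2), 0.01 * sum(s^2))
  # completeness of the decomposition
  withr::with_seed(13, {
    x <- cumsum(rnorm(2000)) / 20 + rnorm(2000)
    dec <- emd_decompose(x)
    recon <- rowSums(cbind(dec$imfs, dec$residue))
    expect_equal(recon, x, tolerance = 1e-8)
  })
})
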
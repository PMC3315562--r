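test_that("continuous B-spline matches box-convolution oracle and its basic shape", {
  expect_identical(continuous_bspline(0, 0), 1)
  expect_equal(continuous_bspline(0, 1), 1)
  expect_equal(continuous_bspline(c(-1, 1), 1), c(0, 0))
  expect_equal(continuous_bspline(0.5, 1), 0.5)
  # degree-3 value against numerical 4-fold convolution of the box
  expect_equal(continuous_bspline(0, 3), box_convolution_oracle(0, 3),
               tolerance = 1e-9)
  expect_equal(continuous_bspline(0.7, 3), box_convolution_oracle(0.7, 3),
               tolerance = 1e-8)
  # symmetry, non-negativity, compact support, unit integral
  x <- seq(-4, 4, by = 0.01)
  for (d in 0:4) {
    v <- continuous_bspline(x, d)
    expect_equal(v, rev(v))
    expect_true(all(v >= 0))
    expect_true(all(v[abs(x) > (d + 1) / 2] == 0))
    expect_equal(sum(v) * 0.01, 1, tolerance = 1e-3)
  }
  expect_error(continuous_bspline(0, -1), "non-negative")
})

test_that("discrete B-spline kernels are lattice samples with the stated invariants", {
  expect_equal(discrete_bspline(0, 3)$taps, c(1, 1, 1))
  expect_equal(discrete_bspline(1, 2)$taps, c(0.5, 1, 0.5))
  for (d in 0:4) for (m in 1:8) {
    k <- discrete_bspline(d, m)
    expect_equal(sum(k$taps), m, tolerance = 1e-12)
    expect_true(all(k$taps >= 0))
    expect_equal(k$taps, rev(k$taps))
    expect_identical(k$lags[k$center_index], 0L)
  }
  expect_error(discrete_bspline(3, 0), "positive integer")
})

test_that("convolution-property construction reproduces the sampled kernels", {
  # degree 0: the width-m moving average
  expect_equal(discrete_bspline_via_convolution(0, 5)$taps, rep(1, 5))
  expect_equal(discrete_bspline_via_convolution(1, 1)$taps,
               discrete_bspline(1, 1)$taps)
  for (d in 0:4) for (m in 1:8) {
    a <- discrete_bspline(d, m)
    b <- discrete_bspline_via_convolution(d, m)
    expect_equal(b$taps, a$taps, tolerance = 1e-10)
    expect_equal(b$lags, a$lags)
  }
})

test_that("direct transform is the exact inverse filter of the unit-step kernel", {
  expect_identical(direct_transform(c(3, 1, 4), 0), c(3, 1, 4))
  expect_identical(direct_transform(c(3, 1, 4), 1), c(3, 1, 4))
  # partition of unity: constant signals have constant coefficients
  expect_equal(direct_transform(rep(2.5, 30), 3), rep(2.5, 30),
               tolerance = 1e-12)
  expect_error(direct_transform(numeric(0), 3), "non-empty")
})

test_that("interpolation round trip at m = 1 is exact for degrees 2 and 3", {
  withr::with_seed(5, {
    g <- rnorm(50)
    for (d in 2:3) {
      expect_equal(indirect_transform(direct_transform(g, d), d, 1), g,
                   tolerance = 1e-10)
    }
  })
})

test_that("indirect transform upsamples coefficients through the expanded kernel", {
  # unit impulse coefficients reproduce the kernel taps
  ker <- discrete_bspline(3, 4)
  co <- c(0, 0, 0, 1, 0, 0, 0)
  out <- indirect_transform(co, 3, 4, out_length = 25)
  centre <- 3 * 4 + 1  # impulse at coefficient index 3 (0-based), position 12
  expect_equal(out[centre + ker$lags], ker$taps, tolerance = 1e-12)
  # partition of unity at scale m: interior samples of a constant expansion
  for (d in 0:3) for (m in c(1, 3, 5)) {
    out <- indirect_transform(rep(4.2, 12), d, m)
    interior <- seq(2 * m + 1, length(out) - 2 * m)
    expect_equal(out[interior], rep(4.2, length(interior)), tolerance = 1e-10)
  }
  expect_error(indirect_transform(1:4, 3, 2, out_length = 100), "inconsistent")
})
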
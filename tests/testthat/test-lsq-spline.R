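test_that("prefilter correlates with the expanded kernel under mirror extension", {
  g <- c(1, 2, 3, 4, 5, 6)
  pf <- prefilter(g, 0, 3)
  expect_equal(pf[2], 6)              # interior: 1 + 2 + 3
  expect_equal(pf[1], 5)              # mirror: g[2] + g[1] + g[2]
  expect_length(pf, length(g))
  # impulse reproduces the taps, constant scales by the tap sum m
  imp <- numeric(25); imp[13] <- 1
  ker <- discrete_bspline(3, 3)
  expect_equal(prefilter(imp, 3, 3)[13 - ker$lags], ker$taps, tolerance = 1e-12)
  expect_equal(prefilter(rep(2, 20), 2, 5), rep(10, 20), tolerance = 1e-10)
})

test_that("decimate keeps every m-th sample from the given phase", {
  expect_equal(decimate(c(1, 2, 3, 4, 5, 6), 3, 0), c(1, 4))
  expect_equal(decimate(c(1, 2, 3, 4, 5, 6), 3, 1), c(2, 5))
  expect_equal(decimate(4:9, 1, 0), 4:9)
  expect_error(decimate(1:6, 3, 3), "phase")
})

test_that("postfilter inverts the Gram operator", {
  # degree 0: Gram is m times the identity, so the pipeline yields block means
  expect_equal(postfilter(c(6, 15), 0, 3, n_signal = 6), c(2, 5))
  # forward Gram application after postfiltering returns the input
  withr::with_seed(8, {
    d <- rnorm(20)
    G <- lsq_gram_matrix(3, 5, n_signal = 5 * 19 + 1)
    expect_equal(as.numeric(G %*% postfilter(d, 3, 5)), d, tolerance = 1e-10)
  })
  # Gram matrices are symmetric positive definite
  for (d in c(0, 1, 3)) for (m in c(2, 5)) {
    G <- lsq_gram_matrix(d, m, 83)
    expect_equal(G, t(G))
    expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("three-step coefficients equal the brute-force normal equations", {
  expect_equal(lsq_coefficients(c(1, 2, 3, 4, 5, 6), 0, 3)$coeffs, c(2, 5))
  expect_equal(brute_force_lsq(c(1, 3, 5, 7), 0, 2), c(2, 6))
  withr::with_seed(3, {
    g <- rnorm(200)
    expect_equal(lsq_coefficients(g, 3, 5)$coeffs, brute_force_lsq(g, 3, 5),
                 tolerance = 1e-8)
  })
  # a single basis function has a unit impulse coefficient vector
  n <- 61; m <- 6
  col <- splinetrend:::folded_basis_column(3, m, n, 5)
  sig <- numeric(n); sig[col$idx] <- col$val
  cf <- brute_force_lsq(sig, 3, m)
  expect_equal(cf[5], 1, tolerance = 1e-8)
  expect_lt(max(abs(cf[-5])), 1e-8)
  expect_error(lsq_coefficients(c(1, 2), 3, 5), "knot interval")
})

test_that("projection is idempotent, energy-contracting and orthogonal", {
  withr::with_seed(9, {
    g <- rnorm(300)
    p1 <- lsq_project(g, 3, 7)
    expect_equal(lsq_project(p1, 3, 7), p1, tolerance = 1e-10)
    expect_lte(sum(p1^2), sum(g^2))
    # residual orthogonal to every folded basis function
    res <- g - p1
    M <- splinetrend:::knot_count(300L, 7L)
    for (k in seq_len(M)) {
      col <- splinetrend:::folded_basis_column(3, 7, 300, k)
      expect_lt(abs(sum(res[col$idx] * col$val)), 1e-8 * sqrt(sum(g^2)))
    }
    # members of the coarse space are reproduced
    cf <- rnorm(M)
    member <- splinetrend:::lsq_reconstruct(
      structure(list(degree = 3L, m = 7L, boundary = "mirror", knots = M,
                     coeffs = cf, n_signal = 300L), class = "lsq_model"))
    expect_lt(sum((lsq_project(member, 3, 7) - member)^2),
              1e-16 * sum(member^2))
    # energy contraction across random draws
    for (s in 1:5) {
      x <- rnorm(120)
      expect_lte(sum(lsq_project(x, 1, 4)^2), sum(x^2))
    }
  })
})

test_that("degree-0 projection is exact block averaging", {
  expect_equal(lsq_project(c(1, 2, 3, 4, 5, 6), 0, 3), c(2, 2, 2, 5, 5, 5))
  withr::with_seed(2, {
    g <- rnorm(40)
    pr <- lsq_project(g, 0, 5)
    means <- tapply(g, rep(1:8, each = 5), mean)
    expect_equal(pr, rep(as.numeric(means), each = 5), tolerance = 1e-12)
  })
})

test_that("filtering-path and oracle coefficients agree across degrees and factors", {
  withr::with_seed(17, {
    for (d in c(0, 1, 3)) for (m in c(2, 3, 5, 10)) {
      g <- rnorm(600)
      cf <- lsq_coefficients(g, d, m)$coeffs
      cb <- brute_force_lsq(g, d, m)
      interior <- seq(d + 2, length(cf) - d - 1)
      expect_lt(max(abs(cf[interior] - cb[interior])), 1e-8)
    }
  })
})

test_that("projection error decays at the Strang-Fix rate in the knot rate", {
  t <- seq(0, 4, by = 1 / 1000)
  g <- sin(2 * pi * t)
  mid <- round(length(t) / 2) + (-500:500)
  ms <- c(25, 50, 100, 200)
  for (d in c(1, 3)) {
    errs <- vapply(ms, function(m)
      sqrt(mean((lsq_project(g, d, m) - g)[mid]^2)), numeric(1))
    slope_vs_fr <- -unname(stats::coef(stats::lm(log(errs) ~ log(ms)))[2])
    expect_lt(abs(slope_vs_fr - (-(d + 1))), 0.4)
  }
})
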
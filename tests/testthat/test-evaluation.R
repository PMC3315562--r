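test_that("error metrics follow their definitions", {
  expect_equal(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse(c(1, 2, 3), c(1, 2, 3) + 2), 4)
  expect_equal(mse(c(1, 2, 3), c(2, 2, 2)), 2 / 3)
  expect_equal(mse(c(1, 2), c(2, 2)), mse(c(2, 2), c(1, 2)))
  expect_error(mse(1:3, 1:4), "equal length")
  x <- c(0.5, -1, 2)
  expect_equal(nmse(x, x), 0)
  expect_equal(nmse(x, rep(0, 3)), 1)
  expect_equal(nmse(x, 2 * x), 1)
  expect_error(nmse(rep(0, 3), 1:3), "positive energy")
})

test_that("rank tests satisfy their contracts", {
  expect_gte(mann_whitney(c(1, 2, 3), c(1, 2, 3)), 0.99)
  withr::with_seed(40, {
    a <- rnorm(30); b <- rnorm(30, mean = 5)
    expect_lt(mann_whitney(a, b), 0.001)
    # invariance under a common monotone transformation
    expect_equal(mann_whitney(a, b), mann_whitney(exp(a), exp(b)))
  })
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
  expect_equal(kruskal_wallis(list(c(1, 1), c(1, 1, 1))), 1)
  expect_error(kruskal_wallis(list(1:3)), "two samples")
  withr::with_seed(41, {
    a <- rnorm(25); b <- rnorm(25)
    kw <- kruskal_wallis(list(a, b))
    mw <- mann_whitney(a, b)
    expect_equal(kw < 0.05, mw < 0.05)
  })
})

test_that("resampling-frequency sweep selects above the trend band and is reproducible", {
  cfg <- small_cfg(snr_db = 20)
  sw1 <- fr_sweep_experiment(cfg, fr_grid = seq(1, 10, by = 1),
                             snr_grid_db = c(10, 20), n_realizations = 3,
                             master_seed = 5)
  sw2 <- fr_sweep_experiment(cfg, fr_grid = seq(1, 10, by = 1),
                             snr_grid_db = c(10, 20), n_realizations = 3,
                             master_seed = 5)
  expect_identical(sw1$per_realization, sw2$per_realization)
  # with a 0-2 Hz trend band the selected f_r exceeds the band edge
  high <- sw1$per_realization$best_fr > 2
  expect_gte(mean(high), 0.9)
  expect_true(all(sw1$kw$p_value >= 0 & sw1$kw$p_value <= 1))
  # degenerate single-group case
  deg <- fr_sweep_experiment(cfg, fr_grid = c(2, 4), snr_grid_db = 10,
                             n_realizations = 1, master_seed = 1)
  expect_equal(deg$kw$p_value, c(1, 1))
})

test_that("method comparison is reproducible and spline NMSE improves with SNR", {
  cfg <- small_cfg()
  mc1 <- method_comparison_experiment(cfg, methods = "spline",
                                      snr_grid_db = c(0, 30),
                                      n_realizations = 6,
                                      condition = "fixed_trend_new_noise",
                                      master_seed = 9)
  mc2 <- method_comparison_experiment(cfg, methods = "spline",
                                      snr_grid_db = c(0, 30),
                                      n_realizations = 6,
                                      condition = "fixed_trend_new_noise",
                                      master_seed = 9)
  expect_identical(mc1$nmse_curves, mc2$nmse_curves)
  expect_true(all(mc1$nmse_curves$mean_nmse >= 0))
  lo <- mc1$nmse_curves$mean_nmse[mc1$nmse_curves$snr_db == 0]
  hi <- mc1$nmse_curves$mean_nmse[mc1$nmse_curves$snr_db == 30]
  expect_true(all(hi <= lo))
  # frozen-components condition redraws only the noise
  mcf <- method_comparison_experiment(cfg, methods = "spline",
                                      snr_grid_db = 10, n_realizations = 3,
                                      condition = "fixed_trend_new_noise",
                                      master_seed = 9)
  expect_equal(nrow(mcf$per_realization), 6)
  expect_gt(stats::sd(mcf$per_realization$nmse), 0)
})
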
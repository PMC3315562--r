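test_that("variance segmenter finds events and keeps a low false-alarm rate", {
  expect_equal(nrow(segment_swallows(rep(0, 5000), 1000)), 0)
  expect_error(segment_swallows(rnorm(100), 1000, window_s = 0.5), "longer")
  # false-alarm calibration: white noise, default settings
  spurious <- vapply(1:20, function(s) {
    x <- withr::with_seed(200 + s, rnorm(40000))
    nrow(segment_swallows(x, 1000))
  }, numeric(1))
  expect_lte(mean(spurious), 1)
  # trendless synthetic recordings at 20 dB: at least 4 of 5 events found
  cfg <- synthetic_config(snr_db = 20, trend_amp_range_ap = c(0, 0),
                          trend_amp_range_si = c(0, 0))
  hits <- vapply(1:5, function(s) {
    rec <- gen_recording(cfg, seed = 300 + s)
    det <- segment_swallows(rec$data$ap, cfg$f_s)
    score_segmentation(rec$events, det)$css
  }, numeric(1))
  expect_true(all(hits >= 4))
  # returned intervals are disjoint and sorted
  rec <- gen_recording(cfg, seed = 311)
  iv <- segment_swallows(rec$data$ap, cfg$f_s)
  expect_true(all(diff(iv$start_s) > 0))
  expect_true(all(utils::head(iv$end_s, -1) <= utils::tail(iv$start_s, -1)))
})

test_that("segmentation scoring applies the 90% capture rule and conserves counts", {
  ev <- tibble::tibble(start_s = c(0, 5), end_s = c(1, 6))
  exact <- score_segmentation(ev, ev)
  expect_equal(tidy(exact), tibble::tibble(tns = 2L, css = 2L, nfp = 0L, nfn = 0L))
  none <- score_segmentation(ev, ev[0, ])
  expect_equal(none$css, 0L); expect_equal(none$nfn, 2L); expect_equal(none$nfp, 0L)
  # 85% capture is not enough under the strict > 90% rule
  one <- tibble::tibble(start_s = 0, end_s = 1)
  det85 <- tibble::tibble(start_s = 0.15, end_s = 1)
  sc <- score_segmentation(one, det85)
  expect_equal(sc$css, 0L); expect_equal(sc$nfn, 1L)
  # 95% capture passes
  sc95 <- score_segmentation(one, tibble::tibble(start_s = 0.05, end_s = 1))
  expect_equal(sc95$css, 1L)
  # non-overlapping detections are false positives; css + nfn = tns always
  withr::with_seed(50, {
    for (r in 1:10) {
      tr <- tibble::tibble(start_s = c(1, 4, 8), end_s = c(2, 5, 9))
      k <- sample(0:4, 1)
      det <- if (k == 0) tr[0, ] else {
        s0 <- sort(runif(k, 0, 9)) + (0:(k - 1)) * 10
        tibble::tibble(start_s = s0, end_s = s0 + 0.5)
      }
      s <- score_segmentation(tr, det)
      expect_identical(s$css + s$nfn, s$tns)
      expect_gte(s$nfp, 0L)
    }
  })
  bad <- tibble::tibble(start_s = c(0, 0.5), end_s = c(1, 1.5))
  expect_error(score_segmentation(bad, ev), "overlapping")
})

test_that("DFA recovers the classical benchmark exponents", {
  withr::with_seed(60, {
    white <- dfa_alpha(rnorm(3e4))
    expect_lt(abs(white$alpha - 0.5), 0.07)
    walk <- dfa_alpha(cumsum(rnorm(3e4)))
    expect_lt(abs(walk$alpha - 1.5), 0.12)
    expect_true(all(white$fluctuation > 0))
  })
  expect_error(dfa_alpha(rnorm(100), scales = c(2, 10)), "detrend_order")
  expect_error(dfa_alpha(rnorm(100), scales = c(10, 60)), "length/4")
})

test_that("before/after study is neutral on trendless recordings", {
  cfg <- small_cfg(snr_db = 20, trend_amp_range_ap = c(0, 0),
                   trend_amp_range_si = c(0, 0))
  recs <- lapply(1:6, function(s) gen_recording(cfg, seed = 400 + s))
  ba <- before_after_study(recs)
  expect_identical(sort(unique(ba$per_recording$phase)), c("after", "before"))
  expect_true(all(ba$per_recording$css + ba$per_recording$nfn ==
                    ba$per_recording$tns))
  # detrending a trendless batch leaves the segmentation scores unchanged
  pr <- ba$per_recording
  for (col in c("css", "nfp", "nfn")) {
    p <- mann_whitney(pr[[col]][pr$phase == "before"],
                      pr[[col]][pr$phase == "after"])
    expect_gt(p, 0.05)
  }
  expect_true(all(is.finite(ba$alpha_tests$p_value)))
})
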
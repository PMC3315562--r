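# Error metrics, Monte-Carlo experiments (resampling-frequency sweep and
# four-method comparison), and rank-based statistical tests.

#' Mean square error between two sequences
#'
#' @param true_trend,est_trend Equal-length numeric vectors.
#' @return Non-negative scalar, the mean of squared sample-wise differences.
#' @export
mse <- function(true_trend, est_trend) {
  check_signal(true_trend, "true_trend")
  check_signal(est_trend, "est_trend")
  abort_if(length(true_trend) != length(est_trend),
           "`true_trend` and `est_trend` must have equal length.")
  mean((true_trend - est_trend)^2)
}

#' Normalised mean square error
#'
#' MSE divided by the mean power of the true sequence, so that the
#' all-zero estimator scores exactly 1.
#'
#' @inheritParams mse
#' @return Non-negative scalar.
#' @export
nmse <- function(true_trend, est_trend) {
  p <- mean(true_trend^2)
  abort_if(!is.finite(p) || p <= 0, "`true_trend` must have positive energy.")
  mse(true_trend, est_trend) / p
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided Wilcoxon rank-sum p-value (normal approximation with
#' continuity correction; rank-based, hence invariant under common
#' monotone transformations).  The 5% significance convention is applied
#' by callers, not here.  Identical pooled samples return p = 1.
#'
#' @param a,b Non-empty numeric samples.
#' @return p-value in `[0, 1]`.
#' @export
mann_whitney <- function(a, b) {
  check_signal(a, "a"); check_signal(b, "b")
  if (length(unique(c(a, b))) == 1L) return(1)
  as.numeric(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis p-value.  Degenerate cases follow the
#' contract: fewer than two usable groups, or identical pooled values,
#' give p = 1.
#'
#' @param groups List of non-empty numeric samples (>= 2 groups).
#' @return p-value in `[0, 1]`.
#' @export
kruskal_wallis <- function(groups) {
  abort_if(!is.list(groups) || length(groups) < 2L,
           "`groups` must be a list of at least two samples.")
  for (g in groups) check_signal(g, "groups[[i]]")
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1L) return(1)
  as.numeric(stats::kruskal.test(groups)$p.value)
}

#' Resampling-frequency sweep experiment
#'
#' Monte-Carlo analogue of the protocol that selects the optimal coarse
#' resampling frequency: for each SNR level and realization of the
#' synthetic recording, find the `f_r` in `fr_grid` minimising the
#' trend-estimation MSE on each axis; report the per-SNR minimiser
#' distributions, their means, and the Kruskal-Wallis p-value across SNR
#' groups per axis (testing whether the optimal `f_r` depends on the noise
#' level).
#'
#' @param cfg A [synthetic_config()]; its `snr_db` and `seed` fields are
#'   overridden by the grid and `master_seed`.
#' @param fr_grid Candidate resampling frequencies (Hz), default 0.5-10 Hz
#'   in 0.25 Hz steps.
#' @param snr_grid_db SNR grid in dB, default `seq(0, 30, by = 5)`.
#' @param n_realizations Realizations per SNR level (default 20; the
#'   full-scale protocol uses 100).
#' @param degree Spline degree.
#' @param master_seed Integer seed governing all randomness.
#' @return Object of class `fr_sweep` with `per_realization` (tibble:
#'   `snr_db`, `realization`, `axis`, `best_fr`, `best_mse`), `summary`,
#'   `kw` (per-axis Kruskal-Wallis p-values), `fr_grid`, `config`.
#' @export
fr_sweep_experiment <- function(cfg = synthetic_config(),
                                fr_grid = seq(0.5, 10, by = 0.25),
                                snr_grid_db = seq(0, 30, by = 5),
                                n_realizations = 20, degree = 3,
                                master_seed = 1L) {
  cfg <- validate_synthetic_config(cfg)
  abort_if(any(fr_grid <= 0 | fr_grid >= cfg$f_s / 2),
           "`fr_grid` must lie within (0, f_s / 2).")
  abort_if(n_realizations < 1, "`n_realizations` must be >= 1.")
  withr::with_seed(as.integer(master_seed), {
    rows <- vector("list", length(snr_grid_db) * n_realizations)
    ri <- 0L
    for (snr in snr_grid_db) {
      cfg_r <- cfg; cfg_r$snr_db <- snr; cfg_r$seed <- NULL
      for (r in seq_len(n_realizations)) {
        rec <- gen_recording(cfg_r)
        ri <- ri + 1L
        rows[[ri]] <- purrr::map_dfr(c("ap", "si"), function(axis) {
          sig <- rec$data[[axis]]
          truth <- rec$truth[[axis]]$trend
          errs <- vapply(fr_grid, function(fr) {
            mse(truth, spline_detrend(sig, cfg$f_s, fr, degree)$trend)
          }, numeric(1))
          best <- which.min(errs)
          tibble::tibble(snr_db = snr, realization = r, axis = axis,
                         best_fr = fr_grid[best], best_mse = errs[best])
        })
      }
    }
    per_real <- dplyr::bind_rows(rows)
  })
  summary <- per_real |>
    dplyr::group_by(.data$axis, .data$snr_db) |>
    dplyr::summarise(mean_fr = mean(.data$best_fr),
                     sd_fr = stats::sd(.data$best_fr),
                     n = dplyr::n(), .groups = "drop")
  kw <- per_real |>
    dplyr::group_by(.data$axis) |>
    dplyr::summarise(p_value = if (length(unique(.data$snr_db)) < 2L ||
                                   dplyr::n() < 2L) 1 else
      kruskal_wallis(split(.data$best_fr, .data$snr_db)),
      mean_fr = mean(.data$best_fr), .groups = "drop")
  structure(list(per_realization = per_real, summary = summary, kw = kw,
                 fr_grid = fr_grid, snr_grid_db = snr_grid_db,
                 n_realizations = n_realizations, config = cfg,
                 master_seed = master_seed),
            class = "fr_sweep")
}

#' @export
print.fr_sweep <- function(x, ...) {
  cat(sprintf("<fr_sweep> %d SNR levels x %d realizations, f_r grid %g-%g Hz\n",
              length(x$snr_grid_db), x$n_realizations,
              min(x$fr_grid), max(x$fr_grid)))
  print(x$kw)
  invisible(x)
}

# Run one detrender on one axis; shared by the comparison experiment.
run_method <- function(method, signal, f_s, f_r, degree = 3,
                       spm_subintervals = 1000, ppf_subintervals = 5000,
                       ppf_degree = 2) {
  switch(method,
         spline = spline_detrend(signal, f_s, f_r, degree),
         spm = spm_detrend(signal, spm_lambda(f_s, f_r), spm_subintervals),
         ppf = ppf_detrend(signal, ppf_subintervals, ppf_degree),
         emd = emd_detrend(signal, f_s, f_r / 2),
         rlang::abort(sprintf("unknown method '%s'", method),
                      class = "splinetrend_error"))
}

#' Four-method detrending comparison experiment
#'
#' Monte-Carlo comparison of the spline detrender against the smoothness
#' priors, piecewise polynomial and (optionally) EMD baselines: per method,
#' axis and SNR level, the mean and standard error of the trend-estimation
#' NMSE over `n_realizations` synthetic recordings.  Condition
#' `"all_random"` redraws trend and swallow components with every
#' realization; `"fixed_trend_new_noise"` freezes them at the master seed
#' and redraws only the noise.
#'
#' @param cfg A [synthetic_config()].
#' @param methods Subset of `c("spline", "spm", "ppf", "emd")`.
#' @param snr_grid_db SNR grid in dB (default `seq(0, 30, by = 10)`; the
#'   full-scale protocol uses 0-30 dB in 1 dB steps).
#' @param n_realizations Realizations per SNR (default 50; full scale 500).
#' @param condition `"all_random"` or `"fixed_trend_new_noise"`.
#' @param fr_ap,fr_si Spline resampling frequency per axis (Hz).
#' @param degree Spline degree.
#' @param spm_subintervals,ppf_subintervals,ppf_degree Baseline settings.
#' @param master_seed Integer seed governing all randomness.
#' @return Object of class `method_comparison` with `nmse_curves` (tibble:
#'   `method`, `axis`, `snr_db`, `mean_nmse`, `se_nmse`, `n`), the
#'   per-realization table, and the experiment settings.
#' @export
method_comparison_experiment <- function(cfg = synthetic_config(),
                                         methods = c("spline", "spm", "ppf"),
                                         snr_grid_db = seq(0, 30, by = 10),
                                         n_realizations = 50,
                                         condition = c("all_random",
                                                       "fixed_trend_new_noise"),
                                         fr_ap = 4, fr_si = 4, degree = 3,
                                         spm_subintervals = 1000,
                                         ppf_subintervals = 5000,
                                         ppf_degree = 2,
                                         master_seed = 1L) {
  cfg <- validate_synthetic_config(cfg)
  condition <- match.arg(condition)
  methods <- match.arg(methods, c("spline", "spm", "ppf", "emd"),
                       several.ok = TRUE)
  fr <- c(ap = fr_ap, si = fr_si)
  rows <- list()
  withr::with_seed(as.integer(master_seed), {
    if (condition == "fixed_trend_new_noise") {
      cfg_f <- cfg; cfg_f$seed <- NULL; cfg_f$snr_db <- Inf
      frozen <- gen_recording(cfg_f)
    }
    for (snr in snr_grid_db) {
      for (r in seq_len(n_realizations)) {
        if (condition == "all_random") {
          cfg_r <- cfg; cfg_r$snr_db <- snr; cfg_r$seed <- NULL
          rec <- gen_recording(cfg_r)
          sigs <- list(ap = rec$data$ap, si = rec$data$si)
          trends <- list(ap = rec$truth$ap$trend, si = rec$truth$si$trend)
        } else {
          sigs <- list(); trends <- list()
          for (axis in c("ap", "si")) {
            clean <- frozen$truth[[axis]]$trend + frozen$truth[[axis]]$swallow
            sigs[[axis]] <- add_noise(clean, snr)$noisy
            trends[[axis]] <- frozen$truth[[axis]]$trend
          }
        }
        for (axis in c("ap", "si")) {
          for (method in methods) {
            est <- run_method(method, sigs[[axis]], cfg$f_s, fr[[axis]],
                              degree, spm_subintervals, ppf_subintervals,
                              ppf_degree)
            rows[[length(rows) + 1L]] <-
              tibble::tibble(method = method, axis = axis, snr_db = snr,
                             realization = r,
                             nmse = nmse(trends[[axis]], est$trend))
          }
        }
      }
    }
  })
  per_real <- dplyr::bind_rows(rows)
  curves <- per_real |>
    dplyr::group_by(.data$method, .data$axis, .data$snr_db) |>
    dplyr::summarise(mean_nmse = mean(.data$nmse),
                     se_nmse = stats::sd(.data$nmse) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  structure(list(nmse_curves = curves, per_realization = per_real,
                 condition = condition, snr_grid_db = snr_grid_db,
                 methods = methods, n_realizations = n_realizations,
                 config = cfg, master_seed = master_seed),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison> condition '%s', methods %s, %d realizations per SNR\n",
              x$condition, paste(x$methods, collapse = "/"),
              x$n_realizations))
  print(x$nmse_curves, n = 20)
  invisible(x)
}
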
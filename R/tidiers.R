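# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method tidy detrend_result
#' @export
tidy.detrend_result <- function(x, ...) {
  tibble::tibble(sample = seq_len(x$n),
                 signal = x$trend + x$residual,
                 trend = x$trend, detrended = x$residual)
}

#' @method glance detrend_result
#' @export
glance.detrend_result <- function(x, ...) {
  sig <- x$trend + x$residual
  tibble::tibble(method = x$method, n = x$n,
                 trend_energy_fraction = sum(x$trend^2) / max(sum(sig^2),
                                                              .Machine$double.xmin))
}

#' @method tidy lsq_model
#' @export
tidy.lsq_model <- function(x, ...) {
  tibble::tibble(knot = seq_len(x$knots) - 1L, coefficient = x$coeffs)
}

#' @method glance lsq_model
#' @export
glance.lsq_model <- function(x, ...) {
  tibble::tibble(degree = x$degree, m = x$m, knots = x$knots,
                 n_signal = x$n_signal, boundary = x$boundary)
}

#' @method tidy dfa_result
#' @export
tidy.dfa_result <- function(x, ...) {
  tibble::tibble(scale = x$scales, fluctuation = x$fluctuation)
}

#' @method glance dfa_result
#' @export
glance.dfa_result <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, min_scale = x$fit_range[1],
                 max_scale = x$fit_range[2], n_scales = length(x$scales))
}

#' @method tidy segmentation_score
#' @export
tidy.segmentation_score <- function(x, ...) {
  tibble::tibble(tns = x$tns, css = x$css, nfp = x$nfp, nfn = x$nfn)
}

#' @method tidy fr_sweep
#' @export
tidy.fr_sweep <- function(x, ...) x$per_realization

#' @method glance fr_sweep
#' @export
glance.fr_sweep <- function(x, ...) {
  tidyr::pivot_wider(x$kw, names_from = "axis",
                     values_from = c("p_value", "mean_fr"))
}

#' @method tidy method_comparison
#' @export
tidy.method_comparison <- function(x, ...) x$nmse_curves

#' @method glance method_comparison
#' @export
glance.method_comparison <- function(x, ...) {
  tibble::tibble(condition = x$condition,
                 methods = paste(x$methods, collapse = ","),
                 n_realizations = x$n_realizations,
                 n_snr_levels = length(x$snr_grid_db))
}

#' @method tidy before_after
#' @export
tidy.before_after <- function(x, ...) x$per_recording

#' @method glance before_after
#' @export
glance.before_after <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$totals, names_from = "phase",
                             values_from = c("tns", "css", "nfp", "nfn"))
  dplyr::bind_cols(wide,
                   tibble::tibble(
                     p_alpha_ap = x$alpha_tests$p_value[x$alpha_tests$axis == "ap"],
                     p_alpha_si = x$alpha_tests$p_value[x$alpha_tests$axis == "si"]))
}

#' @method tidy detrended_recording
#' @export
tidy.detrended_recording <- function(x, ...) {
  x$data |>
    tidyr::pivot_longer(-"time", names_to = "series", values_to = "value") |>
    dplyr::mutate(
      axis = ifelse(grepl("si$", .data$series), "si", "ap"),
      component = dplyr::case_when(
        grepl("^trend", .data$series) ~ "trend",
        grepl("^detrended", .data$series) ~ "detrended",
        TRUE ~ "signal")) |>
    dplyr::select("time", "axis", "component", "value")
}

#' Plot a detrended recording
#'
#' Raw signal, estimated head-motion trend and detrended signal per axis.
#' @param object A `detrended_recording`.
#' @param ... Unused.
#' @method autoplot detrended_recording
#' @export
autoplot.detrended_recording <- function(object, ...) {
  df <- tidy.detrended_recording(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$axis)) +
    ggplot2::labs(x = "time (s)", y = "acceleration (a.u.)",
                  colour = NULL,
                  title = sprintf("Detrending (%s)", object$method)) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic recording and its ground truth
#' @param object A `swacc_recording`.
#' @param ... Unused.
#' @method autoplot swacc_recording
#' @export
autoplot.swacc_recording <- function(object, ...) {
  df <- object$data |>
    tidyr::pivot_longer(c("ap", "si"), names_to = "axis", values_to = "value")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$axis)) +
    ggplot2::labs(x = "time (s)", y = "acceleration (a.u.)") +
    ggplot2::theme_minimal()
  if (!is.null(object$events) && nrow(object$events))
    p <- p + ggplot2::geom_rect(
      data = object$events,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "orange")
  p
}

#' Plot NMSE curves of the method comparison
#' @param object A `method_comparison`.
#' @param ... Unused.
#' @method autoplot method_comparison
#' @export
autoplot.method_comparison <- function(object, ...) {
  ggplot2::ggplot(object$nmse_curves,
                  ggplot2::aes(x = .data$snr_db, y = .data$mean_nmse,
                               colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$axis)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "SNR (dB)", y = "mean NMSE",
                  title = sprintf("Trend-estimation NMSE (%s)",
                                  object$condition)) +
    ggplot2::theme_minimal()
}

#' Plot the optimal resampling-frequency distributions
#' @param object An `fr_sweep`.
#' @param ... Unused.
#' @method autoplot fr_sweep
#' @export
autoplot.fr_sweep <- function(object, ...) {
  ggplot2::ggplot(object$per_realization,
                  ggplot2::aes(x = factor(.data$snr_db), y = .data$best_fr)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$axis)) +
    ggplot2::labs(x = "SNR (dB)", y = "best f_r (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot the DFA fluctuation function
#' @param object A `dfa_result`.
#' @param ... Unused.
#' @method autoplot dfa_result
#' @export
autoplot.dfa_result <- function(object, ...) {
  ggplot2::ggplot(tidy.dfa_result(object),
                  ggplot2::aes(x = .data$scale, y = .data$fluctuation)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "window size n", y = "F(n)",
                  title = sprintf("DFA, alpha = %.3f", object$alpha)) +
    ggplot2::theme_minimal()
}
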
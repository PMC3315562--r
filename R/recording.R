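# Recording-level pipeline entry points: tibble in, tibble-backed result
# out, so calls chain with the pipe.

#' Detrend both axes of a recording
#'
#' Applies one of the detrending methods to the `ap` and `si` channels of
#' a recording and returns a tibble-backed result: the original channels,
#' the estimated head-motion trends and the detrended channels.
#'
#' @param recording A `swacc_recording` or a data frame with `ap`, `si`
#'   (and optionally `time`) columns.
#' @param method One of `"spline"`, `"spm"`, `"ppf"`, `"emd"`.
#' @param f_s Sampling rate (Hz); taken from the recording when absent.
#' @param fr_ap,fr_si Resampling (knot) frequency per axis (Hz), used by
#'   the spline, SPM (cutoff-matched lambda) and EMD (cutoff `fr/2`)
#'   methods.
#' @param degree Spline degree.
#' @param spm_subintervals,ppf_subintervals,ppf_degree Baseline settings.
#' @return Object of class `detrended_recording`: list with `data`
#'   (tibble: `time`, `ap`, `si`, `trend_ap`, `trend_si`, `detrended_ap`,
#'   `detrended_si`), `method`, `params`, `f_s`.
#' @examples
#' rec <- gen_recording(synthetic_config(duration_s = 4, seed = 1))
#' det <- detrend_recording(rec, method = "spline")
#' head(det$data)
#' @export
detrend_recording <- function(recording, method = c("spline", "spm", "ppf", "emd"),
                              f_s = NULL, fr_ap = 4, fr_si = 4, degree = 3,
                              spm_subintervals = 1000, ppf_subintervals = 5000,
                              ppf_degree = 2) {
  method <- match.arg(method)
  if (inherits(recording, "swacc_recording")) {
    data <- recording$data
    if (is.null(f_s)) f_s <- recording$f_s
  } else {
    abort_if(!is.data.frame(recording) ||
               !all(c("ap", "si") %in% names(recording)),
             "`recording` must have 'ap' and 'si' columns.")
    data <- tibble::as_tibble(recording)
    abort_if(is.null(f_s), "`f_s` is required for plain data frames.")
    if (!"time" %in% names(data))
      data$time <- (seq_len(nrow(data)) - 1L) / f_s
  }
  fr <- c(ap = fr_ap, si = fr_si)
  res <- purrr::map(c(ap = "ap", si = "si"), function(axis) {
    run_method(method, data[[axis]], f_s, fr[[axis]], degree,
               spm_subintervals, ppf_subintervals, ppf_degree)
  })
  out <- tibble::tibble(
    time = data$time, ap = data$ap, si = data$si,
    trend_ap = res$ap$trend, trend_si = res$si$trend,
    detrended_ap = res$ap$residual, detrended_si = res$si$residual)
  structure(list(data = out, method = method,
                 params = list(ap = res$ap$params, si = res$si$params),
                 f_s = f_s),
            class = "detrended_recording")
}

#' @export
print.detrended_recording <- function(x, ...) {
  cat(sprintf("<detrended_recording> method '%s', %d samples at %g Hz\n",
              x$method, nrow(x$data), x$f_s))
  print(x$data, n = 5)
  invisible(x)
}
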
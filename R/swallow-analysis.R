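# Downstream analyses used to judge detrending: variance-threshold swallow
# segmentation with CSS/NFP/NFN scoring against ground-truth events, and
# detrended fluctuation analysis of the scaling exponent.

#' Segment swallow events by sliding-window variance
#'
#' A transparent variance-threshold segmenter: the sliding-window variance
#' track (window `window_s`) is thresholded at its median plus
#' `threshold_k` times its median absolute deviation; runs of
#' supra-threshold windows are merged into events and events shorter than
#' `min_event_s` are dropped.  Returns disjoint, sorted intervals in
#' seconds.
#'
#' @param signal Numeric vector (one axis).
#' @param f_s Sampling frequency (Hz).
#' @param window_s Variance window length in seconds (default 0.2 s).
#' @param threshold_k Robust threshold multiplier (default 6).
#' @param min_event_s Minimum event duration in seconds (default 0.3 s).
#' @return Tibble with columns `start_s`, `end_s`.
#' @export
segment_swallows <- function(signal, f_s, window_s = 0.2, threshold_k = 6,
                             min_event_s = 0.3) {
  check_signal(signal)
  check_scalar_number(f_s, "f_s", min = .Machine$double.eps)
  check_scalar_number(threshold_k, "threshold_k", min = 0)
  w <- as.integer(round(window_s * f_s))
  abort_if(w < 4L, "`window_s * f_s` must be at least 4 samples.")
  n <- length(signal)
  abort_if(w > n, "variance window is longer than the signal.")
  if (all(signal == 0))
    return(tibble::tibble(start_s = numeric(0), end_s = numeric(0)))
  # rolling variance over windows [i, i + w - 1] via cumulative sums
  c1 <- cumsum(c(0, signal))
  c2 <- cumsum(c(0, signal^2))
  idx <- seq_len(n - w + 1L)
  s1 <- c1[idx + w] - c1[idx]
  s2 <- c2[idx + w] - c2[idx]
  v <- (s2 - s1^2 / w) / (w - 1L)
  thr <- stats::median(v) + threshold_k * stats::mad(v)
  marked <- v > thr
  if (!any(marked))
    return(tibble::tibble(start_s = numeric(0), end_s = numeric(0)))
  r <- rle(marked)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  on <- which(r$values)
  # window i covers samples i .. i + w - 1; report the covered extent and
  # merge marks whose extents overlap or touch
  start_s <- (starts_i[on] - 1L) / f_s
  end_s <- (ends_i[on] - 1L + w) / f_s
  merged_s <- start_s[1]; merged_e <- end_s[1]
  if (length(start_s) > 1L) {
    for (j in 2:length(start_s)) {
      last <- length(merged_e)
      if (start_s[j] <= merged_e[last]) {
        merged_e[last] <- max(merged_e[last], end_s[j])
      } else {
        merged_s <- c(merged_s, start_s[j]); merged_e <- c(merged_e, end_s[j])
      }
    }
  }
  keep <- (merged_e - merged_s) >= min_event_s
  tibble::tibble(start_s = merged_s[keep], end_s = merged_e[keep])
}

check_intervals <- function(x, name) {
  abort_if(!is.data.frame(x) || !all(c("start_s", "end_s") %in% names(x)),
           sprintf("`%s` must be a data frame with start_s and end_s.", name))
  if (nrow(x) == 0L) return(x[order(x$start_s), , drop = FALSE])
  abort_if(any(x$end_s < x$start_s),
           sprintf("`%s` has intervals with end before start.", name))
  x <- x[order(x$start_s), , drop = FALSE]
  abort_if(any(utils::head(x$end_s, -1) > utils::tail(x$start_s, -1) +
                 sqrt(.Machine$double.eps)),
           sprintf("`%s` contains overlapping intervals.", name))
  x
}

overlap_len <- function(a0, a1, b0, b1) pmax(0, pmin(a1, b1) - pmax(a0, b0))

#' Score a segmentation against ground-truth events
#'
#' Each detected interval is assigned to the true event it overlaps most
#' (greedy matching).  A true event counts as correctly segmented (CSS)
#' only when the union of its matched detected intervals captures more
#' than 90% of the event duration; detected intervals overlapping no true
#' event count as false positives; unmatched true events are false
#' negatives, so `css + nfn = tns` always.
#'
#' @param true_events,detected Data frames with `start_s`, `end_s`;
#'   internally disjoint.
#' @param min_capture Required captured fraction (default 0.9, exclusive).
#' @return List of class `segmentation_score` with `tns`, `css`, `nfp`,
#'   `nfn`.
#' @export
score_segmentation <- function(true_events, detected, min_capture = 0.9) {
  true_events <- check_intervals(true_events, "true_events")
  detected <- check_intervals(detected, "detected")
  tns <- nrow(true_events)
  if (nrow(detected) == 0L)
    return(structure(list(tns = tns, css = 0L, nfp = 0L, nfn = tns),
                     class = "segmentation_score"))
  captured <- numeric(tns)
  nfp <- 0L
  for (j in seq_len(nrow(detected))) {
    if (tns == 0L) { nfp <- nfp + 1L; next }
    ov <- overlap_len(detected$start_s[j], detected$end_s[j],
                      true_events$start_s, true_events$end_s)
    if (max(ov) <= 0) { nfp <- nfp + 1L; next }
    best <- which.max(ov)
    captured[best] <- captured[best] + ov[best]
  }
  durations <- true_events$end_s - true_events$start_s
  css <- sum(captured > min_capture * durations)
  structure(list(tns = tns, css = as.integer(css), nfp = nfp,
                 nfn = as.integer(tns - css)),
            class = "segmentation_score")
}

#' @export
print.segmentation_score <- function(x, ...) {
  cat(sprintf("<segmentation_score> TNS %d, CSS %d, NFP %d, NFN %d\n",
              x$tns, x$css, x$nfp, x$nfn))
  invisible(x)
}

#' Detrended fluctuation analysis scaling exponent
#'
#' Classical DFA: the mean-removed signal is integrated; for each window
#' size the RMS of residuals from per-window polynomial fits of order
#' `detrend_order` gives the fluctuation function F(n); the scaling
#' exponent alpha is the log-log slope of F(n) over the fitted scale
#' range.  White noise gives alpha near 0.5, a random walk near 1.5.
#'
#' @param signal Numeric vector.
#' @param scales Integer window sizes; default 20 log-spaced scales from 10
#'   to `length(signal)/4`.
#' @param detrend_order Per-window polynomial order (default 1).
#' @return Object of class `dfa_result` with `scales`, `fluctuation`,
#'   `alpha`, `fit_range`.
#' @export
dfa_alpha <- function(signal, scales = NULL, detrend_order = 1) {
  check_signal(signal)
  n <- length(signal)
  abort_if(detrend_order < 1 || detrend_order != round(detrend_order),
           "`detrend_order` must be a positive integer.")
  if (is.null(scales)) {
    abort_if(n < 40L, "signal too short for the default DFA scales.")
    scales <- unique(round(exp(seq(log(10), log(n / 4), length.out = 20))))
  }
  scales <- sort(unique(as.integer(scales)))
  abort_if(min(scales) < detrend_order + 2,
           "minimum scale must be at least detrend_order + 2.")
  abort_if(max(scales) > n / 4, "maximum scale must not exceed length/4.")
  y <- cumsum(signal - mean(signal))
  fl <- vapply(scales, function(s) {
    k <- n %/% s
    Y <- matrix(y[seq_len(k * s)], nrow = s)
    X <- outer(seq_len(s) / s, 0:detrend_order, `^`)
    qrX <- qr(X)
    res <- Y - X %*% qr.coef(qrX, Y)
    sqrt(mean(res^2))
  }, numeric(1))
  ok <- fl > 0
  abort_if(sum(ok) < 2L, "fluctuation function is degenerate.")
  fit <- stats::lm.fit(cbind(1, log(scales[ok])), log(fl[ok]))
  structure(list(scales = scales, fluctuation = fl,
                 alpha = as.numeric(fit$coefficients[2]),
                 fit_range = range(scales[ok])),
            class = "dfa_result")
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("<dfa_result> alpha = %.3f over scales %d-%d (%d scales)\n",
              x$alpha, x$fit_range[1], x$fit_range[2], length(x$scales)))
  invisible(x)
}

#' Segmentation and persistence before vs after spline detrending
#'
#' For each synthetic recording and axis, segments the raw signal and the
#' spline-detrended signal, scores both against the ground-truth events
#' (CSS/NFP/NFN), and computes the DFA scaling exponent before and after
#' removal.  Reports per-recording rows, aggregate totals, and
#' Mann-Whitney p-values for the alpha shift per axis.
#'
#' @param recordings List of `swacc_recording` objects (see
#'   [gen_recording()]).
#' @param fr_ap,fr_si Spline resampling frequency per axis (Hz).
#' @param degree Spline degree.
#' @param window_s,threshold_k,min_event_s Segmenter settings, see
#'   [segment_swallows()].
#' @param dfa_scales Optional DFA scales.
#' @return Object of class `before_after` with `per_recording` (tibble),
#'   `totals` (tibble of aggregate CSS/NFP/NFN by phase), `alpha_tests`
#'   (tibble: axis, mean alpha before/after, Mann-Whitney p).
#' @export
before_after_study <- function(recordings, fr_ap = 4, fr_si = 4, degree = 3,
                               window_s = 0.2, threshold_k = 6,
                               min_event_s = 0.3, dfa_scales = NULL) {
  abort_if(!is.list(recordings) || length(recordings) == 0L ||
             !all(vapply(recordings, inherits, logical(1), "swacc_recording")),
           "`recordings` must be a non-empty list of swacc_recording objects.")
  fr <- c(ap = fr_ap, si = fr_si)
  rows <- list()
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    for (axis in c("ap", "si")) {
      sig <- rec$data[[axis]]
      after <- spline_detrend(sig, rec$f_s, fr[[axis]], degree)$residual
      for (phase in c("before", "after")) {
        x <- if (phase == "before") sig else after
        det <- segment_swallows(x, rec$f_s, window_s, threshold_k, min_event_s)
        sc <- score_segmentation(rec$events, det)
        alpha <- dfa_alpha(x, dfa_scales)$alpha
        rows[[length(rows) + 1L]] <-
          tibble::tibble(recording = i, axis = axis, phase = phase,
                         tns = sc$tns, css = sc$css, nfp = sc$nfp,
                         nfn = sc$nfn, alpha = alpha)
      }
    }
  }
  per_rec <- dplyr::bind_rows(rows)
  totals <- per_rec |>
    dplyr::group_by(.data$phase) |>
    dplyr::summarise(tns = sum(.data$tns), css = sum(.data$css),
                     nfp = sum(.data$nfp), nfn = sum(.data$nfn),
                     .groups = "drop")
  alpha_tests <- per_rec |>
    dplyr::group_by(.data$axis) |>
    dplyr::summarise(
      mean_alpha_before = mean(.data$alpha[.data$phase == "before"]),
      mean_alpha_after = mean(.data$alpha[.data$phase == "after"]),
      p_value = mann_whitney(.data$alpha[.data$phase == "before"],
                             .data$alpha[.data$phase == "after"]),
      .groups = "drop")
  structure(list(per_recording = per_rec, totals = totals,
                 alpha_tests = alpha_tests,
                 settings = list(fr_ap = fr_ap, fr_si = fr_si, degree = degree,
                                 window_s = window_s, threshold_k = threshold_k,
                                 min_event_s = min_event_s)),
            class = "before_after")
}

#' @export
print.before_after <- function(x, ...) {
  cat(sprintf("<before_after> %d recordings\n",
              max(x$per_recording$recording)))
  print(x$totals)
  print(x$alpha_tests)
  invisible(x)
}
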
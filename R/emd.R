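# Empirical mode decomposition, implemented for the EMD detrending
# baseline: standard sifting with cubic-spline envelopes through the
# extrema, mirrored end extrema, and the normalised successive-difference
# stopping rule.

find_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(max = integer(0), min = integer(0)))
  d <- diff(x)
  # collapse plateaus: use sign of differences, carrying the last non-zero
  s <- sign(d)
  nz <- s != 0
  if (!any(nz)) return(list(max = integer(0), min = integer(0)))
  idx_nz <- which(nz)
  carry <- findInterval(seq_along(s), idx_nz)
  s_filled <- ifelse(carry == 0, 0, s[idx_nz[pmax(carry, 1L)]])
  turn <- diff(s_filled)
  list(max = which(turn < 0) + 1L, min = which(turn > 0) + 1L)
}

# Envelope through extrema (idx, x[idx]) with end conditions obtained by
# mirroring the outermost extrema about the signal end points.
emd_envelope <- function(x, idx) {
  n <- length(x)
  k <- min(2L, length(idx))
  left_i <- 2L - rev(idx[seq_len(k)])          # mirror about sample 1
  right_i <- 2L * n - rev(idx[length(idx) - seq_len(k) + 1L])
  xi <- c(left_i, idx, right_i)
  yi <- c(x[rev(idx[seq_len(k)])], x[idx], x[rev(idx[length(idx) - seq_len(k) + 1L])])
  keep <- !duplicated(xi)
  stats::spline(xi[keep], yi[keep], xout = seq_len(n), method = "fmm")$y
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) by sifting:
#' cubic-spline upper/lower envelopes through local extrema (end extrema
#' mirrored about the signal boundaries), subtracting the envelope mean
#' until the normalised successive-difference criterion falls below
#' `sd_tol` or `max_sifts` is reached.  Extraction stops when the residue
#' has fewer than three extrema (e.g. is monotone) or `max_imfs` is
#' reached.  By construction the IMFs plus residue reconstruct the input
#' exactly.
#'
#' @param signal Numeric vector, length >= 16.
#' @param sd_tol Sifting stop tolerance (default 0.05).
#' @param max_sifts Maximum sifting iterations per IMF (default 50).
#' @param max_imfs Maximum number of IMFs (default 16).
#' @return List with `imfs` (matrix, one column per IMF; zero columns when
#'   no extrema exist) and `residue`.
#' @export
emd_decompose <- function(signal, sd_tol = 0.05, max_sifts = 50L,
                          max_imfs = 16L) {
  check_signal(signal)
  abort_if(length(signal) < 16L, "`signal` must have at least 16 samples.")
  residue <- signal
  imfs <- list()
  for (k in seq_len(max_imfs)) {
    ex <- find_extrema(residue)
    if (length(ex$max) + length(ex$min) < 3L ||
        length(ex$max) < 2L || length(ex$min) < 2L) break
    h <- residue
    for (s in seq_len(max_sifts)) {
      ex_h <- find_extrema(h)
      if (length(ex_h$max) < 2L || length(ex_h$min) < 2L) break
      upper <- emd_envelope(h, ex_h$max)
      lower <- emd_envelope(h, ex_h$min)
      mean_env <- (upper + lower) / 2
      h_new <- h - mean_env
      sd_crit <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.xmin)
      h <- h_new
      if (sd_crit < sd_tol) break
    }
    imfs[[k]] <- h
    residue <- residue - h
  }
  list(imfs = if (length(imfs)) do.call(cbind, imfs)
       else matrix(numeric(0), nrow = length(signal), ncol = 0),
       residue = residue)
}

# Mean frequency of a component from its zero-crossing count.
zero_crossing_freq <- function(x, f_s) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0)
  zc <- sum(diff(s) != 0)
  zc / 2 * f_s / length(x)
}

#' EMD-based detrending
#'
#' Decomposes the signal by [emd_decompose()] and assembles the trend from
#' the residue plus every IMF whose mean zero-crossing frequency is below
#' `trend_cutoff`; the residual (the sum of the faster IMFs) is the
#' detrended signal.  Degenerate inputs are handled gracefully: a strictly
#' monotone or constant signal yields no IMFs, so the trend is the signal
#' itself.
#'
#' @param signal Numeric vector, length >= 16.
#' @param f_s Sampling frequency (Hz).
#' @param trend_cutoff Frequency (Hz) below which an IMF is assigned to
#'   the trend; a natural choice is `f_r / 2`.
#' @return A `detrend_result` whose `params` include the number of IMFs
#'   and how many were assigned to the trend.
#' @export
emd_detrend <- function(signal, f_s, trend_cutoff) {
  check_signal(signal)
  check_scalar_number(f_s, "f_s", min = .Machine$double.eps)
  check_scalar_number(trend_cutoff, "trend_cutoff", min = 0)
  dec <- emd_decompose(signal)
  n_imf <- ncol(dec$imfs)
  trend <- dec$residue
  n_trend_imfs <- 0L
  if (n_imf > 0L) {
    freqs <- apply(dec$imfs, 2L, zero_crossing_freq, f_s = f_s)
    sel <- freqs < trend_cutoff
    n_trend_imfs <- sum(sel)
    if (any(sel)) trend <- trend + rowSums(dec$imfs[, sel, drop = FALSE])
  }
  new_detrend_result(signal, trend, "emd",
                     list(f_s = f_s, trend_cutoff = trend_cutoff,
                          n_imfs = n_imf, n_trend_imfs = n_trend_imfs))
}
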
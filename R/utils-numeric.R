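# Internal numeric helpers: validation, mirror extension, convolution.

abort_if <- function(cond, msg) {
  if (isTRUE(cond)) rlang::abort(msg, class = "splinetrend_error")
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  abort_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
           sprintf("`%s` must be a single finite number.", name))
  abort_if(x < min || x > max,
           sprintf("`%s` must be in [%s, %s].", name, format(min), format(max)))
  invisible(x)
}

check_signal <- function(x, name = "signal") {
  abort_if(!is.numeric(x) || length(x) == 0L,
           sprintf("`%s` must be a non-empty numeric vector.", name))
  abort_if(anyNA(x) || any(!is.finite(x)),
           sprintf("`%s` contains missing or non-finite values.", name))
  invisible(x)
}

check_degree <- function(degree) {
  abort_if(!is.numeric(degree) || length(degree) != 1L || is.na(degree) ||
             degree < 0 || degree != round(degree),
           "`degree` must be a non-negative integer.")
  as.integer(degree)
}

check_m <- function(m) {
  abort_if(!is.numeric(m) || length(m) != 1L || is.na(m) ||
             m < 1 || m != round(m),
           "`m` must be a positive integer.")
  as.integer(m)
}

match_boundary <- function(boundary) {
  match.arg(boundary, c("mirror", "zero"))
}

# Whole-sample symmetric reflection of 0-based indices into 0..(n-1).
# Period is 2n - 2 so that x[-1] -> x[1] and x[n] -> x[n-2].
fold_index0 <- function(j, n) {
  if (n == 1L) return(rep.int(0L, length(j)))
  p <- 2L * n - 2L
  j <- j %% p
  ifelse(j > n - 1L, p - j, j)
}

# Extend a signal by `left`/`right` samples under the chosen boundary mode.
extend_signal <- function(x, left, right, boundary = "mirror") {
  n <- length(x)
  idx <- seq.int(-left, n - 1L + right)
  if (boundary == "mirror") {
    x[fold_index0(idx, n) + 1L]
  } else {
    out <- numeric(length(idx))
    inside <- idx >= 0L & idx <= n - 1L
    out[inside] <- x[idx[inside] + 1L]
    out
  }
}

# Full linear convolution.  Direct loop over the shorter vector when cheap,
# FFT with padding to a highly composite length otherwise.
conv_full <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) return(numeric(0))
  if (ny > nx) { tmp <- x; x <- y; y <- tmp; tmp <- nx; nx <- ny; ny <- tmp }
  nout <- nx + ny - 1L
  if (as.double(nx) * ny <= 2e6) {
    out <- numeric(nout)
    for (k in seq_len(ny)) {
      out[k:(k + nx - 1L)] <- out[k:(k + nx - 1L)] + y[k] * x
    }
    return(out)
  }
  nfft <- stats::nextn(nout, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(nfft - nx)))
  Y <- stats::fft(c(y, numeric(nfft - ny)))
  Re(stats::fft(X * Y, inverse = TRUE))[seq_len(nout)] / nfft
}

# Correlation of `x` (length n, boundary-extended) with taps at integer lags
# `lags`: out[i] = sum_j taps[j] * x_ext[i + lags[j]], i = 0..n-1 (0-based).
correlate_ext <- function(x, taps, lags, boundary = "mirror") {
  n <- length(x)
  L <- max(abs(lags))
  xe <- extend_signal(x, L, L, boundary)
  # conv(xe, rev(taps)): rev(taps) has lags -max(lags)..-min(lags)
  cv <- conv_full(xe, rev(taps))
  # xe starts at position -L; rev(taps) contributes starting lag -max(lags);
  # position of cv[1] is (-L) + (-max(lags)).
  start <- -L - max(lags)
  # out[i] (i = 0..n-1) sits at cv index i - start + 1
  cv[(0:(n - 1L)) - start + 1L]
}
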
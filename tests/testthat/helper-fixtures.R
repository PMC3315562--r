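# Small, fast synthetic profiles for unit tests (the acceptance tests use
# the full study conditions).
small_cfg <- function(...) {
  synthetic_config(duration_s = 8, f_s = 500, ...)
}

# Numerical (degree+1)-fold self-convolution of the unit box, evaluated at
# a point: independent oracle for the continuous B-spline.
box_convolution_oracle <- function(x0, degree, dx = 2e-5) {
  half_width <- (degree + 1) / 2 + 0.5
  x <- seq(-half_width, half_width, by = dx)
  box <- as.numeric(abs(x) < 0.5)
  box[abs(abs(x) - 0.5) < dx / 2] <- 0.5
  # full linear convolution via FFT, padded to a highly composite length
  conv_open <- function(a, b) {
    nout <- length(a) + length(b) - 1L
    nfft <- stats::nextn(nout, c(2, 3, 5))
    A <- stats::fft(c(a, numeric(nfft - length(a))))
    B <- stats::fft(c(b, numeric(nfft - length(b))))
    Re(stats::fft(A * B, inverse = TRUE))[seq_len(nout)] / nfft
  }
  f <- box
  for (i in seq_len(degree)) {
    f <- conv_open(f, box) * dx
    start <- (length(f) - length(x)) / 2
    f <- f[start + seq_along(x)]
  }
  f[which.min(abs(x - x0))]
}
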
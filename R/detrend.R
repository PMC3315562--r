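# Trend removal: the spline least-squares detrender and three baselines
# (smoothness priors, piecewise polynomial fitting, EMD).  Every method
# returns a detrend_result whose trend + residual reconstructs the input
# exactly; the residual is the swallow-preserving, head-motion-free signal.

new_detrend_result <- function(signal, trend, method, params) {
  structure(
    list(trend = trend, residual = signal - trend,
         method = method, params = params, n = length(signal)),
    class = "detrend_result")
}

#' @export
print.detrend_result <- function(x, ...) {
  cat(sprintf("<detrend_result> method '%s', %d samples\n", x$method, x$n))
  cat("  params:", paste(names(x$params),
                         vapply(x$params, function(p) format(p, digits = 4),
                                character(1)),
                         sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Choose the knot lattice for a resampling frequency
#'
#' Maps a target resampling frequency `f_r` (the coarse rate used to follow
#' head motions, well below the swallowing band) to an integer decimation
#' factor `m = round(f_s / f_r)` and the knot count
#' `M = floor((N - 1)/m) + 1`.  Requires `0 < f_r < f_s / 2`; the realized
#' resampling frequency `f_s / m` is reported back.
#'
#' @param f_s Sampling frequency in Hz.
#' @param f_r Target resampling frequency in Hz.
#' @param signal_length Number of samples N.
#' @return A list of class `resampling_choice` with fields `f_s`, `f_r`
#'   (requested), `f_r_realized`, `m`, `M`.
#' @examples
#' choose_resampling(1000, 4, 10001)   # m = 250, M = 41
#' @export
choose_resampling <- function(f_s, f_r, signal_length) {
  check_scalar_number(f_s, "f_s", min = .Machine$double.eps)
  check_scalar_number(f_r, "f_r")
  abort_if(f_r <= 0 || f_r >= f_s / 2,
           "`f_r` must satisfy 0 < f_r < f_s / 2.")
  abort_if(!is.numeric(signal_length) || length(signal_length) != 1L ||
             signal_length < 1 || signal_length != round(signal_length),
           "`signal_length` must be a positive integer.")
  m <- as.integer(round(f_s / f_r))
  structure(
    list(f_s = f_s, f_r = f_r, f_r_realized = f_s / m,
         m = m, M = knot_count(as.integer(signal_length), m)),
    class = "resampling_choice")
}

#' @export
print.resampling_choice <- function(x, ...) {
  cat(sprintf("<resampling_choice> f_s = %g Hz, f_r = %g Hz (realized %.4g Hz), m = %d, M = %d knots\n",
              x$f_s, x$f_r, x$f_r_realized, x$m, x$M))
  invisible(x)
}

#' Spline least-squares detrending
#'
#' Estimates the low-frequency head-motion component as the least-squares
#' spline approximation of the signal on a coarse knot lattice (knot rate
#' `f_r`), and removes it.  The trend is [lsq_project()] at
#' `m = round(f_s/f_r)`; the residual `signal - trend` keeps the swallowing
#' vibrations, whose frequency content lies far above `f_r`.
#'
#' @param signal Numeric vector (one accelerometry axis).
#' @param f_s Sampling frequency (Hz).
#' @param f_r Resampling (knot) frequency (Hz); default 4 Hz, twice the
#'   upper edge of the default 0-2 Hz head-motion band.
#' @param degree Spline degree (default 3, i.e. fourth-order splines).
#' @param boundary Boundary mode for the spline machinery.
#' @return A `detrend_result` with fields `trend`, `residual`, `method`,
#'   `params`.
#' @export
spline_detrend <- function(signal, f_s, f_r = 4, degree = 3,
                           boundary = "mirror") {
  check_signal(signal)
  rc <- choose_resampling(f_s, f_r, length(signal))
  trend <- lsq_project(signal, degree, rc$m, boundary)
  new_detrend_result(signal, trend, "spline",
                     list(f_s = f_s, f_r = f_r, f_r_realized = rc$f_r_realized,
                          m = rc$m, M = rc$M, degree = check_degree(degree)))
}

#' Regularisation parameter for the smoothness priors detrender
#'
#' Closed-form choice of the smoothness priors parameter so that the
#' whole-signal smoother's half-power frequency equals `f_r`: the
#' second-difference smoother has frequency response
#' `1 / (1 + lambda^2 (2 sin(pi f / f_s))^4)`, giving
#' `lambda = 1 / (2 sin(pi f_r / f_s))^2`.
#'
#' @param f_s Sampling frequency (Hz). @param f_r Target cutoff (Hz).
#' @return Positive scalar `lambda`.
#' @export
spm_lambda <- function(f_s, f_r) {
  check_scalar_number(f_s, "f_s", min = .Machine$double.eps)
  abort_if(f_r <= 0 || f_r >= f_s / 2, "`f_r` must satisfy 0 < f_r < f_s / 2.")
  1 / (2 * sin(pi * f_r / f_s))^2
}

block_bounds <- function(n, n_subintervals) {
  nb <- n %/% n_subintervals
  abort_if(nb < 1L, "`n_subintervals` exceeds the signal length.")
  starts <- (seq_len(n_subintervals) - 1L) * nb + 1L
  ends <- c(starts[-1L] - 1L, n)  # last block absorbs the remainder
  list(starts = starts, ends = ends, nb = nb)
}

spm_hat <- function(nb, lambda) {
  if (nb < 3L) return(diag(nb))
  D <- diff(diag(nb), differences = 2)
  solve(diag(nb) + lambda^2 * crossprod(D))
}

#' Smoothness priors (SPM) detrending
#'
#' Within each of `n_subintervals` equal-length contiguous blocks (the last
#' absorbs the remainder), the trend is the second-difference-regularised
#' least-squares smoother `(I + lambda^2 D2' D2)^{-1} g`; block trends are
#' concatenated and subtracted.  As `lambda -> 0` the trend interpolates
#' the signal; as `lambda -> Inf` it approaches the per-block straight-line
#' fit (the null space of the penalty).
#'
#' @param signal Numeric vector.
#' @param regularization Positive smoothing parameter `lambda`; see
#'   [spm_lambda()] for a cutoff-matched default.
#' @param n_subintervals Number of blocks (default 1000).
#' @param whole_signal If `TRUE`, apply the smoother to the whole signal at
#'   once (`n_subintervals` ignored).
#' @return A `detrend_result`.
#' @export
spm_detrend <- function(signal, regularization, n_subintervals = 1000,
                        whole_signal = FALSE) {
  check_signal(signal)
  check_scalar_number(regularization, "regularization",
                      min = .Machine$double.eps)
  n <- length(signal)
  if (isTRUE(whole_signal)) n_subintervals <- 1L
  abort_if(!is.numeric(n_subintervals) || length(n_subintervals) != 1L ||
             n_subintervals < 1 || n_subintervals != round(n_subintervals),
           "`n_subintervals` must be a positive integer.")
  abort_if(n_subintervals > n, "`n_subintervals` exceeds the signal length.")
  abort_if(n / n_subintervals > 2000,
           "SPM subintervals longer than 2000 samples are not supported; increase `n_subintervals`.")
  bb <- block_bounds(n, as.integer(n_subintervals))
  trend <- numeric(n)
  if (n_subintervals > 1L) {
    H <- spm_hat(bb$nb, regularization)
    main <- seq_len((n_subintervals - 1L) * bb$nb)
    trend[main] <- as.numeric(H %*% matrix(signal[main], nrow = bb$nb))
  }
  last <- bb$starts[n_subintervals]:n
  trend[last] <- as.numeric(spm_hat(length(last), regularization) %*% signal[last])
  new_detrend_result(signal, trend, "spm",
                     list(lambda = regularization,
                          n_subintervals = n_subintervals))
}

poly_hat <- function(nb, degree) {
  x <- seq(-1, 1, length.out = nb)
  X <- outer(x, 0:degree, `^`)
  X %*% solve(crossprod(X), t(X))
}

#' Piecewise polynomial fitting (PPF) detrending
#'
#' The trend is the per-subinterval ordinary least-squares polynomial of
#' the stated degree (default: second-order polynomials over 5000 equal
#' blocks, the last absorbing the remainder); the residual is the
#' detrended signal.
#'
#' @param signal Numeric vector.
#' @param n_subintervals Number of blocks (default 5000).
#' @param poly_degree Polynomial degree per block (default 2).
#' @return A `detrend_result`.
#' @export
ppf_detrend <- function(signal, n_subintervals = 5000, poly_degree = 2) {
  check_signal(signal)
  poly_degree <- check_degree(poly_degree)
  n <- length(signal)
  abort_if(!is.numeric(n_subintervals) || length(n_subintervals) != 1L ||
             n_subintervals < 1 || n_subintervals != round(n_subintervals),
           "`n_subintervals` must be a positive integer.")
  abort_if(n_subintervals > n, "`n_subintervals` exceeds the signal length.")
  bb <- block_bounds(n, as.integer(n_subintervals))
  abort_if(bb$nb < poly_degree + 1L,
           "each subinterval must contain at least poly_degree + 1 samples.")
  trend <- numeric(n)
  if (n_subintervals > 1L) {
    H <- poly_hat(bb$nb, poly_degree)
    main <- seq_len((n_subintervals - 1L) * bb$nb)
    trend[main] <- as.numeric(H %*% matrix(signal[main], nrow = bb$nb))
  }
  last <- bb$starts[n_subintervals]:n
  trend[last] <- as.numeric(poly_hat(length(last), poly_degree) %*% signal[last])
  new_detrend_result(signal, trend, "ppf",
                     list(n_subintervals = n_subintervals,
                          poly_degree = poly_degree))
}
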
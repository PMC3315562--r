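#' Evaluate the continuous B-spline of a given degree
#'
#' The continuous B-spline of degree \eqn{n}, \eqn{\beta^n(x)}, is the
#' (n+1)-fold self-convolution of the unit-width indicator function.  It is
#' symmetric about zero, non-negative, compactly supported on
#' \eqn{[-(n+1)/2, (n+1)/2]} and integrates to one.  Evaluation uses the
#' stable two-term recursion
#' \deqn{\beta^n(x) = \frac{(x + \frac{n+1}{2})\,\beta^{n-1}(x + \tfrac12)
#'   + (\frac{n+1}{2} - x)\,\beta^{n-1}(x - \tfrac12)}{n},}
#' which supports arbitrary degree without tabulating piecewise polynomials.
#' At the jump points of the degree-0 box the mid-value convention
#' \eqn{\beta^0(\pm 1/2) = 1/2} is used, so that sampled kernels retain the
#' partition-of-unity property on every lattice.
#'
#' @param x Numeric vector of evaluation points.
#' @param degree Non-negative integer polynomial degree (the spline order is
#'   `degree + 1`).
#' @return Numeric vector of the same length as `x`.
#' @examples
#' continuous_bspline(0, 3)        # 2/3
#' continuous_bspline(c(-1, 0, 1), 1)
#' @export
continuous_bspline <- function(x, degree) {
  degree <- check_degree(degree)
  abort_if(!is.numeric(x), "`x` must be numeric.")
  beta_rec(as.numeric(x), degree)
}

beta_rec <- function(x, n) {
  if (n == 0L) {
    out <- numeric(length(x))
    out[abs(x) < 0.5] <- 1
    out[abs(x) == 0.5] <- 0.5
    return(out)
  }
  h <- (n + 1) / 2
  ((x + h) * beta_rec(x + 0.5, n - 1L) + (h - x) * beta_rec(x - 0.5, n - 1L)) / n
}

new_kernel_seq <- function(taps, lags, degree = NA_integer_, m = NA_integer_,
                           shift = 0) {
  keep <- range(which(taps != 0))
  taps <- taps[keep[1]:keep[2]]
  lags <- lags[keep[1]:keep[2]]
  structure(
    list(taps = taps, lags = lags,
         center_index = match(0L, lags),
         support = length(taps),
         degree = degree, m = m, shift = shift),
    class = "kernel_seq")
}

#' @export
print.kernel_seq <- function(x, ...) {
  cat(sprintf("<kernel_seq> degree %s, m %s, %d taps (lags %d..%d%s)\n",
              x$degree, x$m, x$support, min(x$lags), max(x$lags),
              if (x$shift != 0) sprintf(", half-sample shift %g", x$shift) else ""))
  print(stats::setNames(x$taps, x$lags), ...)
  invisible(x)
}

#' Discrete B-spline kernel by lattice sampling
#'
#' The discrete B-spline \eqn{b^n_m} is the sequence of integer-lattice
#' samples of the continuous B-spline expanded by the integer factor `m`,
#' i.e. taps \eqn{\beta^n(k/m)}.  The kernel is symmetric about lag zero,
#' non-negative, and its taps sum to `m` for every degree (partition of
#' unity under `m`-fold sampling).  For `degree = 0` it is the width-`m`
#' moving-average window, centered when `m` is odd; for even `m` the box
#' edges fall on the lattice and take the mid-value 1/2.
#'
#' @param degree Non-negative integer spline degree.
#' @param m Positive integer expansion factor.
#' @return A `kernel_seq` object with fields `taps`, `lags`, `center_index`,
#'   `support`.
#' @examples
#' discrete_bspline(0, 3)$taps  # 1 1 1
#' discrete_bspline(1, 2)$taps  # 0.5 1.0 0.5
#' @export
discrete_bspline <- function(degree, m) {
  degree <- check_degree(degree)
  m <- check_m(m)
  half <- m * (degree + 1) / 2
  lags <- seq.int(-ceiling(half), ceiling(half))
  taps <- beta_rec(lags / m, degree)
  new_kernel_seq(taps, lags, degree, m)
}

# Expanded-basis taps aligned to the least-squares knot lattice: for even m
# the basis functions are centered between samples (half-sample shift), so
# the taps are beta^n((j - 1/2)/m).  For odd m this equals discrete_bspline.
knot_basis_taps <- function(degree, m) {
  if (m %% 2L == 1L) return(discrete_bspline(degree, m))
  half <- m * (degree + 1) / 2
  lags <- seq.int(floor(-half + 0.5), ceiling(half + 0.5))
  taps <- beta_rec((lags - 0.5) / m, degree)
  new_kernel_seq(taps, lags, degree, m, shift = -0.5)
}

#' Discrete B-spline kernel via the moving-average convolution property
#'
#' Builds \eqn{b^n_m} from repeated discrete convolution of the width-`m`
#' moving-average window with a correction kernel, instead of sampling the
#' continuous B-spline directly.  Writing \eqn{u_m} for the width-`m` box,
#' the two-scale relation gives
#' \deqn{b^n_m = \frac{1}{m^n}\, u_m^{*(n+1)} * h,}
#' where \eqn{h} holds integer samples of \eqn{\beta^n} when the total shift
#' \eqn{(n+1)(m-1)/2} is an integer, and half-integer samples (the
#' half-sample-consistent shift for even `m`, even order) otherwise.  The
#' result equals [discrete_bspline()] tap-for-tap; the two construction
#' paths cross-validate each other.
#'
#' @inheritParams discrete_bspline
#' @return A `kernel_seq`, identical (within 1e-12) to `discrete_bspline(degree, m)`.
#' @export
discrete_bspline_via_convolution <- function(degree, m) {
  degree <- check_degree(degree)
  m <- check_m(m)
  if (m == 1L) return(discrete_bspline(degree, 1L))
  box <- rep.int(1, m)
  acc <- 1
  for (i in seq_len(degree + 1L)) acc <- conv_full(acc, box)
  # acc spans lags 0..(degree+1)(m-1) relative to its own start
  delta <- (degree + 1L) * (m - 1L) / 2
  if (delta == floor(delta)) {
    corr <- beta_rec(seq.int(-ceiling((degree + 1) / 2), ceiling((degree + 1) / 2)),
                     degree)
    corr_start <- -ceiling((degree + 1) / 2)
  } else {
    # half-integer total shift: correction kernel on the half-integer lattice
    hl <- seq.int(-floor(degree / 2 + 1), floor(degree / 2 + 1))
    corr <- beta_rec(hl + 0.5, degree)
    corr_start <- min(hl)
    delta <- delta - 0.5
  }
  taps <- conv_full(acc, corr) / m^degree
  start <- 0 - delta + corr_start
  new_kernel_seq(taps, seq.int(start, by = 1, length.out = length(taps)),
                 degree, m)
}

#' Direct B-spline transform (interpolation coefficients)
#'
#' Computes expansion coefficients `c` such that convolving `c` with the
#' unit-step discrete B-spline \eqn{b^n_1} reproduces the input samples
#' exactly: the inverse filtering step of spline interpolation.  The
#' banded symmetric Toeplitz system is solved exactly under the chosen
#' boundary extension (default whole-sample mirror), rather than by the
#' truncated recursive-filter approximation, so the round trip
#' `indirect_transform(direct_transform(g))` is exact to solver tolerance.
#'
#' @param signal Non-empty numeric vector.
#' @param degree Non-negative integer spline degree.
#' @param boundary Boundary extension: `"mirror"` (default) or `"zero"`.
#' @return Numeric vector of coefficients, same length as `signal`.
#' @export
direct_transform <- function(signal, degree, boundary = "mirror") {
  check_signal(signal)
  degree <- check_degree(degree)
  boundary <- match_boundary(boundary)
  n <- length(signal)
  if (degree <= 1L) return(signal)  # b^0_1 and b^1_1 are the identity tap
  abort_if(n > 4000L, "`direct_transform` supports signals up to 4000 samples.")
  ker <- discrete_bspline(degree, 1L)
  A <- matrix(0, n, n)
  for (t in seq_along(ker$taps)) {
    lag <- ker$lags[t]
    k_ext <- seq.int(0L, n - 1L) + lag       # coefficient index hit at row i
    if (boundary == "mirror") {
      k_fold <- fold_index0(k_ext, n)
      for (i in seq_len(n)) A[i, k_fold[i] + 1L] <- A[i, k_fold[i] + 1L] + ker$taps[t]
    } else {
      ok <- k_ext >= 0L & k_ext <= n - 1L
      idx <- which(ok)
      A[cbind(idx, k_ext[ok] + 1L)] <- A[cbind(idx, k_ext[ok] + 1L)] + ker$taps[t]
    }
  }
  as.numeric(solve(A, signal))
}

#' Indirect B-spline transform (reconstruction, optionally upsampled)
#'
#' Reconstructs a signal from B-spline coefficients by zero-insertion
#' upsampling by `m` followed by convolution with the discrete B-spline
#' \eqn{b^n_m}: \eqn{g(j) = \sum_k c(k)\, b^n_m(j - km)}.  At `m = 1` this is
#' the inverse of [direct_transform()].  Coefficients are boundary-extended
#' by mirroring (default).
#'
#' @param coeffs Non-empty numeric coefficient vector.
#' @param degree Non-negative integer spline degree.
#' @param m Positive integer upsampling factor.
#' @param out_length Output length; defaults to `(length(coeffs) - 1) * m + 1`.
#' @param boundary Boundary extension mode.
#' @return Numeric vector of length `out_length`.
#' @export
indirect_transform <- function(coeffs, degree, m, out_length = NULL,
                               boundary = "mirror") {
  check_signal(coeffs, "coeffs")
  degree <- check_degree(degree)
  m <- check_m(m)
  boundary <- match_boundary(boundary)
  nc <- length(coeffs)
  if (is.null(out_length)) out_length <- (nc - 1L) * m + 1L
  abort_if(!is.numeric(out_length) || length(out_length) != 1L ||
             out_length < 1 || out_length != round(out_length),
           "`out_length` must be a positive integer.")
  out_length <- as.integer(out_length)
  abort_if(out_length > nc * m + m,
           "`out_length` is inconsistent with `length(coeffs)` and `m`.")
  ker <- discrete_bspline(degree, m)
  # extend coefficients so that the kernel support is covered at both ends
  ext <- ceiling(max(abs(ker$lags)) / m) + 1L
  ce <- extend_signal(coeffs, ext, ext, boundary)
  up <- numeric((length(ce) - 1L) * m + 1L)
  up[seq.int(1L, by = m, length.out = length(ce))] <- ce
  cv <- conv_full(up, ker$taps)
  # up[1] is coefficient index -ext (position -ext*m); taps start at min lag
  start <- -ext * m + min(ker$lags)
  cv[(0:(out_length - 1L)) - start + 1L]
}
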
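# Least-squares spline approximation on a coarse knot lattice.
#
# A signal g of length N is approximated in the span of the m-expanded,
# shifted B-spline basis functions
#     phi_k(i) = beta^n((i - t_k) / m),   t_k = k*m + (m - 1)/2,
# k = 0..M-1 with M = floor((N - 1)/m) + 1 knots.  For even m the centers
# t_k fall between samples (half-sample shift), which is what makes the
# degree-0 approximation an exact partition into blocks [km, km + m).
# Under the mirror boundary decision the basis functions are folded back
# into [0, N), and the least-squares solution is computed either by the
# three-step filtering procedure (prefilter, decimate, postfilter) or by
# explicit normal equations (the brute-force oracle).

.splinetrend_cache <- new.env(parent = emptyenv())

knot_count <- function(n, m) (n - 1L) %/% m + 1L

knot_centers0 <- function(M, m) (seq_len(M) - 1) * m + (m - 1) / 2

# Sparse folded basis column: positions (1-based) and values of phi_k folded
# into the signal domain (or truncated, for zero boundary).
folded_basis_column <- function(degree, m, n, k, boundary = "mirror") {
  tk <- (k - 1) * m + (m - 1) / 2
  w <- m * (degree + 1) / 2
  j <- seq.int(ceiling(tk - w), floor(tk + w))
  val <- beta_rec((j - tk) / m, degree)
  keep <- val != 0
  j <- j[keep]; val <- val[keep]
  if (boundary == "mirror") {
    i <- fold_index0(j, n)
  } else {
    ok <- j >= 0L & j <= n - 1L
    j <- j[ok]; val <- val[ok]; i <- j
  }
  agg <- rowsum(val, i)
  list(idx = as.integer(rownames(agg)) + 1L, val = as.numeric(agg))
}

# Autocorrelation of the knot-lattice basis taps at knot lags: the Gram
# kernel, i.e. the interior entries of the least-squares normal matrix.
gram_kernel <- function(degree, m) {
  ker <- knot_basis_taps(degree, m)
  taps <- ker$taps
  nt <- length(taps)
  maxr <- (nt - 1L) %/% m
  a <- vapply(0:maxr, function(r) {
    s <- r * m
    if (s >= nt) return(0)
    sum(taps[1:(nt - s)] * taps[(1 + s):nt])
  }, numeric(1))
  a[seq_len(max(which(a != 0)))]
}

#' Gram matrix of the coarse spline basis
#'
#' Returns the `M x M` normal-equation matrix of the folded, `m`-expanded
#' B-spline basis for a signal of length `n_signal`.  Interior entries form
#' a banded symmetric Toeplitz matrix built from the tap autocorrelation of
#' the expanded kernel; rows and columns of knots whose support reaches a
#' boundary are corrected for the folded (mirror) or truncated (zero)
#' basis.  The matrix is symmetric positive definite.
#'
#' @param degree Spline degree. @param m Expansion/decimation factor.
#' @param n_signal Signal length. @param boundary Boundary mode.
#' @return Dense numeric matrix.
#' @export
lsq_gram_matrix <- function(degree, m, n_signal, boundary = "mirror") {
  degree <- check_degree(degree); m <- check_m(m)
  boundary <- match_boundary(boundary)
  n <- as.integer(n_signal)
  M <- knot_count(n, m)
  a <- gram_kernel(degree, m)
  maxr <- length(a) - 1L
  G <- matrix(0, M, M)
  for (r in 0:min(maxr, M - 1L)) {
    idx <- seq_len(M - r)
    G[cbind(idx, idx + r)] <- a[r + 1L]
    G[cbind(idx + r, idx)] <- a[r + 1L]
  }
  # Boundary-affected pairs: a folded (or truncated) basis function can
  # overlap any knot whose support lies within 2w of the same boundary,
  # also at knot lags beyond the interior bandwidth.
  w <- m * (degree + 1) / 2
  tk <- knot_centers0(M, m)
  kb <- which(tk - w < 0 | tk + w > n - 1)
  if (length(kb)) {
    near_left <- which(tk < 2 * w + m)
    near_right <- which(tk > n - 1 - 2 * w - m)
    pairs <- rbind(
      expand.grid(k = intersect(kb, near_left), l = near_left),
      expand.grid(k = intersect(kb, near_right), l = near_right))
    pairs <- unique(data.frame(k = pmin(pairs$k, pairs$l),
                               l = pmax(pairs$k, pairs$l)))
    cols <- vector("list", M)
    getcol <- function(k) {
      if (is.null(cols[[k]]))
        cols[[k]] <<- folded_basis_column(degree, m, n, k, boundary)
      cols[[k]]
    }
    for (p in seq_len(nrow(pairs))) {
      k <- pairs$k[p]; l <- pairs$l[p]
      ck <- getcol(k); cl <- getcol(l)
      common <- intersect(ck$idx, cl$idx)
      v <- if (length(common))
        sum(ck$val[match(common, ck$idx)] * cl$val[match(common, cl$idx)])
      else 0
      G[k, l] <- v; G[l, k] <- v
    }
  }
  G
}

# Cholesky factor of the Gram matrix, cached per geometry.
gram_chol <- function(degree, m, n_signal, boundary) {
  key <- paste(degree, m, n_signal, boundary, sep = "|")
  val <- .splinetrend_cache[[key]]
  if (!is.null(val)) return(val)
  G <- lsq_gram_matrix(degree, m, n_signal, boundary)
  R <- tryCatch(chol(G), error = function(e)
    rlang::abort("Gram matrix is not positive definite; invalid spline geometry.",
                 class = "splinetrend_error"))
  if (length(ls(.splinetrend_cache)) > 64L)
    rm(list = ls(.splinetrend_cache), envir = .splinetrend_cache)
  .splinetrend_cache[[key]] <- R
  R
}

#' Prefilter a signal with the expanded B-spline kernel
#'
#' First step of the three-step least-squares procedure: correlation of the
#' signal with the knot-aligned discrete B-spline of width factor `m`
#' (half-sample-shifted taps for even `m`), under the chosen boundary
#' extension.  Output length equals input length; decimating the result at
#' the knot phase yields the right-hand side of the normal equations.
#'
#' @param signal Non-empty numeric vector.
#' @param degree Spline degree. @param m Expansion factor.
#' @param boundary Boundary mode.
#' @return Numeric vector, same length as `signal`.
#' @export
prefilter <- function(signal, degree, m, boundary = "mirror") {
  check_signal(signal)
  degree <- check_degree(degree); m <- check_m(m)
  boundary <- match_boundary(boundary)
  ker <- knot_basis_taps(degree, m)
  correlate_ext(signal, ker$taps, ker$lags, boundary)
}

#' Decimate a sequence
#'
#' Keeps every `m`-th sample starting at the 0-based `phase`; with the knot
#' phase `(m - 1) %/% 2` (odd `m`) this samples a prefiltered signal at the
#' knot positions.
#'
#' @param seq Numeric vector. @param m Decimation factor.
#' @param phase Integer in `[0, m)`.
#' @return Numeric vector of length `floor((N - 1 - phase)/m) + 1`.
#' @export
decimate <- function(seq, m, phase = 0L) {
  check_signal(seq, "seq")
  m <- check_m(m)
  abort_if(!is.numeric(phase) || length(phase) != 1L || is.na(phase) ||
             phase < 0 || phase >= m || phase != round(phase),
           "`phase` must be an integer in [0, m).")
  seq[seq.int(phase + 1L, length(seq), by = m)]
}

# Right-hand side of the normal equations: correlation of the (extended)
# signal with each folded basis function, evaluated directly at the knot
# lattice.  Equivalent to prefilter + decimation at the knot phase, but
# valid also for the last knot when its phase position falls beyond N - 1.
knot_correlation <- function(signal, degree, m, boundary = "mirror") {
  n <- length(signal)
  M <- knot_count(n, m)
  ker <- knot_basis_taps(degree, m)
  L <- max(abs(ker$lags)) + m
  xe <- extend_signal(signal, L, L, boundary)
  cv <- conv_full(xe, rev(ker$taps))
  start <- -L - max(ker$lags)
  # knot k sits at correlation position t_k - shift_correction
  phase <- if (m %% 2L == 1L) (m - 1L) %/% 2L else m %/% 2L - 1L
  pos <- (seq_len(M) - 1L) * m + phase
  cv[pos - start + 1L]
}

#' Postfilter: solve the Gram system for the decimated sequence
#'
#' Third step of the least-squares procedure: applies the inverse of the
#' Gram convolution operator (the knot-lattice autocorrelation of the
#' expanded B-spline basis) by a direct symmetric positive-definite solve
#' under the boundary decision.  For `degree = 0` the Gram operator is
#' `m` times the identity, so postfiltering reduces to scaling by `1/m`
#' and the three-step pipeline returns exact block means.
#'
#' @param decimated Non-empty numeric vector (length = knot count `M`).
#' @param degree Spline degree. @param m Expansion factor.
#' @param n_signal Length of the originating signal; defaults to
#'   `(M - 1) * m + 1`.
#' @param boundary Boundary mode.
#' @return Numeric coefficient vector of length `M`.
#' @export
postfilter <- function(decimated, degree, m, n_signal = NULL,
                       boundary = "mirror") {
  check_signal(decimated, "decimated")
  degree <- check_degree(degree); m <- check_m(m)
  boundary <- match_boundary(boundary)
  M <- length(decimated)
  if (is.null(n_signal)) n_signal <- (M - 1L) * m + 1L
  n_signal <- as.integer(n_signal)
  abort_if(knot_count(n_signal, m) != M,
           "`n_signal` is inconsistent with the number of knots.")
  if (M <= 2500L) {
    R <- gram_chol(degree, m, n_signal, boundary)
    as.numeric(backsolve(R, backsolve(R, decimated, transpose = TRUE)))
  } else {
    G <- lsq_gram_matrix(degree, m, n_signal, boundary)
    as.numeric(solve(G, decimated))
  }
}

#' Least-squares B-spline expansion coefficients (three-step procedure)
#'
#' Computes the coefficients of the orthogonal projection of `signal` onto
#' the coarse spline space with knot spacing `m`, via prefiltering with the
#' expanded B-spline kernel, decimation at the knot lattice, and
#' postfiltering with the inverse Gram operator.  The result minimises the
#' residual sum of squares over the coarse spline space and agrees with
#' [brute_force_lsq()] to solver tolerance.
#'
#' @param signal Numeric vector, `length(signal) >= m`.
#' @param degree Spline degree (default 3: fourth-order splines).
#' @param m Positive integer knot spacing (decimation factor).
#' @param boundary Boundary mode.
#' @return An object of class `lsq_model` with fields `degree`, `m`,
#'   `boundary`, `knots`, `coeffs`, `gram` (Gram kernel taps), `n_signal`.
#' @export
lsq_coefficients <- function(signal, degree = 3, m, boundary = "mirror") {
  check_signal(signal)
  degree <- check_degree(degree); m <- check_m(m)
  boundary <- match_boundary(boundary)
  abort_if(length(signal) < m,
           "`signal` must be at least one knot interval (m samples) long.")
  d <- knot_correlation(signal, degree, m, boundary)
  coeffs <- postfilter(d, degree, m, n_signal = length(signal),
                       boundary = boundary)
  a <- gram_kernel(degree, m)
  structure(
    list(degree = degree, m = m, boundary = boundary,
         knots = length(coeffs), coeffs = coeffs,
         gram = new_kernel_seq(c(rev(a[-1]), a),
                               seq.int(-(length(a) - 1L), length(a) - 1L),
                               2L * degree + 1L, m),
         n_signal = length(signal)),
    class = "lsq_model")
}

#' @export
print.lsq_model <- function(x, ...) {
  cat(sprintf("<lsq_model> degree %d spline, m = %d, %d knots, N = %d (%s boundary)\n",
              x$degree, x$m, x$knots, x$n_signal, x$boundary))
  invisible(x)
}

# Reconstruct the projection from an lsq_model by expanded-basis synthesis
# (upsampling + convolution with the knot-aligned kernel), folded back into
# the signal domain.
lsq_reconstruct <- function(model) {
  m <- model$m; n <- model$n_signal; M <- model$knots
  ker <- knot_basis_taps(model$degree, m)
  up <- numeric((M - 1L) * m + 1L)
  up[seq.int(1L, by = m, length.out = M)] <- model$coeffs
  cv <- conv_full(up, ker$taps)
  h <- if (m %% 2L == 1L) (m - 1L) %/% 2L else m %/% 2L - 1L
  pos <- seq.int(min(ker$lags) + h, by = 1L, length.out = length(cv))
  out <- numeric(n)
  if (model$boundary == "mirror") {
    i <- fold_index0(pos, n)
  } else {
    ok <- pos >= 0L & pos <= n - 1L
    pos <- pos[ok]; cv <- cv[ok]; i <- pos
  }
  agg <- rowsum(cv, i)
  out[as.integer(rownames(agg)) + 1L] <- agg
  out
}

#' Project a signal onto the coarse spline space
#'
#' Orthogonal projection: least-squares coefficients via the three-step
#' procedure, followed by reconstruction with the B-spline indirect
#' transform at expansion `m`.  The operation is idempotent, linear, and
#' contracts energy; the residual is orthogonal to every basis function.
#'
#' @inheritParams lsq_coefficients
#' @return Numeric vector of the same length as `signal`.
#' @export
lsq_project <- function(signal, degree = 3, m, boundary = "mirror") {
  lsq_reconstruct(lsq_coefficients(signal, degree, m, boundary))
}

#' Brute-force least-squares spline coefficients (normal-equation oracle)
#'
#' Forms the explicit design matrix of the folded, shifted, `m`-expanded
#' B-spline basis functions sampled on the signal lattice (same boundary
#' convention as the filtering path) and solves the normal equations
#' directly.  Exists as an independent cross-check of
#' [lsq_coefficients()]; quadratic memory, so guarded to
#' `N <= 1e5`, `M <= 1e3`.
#'
#' @inheritParams lsq_coefficients
#' @return Numeric coefficient vector of length `M`.
#' @export
brute_force_lsq <- function(signal, degree = 3, m, boundary = "mirror") {
  check_signal(signal)
  degree <- check_degree(degree); m <- check_m(m)
  boundary <- match_boundary(boundary)
  n <- length(signal)
  M <- knot_count(n, m)
  abort_if(n > 1e5 || M > 1e3,
           "brute_force_lsq size guard exceeded (N <= 1e5, M <= 1e3).")
  B <- matrix(0, n, M)
  for (k in seq_len(M)) {
    col <- folded_basis_column(degree, m, n, k, boundary)
    B[col$idx, k] <- col$val
  }
  as.numeric(solve(crossprod(B), crossprod(B, signal)))
}
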
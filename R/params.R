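#' Clamp a square-root equilibrium vector away from zero
#'
#' Entries of the square-root equilibrium vector smaller than `1e-10` are
#' replaced by `1e-10`; everything else passes through unchanged.  The
#' spectral transforms `A = diag(sqrt_pi)^{-1} B` and
#' `A^{-1} = B^T diag(sqrt_pi)` become ill-conditioned when a component of
#' `sqrt_pi` approaches zero, so the clamp keeps every downstream
#' eigendecomposition and back-substitution well behaved.
#'
#' @param raw Numeric vector of non-negative, finite values.
#' @return The clamped vector, with attribute `"clamped"` marking the
#'   coordinates that were raised to the floor.
#' @export
clamp_sqrt_pi <- function(raw) {
  if (!is.numeric(raw) || any(!is.finite(raw))) {
    stop("sqrt_pi entries must be finite numbers", call. = FALSE)
  }
  if (any(raw < 0)) {
    stop("sqrt_pi entries must be non-negative", call. = FALSE)
  }
  clamped <- raw < 1e-10
  out <- raw
  out[clamped] <- 1e-10
  attr(out, "clamped") <- clamped
  out
}

#' Parameters of a time-reversible substitution model
#'
#' A time-reversible rate matrix Q over `n` residues is parametrized by the
#' `n(n-1)/2` non-negative exchangeabilities `s_ij` (the upper triangle, in
#' row-major order, of the symmetrized generator `S = diag(sqrt_pi) Q
#' diag(sqrt_pi)^{-1}`) and the positive vector `sqrt_pi`, the
#' component-wise square root of an unnormalized equilibrium distribution.
#' The equilibrium distribution itself is derived by squaring and
#' normalizing, so `sqrt_pi` carries no sum constraint and the whole model
#' is invariant under positive rescaling of `sqrt_pi`.
#'
#' @param n State count (4 for nucleotides, 20 for amino acids; any n >= 2
#'   is accepted).
#' @param exch Numeric vector of `n(n-1)/2` non-negative exchangeabilities,
#'   upper triangle in row-major order: (1,2), (1,3), ..., (1,n), (2,3), ...
#' @param sqrt_pi Numeric vector of `n` non-negative values; entries below
#'   `1e-10` are clamped to `1e-10`.
#' @return An object of class `"reversible_params"`.
#' @examples
#' p <- reversible_params(4, exch = rep(1, 6), sqrt_pi = rep(0.5, 4))
#' stationary_distribution(p)
#' @export
reversible_params <- function(n, exch, sqrt_pi) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 2L) {
    stop("n must be a single integer >= 2", call. = FALSE)
  }
  k <- n * (n - 1L) / 2L
  exch <- as.numeric(exch)
  if (length(exch) != k) {
    stop(sprintf("exch must have length n(n-1)/2 = %d, got %d", k, length(exch)),
         call. = FALSE)
  }
  if (any(!is.finite(exch)) || any(exch < 0)) {
    stop("exchangeabilities must be finite and non-negative", call. = FALSE)
  }
  sqrt_pi <- as.numeric(sqrt_pi)
  if (length(sqrt_pi) != n) {
    stop(sprintf("sqrt_pi must have length n = %d", n), call. = FALSE)
  }
  sp <- clamp_sqrt_pi(sqrt_pi)
  structure(
    list(n = n, exch = as.numeric(exch), sqrt_pi = as.numeric(sp),
         clamped = attr(sp, "clamped")),
    class = "reversible_params"
  )
}

#' @export
print.reversible_params <- function(x, ...) {
  cat(sprintf("Time-reversible model parameters: n = %d states, %d exchangeabilities\n",
              x$n, length(x$exch)))
  cat("equilibrium:", format(stationary_distribution(x), digits = 4), "\n")
  invisible(x)
}

# upper-triangle (row-major) <-> symmetric matrix with zero diagonal
vec_to_sym <- function(exch, n) {
  m <- matrix(0, n, n)
  tm <- matrix(0, n, n)
  tm[lower.tri(tm)] <- exch   # column-major lower triangle == row-major upper
  m <- t(tm)
  m + tm
}

sym_to_vec <- function(m) {
  t(m)[lower.tri(m)]
}

#' Stationary distribution implied by the parameters
#'
#' `pi_i = sqrt_pi_i^2 / sum_k sqrt_pi_k^2`.  This is the left null vector
#' of the rate matrix and the root prior used by the likelihood engine.
#'
#' @param params A [reversible_params()] object.
#' @return Probability vector of length `n`.
#' @export
stationary_distribution <- function(params) {
  stopifnot(inherits(params, "reversible_params"))
  v2 <- params$sqrt_pi^2
  v2 / sum(v2)
}

#' Build the rate matrix Q from reversible parameters
#'
#' Off-diagonal rates are `q_ij = s_ij * sqrt_pi_j / sqrt_pi_i` (with
#' `s_ji = s_ij`); the diagonal is set so every row sums to zero.  The
#' resulting generator satisfies detailed balance
#' `pi_i q_ij = pi_j q_ji` by construction.
#'
#' @param params A [reversible_params()] object.
#' @return An `n x n` rate matrix of class `"rate_matrix"`.
#' @export
build_rate_matrix <- function(params) {
  stopifnot(inherits(params, "reversible_params"))
  n <- params$n
  v <- params$sqrt_pi
  s <- vec_to_sym(params$exch, n)
  q <- s * outer(1 / v, v)            # q_ij = s_ij v_j / v_i
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  class(q) <- c("rate_matrix", class(q))
  q
}

#' Overall substitution rate of the model
#'
#' The expected number of substitutions per unit time at equilibrium,
#' `mu = -sum_i pi_i q_ii = (2 / sum(sqrt_pi^2)) * sum_{i<j} s_ij
#' sqrt_pi_i sqrt_pi_j`.  Under rate normalization the model is rescaled so
#' that `mu = 1` and branch lengths are measured in expected substitutions
#' per site.  Gradients of `mu` with respect to both parameter blocks are
#' returned so fitting code can chain through the normalization.
#'
#' @param params A [reversible_params()] object.
#' @return List with elements `mu`, `d_exch` (gradient w.r.t. the
#'   exchangeabilities) and `d_sqrt_pi`.
#' @export
rate_scale <- function(params) {
  stopifnot(inherits(params, "reversible_params"))
  n <- params$n
  v <- params$sqrt_pi
  tot <- sum(v^2)
  s <- vec_to_sym(params$exch, n)
  vv <- outer(v, v)
  mu <- 2 * sum(sym_to_vec(s * vv)) / tot
  d_exch <- 2 * sym_to_vec(vv) / tot
  # d mu / d v_m = (2/T) sum_j s_mj v_j  - mu * 2 v_m / T
  d_sqrt_pi <- (2 / tot) * as.numeric(s %*% v) - mu * 2 * v / tot
  list(mu = mu, d_exch = d_exch, d_sqrt_pi = d_sqrt_pi)
}

#' Rescale parameters so the mean substitution rate is one
#'
#' Divides the exchangeabilities by the current [rate_scale()] so that
#' `-sum_i pi_i q_ii = 1`; `sqrt_pi` is untouched.
#'
#' @param params A [reversible_params()] object.
#' @return A rescaled `reversible_params` object.
#' @export
normalize_params <- function(params) {
  mu <- rate_scale(params)$mu
  if (mu <= 0) stop("cannot normalize a zero-rate model", call. = FALSE)
  reversible_params(params$n, params$exch / mu, params$sqrt_pi)
}

#' Spectral decomposition of the rate matrix
#'
#' The similarity transform `S_full = diag(sqrt_pi) Q diag(sqrt_pi)^{-1}`
#' is symmetric (its off-diagonal entries are the exchangeabilities, its
#' diagonal equals Q's), so it has an orthonormal eigendecomposition
#' `S_full = B Lambda B^T` with real eigenvalues.  Undoing the transform
#' gives `Q = A Lambda A^{-1}` with `A = diag(sqrt_pi)^{-1} B` and
#' `A^{-1} = B^T diag(sqrt_pi)`, i.e. a numerically stable diagonalization
#' of the (generally non-symmetric) generator without a general
#' eigensolver and without matrix inversion.
#'
#' @param params A [reversible_params()] object.
#' @return Object of class `"spectral_form"` with fields `eigvals`, `a`,
#'   `a_inv`, `sqrt_pi`, `q`.
#' @export
spectral_decompose <- function(params) {
  stopifnot(inherits(params, "reversible_params"))
  n <- params$n
  v <- params$sqrt_pi
  q <- build_rate_matrix(params)
  s_full <- vec_to_sym(params$exch, n)
  diag(s_full) <- diag(q)
  es <- tryCatch(eigen(s_full, symmetric = TRUE), error = function(e) {
    stop(sprintf("eigendecomposition failed (%s); exch = [%s], sqrt_pi = [%s]",
                 conditionMessage(e),
                 paste(signif(params$exch, 6), collapse = ", "),
                 paste(signif(v, 6), collapse = ", ")), call. = FALSE)
  })
  lam <- es$values
  if (max(lam) > 1e-8) {
    stop(sprintf("rate matrix has a positive eigenvalue (%.3e): not a proper generator",
                 max(lam)), call. = FALSE)
  }
  b <- es$vectors
  a <- b / v                               # diag(1/v) %*% B
  a_inv <- t(b) * rep(v, each = n)         # B^T %*% diag(v)
  structure(
    list(eigvals = lam, a = a, a_inv = a_inv, sqrt_pi = v,
         q = unclass(q), n = n),
    class = "spectral_form"
  )
}

#' @export
print.spectral_form <- function(x, ...) {
  cat(sprintf("Spectral form of a %d-state reversible generator\n", x$n))
  cat("eigenvalues:", format(x$eigvals, digits = 4), "\n")
  invisible(x)
}

#' Backpropagate a rate-matrix gradient to the free parameters
#'
#' Given `g_q = dL/dQ` (treating all n^2 entries as independent), applies
#' the chain rule through `q_ij = s_ij sqrt_pi_j / sqrt_pi_i` and the
#' zero-row-sum diagonal to obtain `dL/d exch` and `dL/d sqrt_pi`.  When
#' the objective also depends on the normalized equilibrium distribution
#' directly (the root prior of the likelihood), pass that contribution as
#' `g_pi = dL/d pi`; it is folded into `dL/d sqrt_pi` through
#' `pi_i = sqrt_pi_i^2 / sum_k sqrt_pi_k^2`.
#'
#' Gradients at clamped `sqrt_pi` coordinates are zeroed (the clamp is
#' flat, so the subgradient 0 is used).
#'
#' @param g_q `n x n` numeric matrix, the gradient with respect to Q.
#' @param params The [reversible_params()] the matrix was built from.
#' @param g_pi Optional length-`n` gradient with respect to the normalized
#'   equilibrium distribution.
#' @return List with `g_exch` and `g_sqrt_pi`.
#' @export
backprop_params <- function(g_q, params, g_pi = NULL) {
  stopifnot(inherits(params, "reversible_params"))
  n <- params$n
  if (!is.matrix(g_q) || any(dim(g_q) != n)) {
    stop("g_q must be an n x n matrix", call. = FALSE)
  }
  if (any(!is.finite(g_q))) stop("g_q must be finite", call. = FALSE)
  v <- params$sqrt_pi
  s <- vec_to_sym(params$exch, n)
  # effective off-diagonal weight: dq_ii = -sum_{j != i} dq_ij
  h <- sweep(g_q, 1, diag(g_q), "-")
  r <- outer(1 / v, v)                 # v_j / v_i
  gs_full <- h * r
  diag(gs_full) <- 0
  g_exch <- sym_to_vec(gs_full + t(gs_full))
  term1 <- colSums((h * s) / v)                     # sum_i h_im s_im / v_i
  term2 <- rowSums(sweep(h * s, 2, v, "*")) / v^2   # sum_j h_mj s_mj v_j / v_m^2
  g_v <- term1 - term2
  if (!is.null(g_pi)) {
    if (length(g_pi) != n) stop("g_pi must have length n", call. = FALSE)
    tot <- sum(v^2)
    pi <- v^2 / tot
    g_v <- g_v + (2 * v / tot) * (g_pi - sum(g_pi * pi))
  }
  g_v[params$clamped] <- 0
  list(g_exch = g_exch, g_sqrt_pi = g_v)
}
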
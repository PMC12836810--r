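# sinch(z) = sinh(z)/z with sinch(0) = 1; series below 1e-5 keeps full
# double precision through the removable singularity.
sinch <- function(z) {
  out <- z
  small <- abs(z) < 1e-5
  zs <- z[small]
  out[small] <- 1 + zs^2 / 6 * (1 + zs^2 / 20)
  zl <- z[!small]
  out[!small] <- sinh(zl) / zl
  out
}

#' Divided-difference matrix of the scalar exponential
#'
#' For eigenvalues `lambda` and time `t`, returns the matrix
#' `X(Lambda, t)` with diagonal `t * exp(t lambda_i)` and off-diagonal
#' entries equal to the first divided difference
#' `(exp(t lambda_i) - exp(t lambda_j)) / (lambda_i - lambda_j)`.
#' This is the Hadamard factor in both the forward Fréchet derivative and
#' the reverse-mode adjoint of the matrix exponential.
#'
#' The naive quotient loses all significant digits when two eigenvalues
#' nearly coincide.  Here every entry is evaluated through the identical
#' symmetric form
#' `exp(t (lambda_i + lambda_j) / 2) * t * sinch(t (lambda_i - lambda_j) / 2)`,
#' which is continuous in the eigenvalue gap and accurate for gaps of any
#' size, including exact ties (where it reduces to the diagonal formula).
#' A guard switches to the plain quotient only when `t * gap / 2`
#' exceeds 350, where `sinh` would overflow while the quotient is exact
#' to machine precision.
#'
#' @param eigvals Real eigenvalues (non-positive for a proper generator).
#' @param t Non-negative time (branch length).
#' @return Symmetric `n x n` matrix of class `"phi_matrix"` with
#'   attribute `"t"`.
#' @export
phi_matrix <- function(eigvals, t) {
  structure(phi_core(eigvals, t), t = t,
            class = c("phi_matrix", "matrix", "array"))
}

# bare divided-difference matrix, attribute-free for internal algebra
phi_core <- function(eigvals, t) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0) {
    stop("t must be a single finite non-negative number", call. = FALSE)
  }
  if (any(!is.finite(eigvals))) stop("eigenvalues must be finite", call. = FALSE)
  lam <- as.numeric(eigvals)
  mid <- outer(lam, lam, "+") / 2
  gap <- outer(lam, lam, "-") / 2
  x <- exp(t * mid) * t * sinch(t * gap)
  big <- t * abs(gap) > 350
  if (any(big)) {
    ei <- exp(t * lam)
    num <- outer(ei, ei, "-")
    x[big] <- (num / (2 * gap))[big]
  }
  x
}

#' Transition matrix from the spectral form
#'
#' `P(t) = e^{Qt} = A diag(exp(lambda_i t)) A^{-1}`: one vector of scalar
#' exponentials and two matrix multiplications per branch length, reusing
#' the single eigendecomposition of Q.  Tiny negative entries caused by
#' round-off (above -1e-10) are clipped to zero; more negative entries
#' signal a failed decomposition and raise an error.
#'
#' @param spec A [spectral_decompose()] result.
#' @param t Non-negative branch length (expected substitutions per site).
#' @return Row-stochastic `n x n` matrix.
#' @export
expm_spectral <- function(spec, t) {
  stopifnot(inherits(spec, "spectral_form"))
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0) {
    stop("t must be a single finite non-negative number", call. = FALSE)
  }
  p <- spec$a %*% (exp(spec$eigvals * t) * spec$a_inv)
  neg <- p < 0
  if (any(neg)) {
    if (min(p) < -1e-8) {
      stop(sprintf("transition matrix entry %.3e below -1e-8: numerical failure",
                   min(p)), call. = FALSE)
    }
    p[neg] <- 0
  }
  p[p > 1] <- 1
  p
}

#' Forward-mode (Fréchet) derivative of the matrix exponential
#'
#' The directional derivative of `Q -> e^{Qt}` along a perturbation
#' `d_q = dQ/d theta_u`:
#' `A (A^{-1} d_q A ⊙ X(Lambda, t)) A^{-1}`, linear in `d_q`.
#'
#' @param spec A [spectral_decompose()] result.
#' @param d_q `n x n` perturbation direction.
#' @param t Non-negative branch length.
#' @return `n x n` matrix `d e^{Qt} / d theta_u`.
#' @export
frechet_forward <- function(spec, d_q, t) {
  stopifnot(inherits(spec, "spectral_form"))
  n <- spec$n
  if (!is.matrix(d_q) || any(dim(d_q) != n)) {
    stop("d_q must be n x n", call. = FALSE)
  }
  x <- phi_core(spec$eigvals, t)
  spec$a %*% ((spec$a_inv %*% d_q %*% spec$a) * x) %*% spec$a_inv
}

#' Reverse-mode adjoint of the matrix exponential
#'
#' Carries a gradient with respect to the transition matrix back to a
#' gradient with respect to the rate matrix:
#' `dL/dQ = A^{-T} (A^T g_p A^{-T} ⊙ X(Lambda, t)) A^T`,
#' four matrix multiplications for any `t`.  This map is the transpose of
#' [frechet_forward()] under the trace inner product
#' `<M, N> = Tr(M^T N)`.
#'
#' @param spec A [spectral_decompose()] result.
#' @param g_p `n x n` gradient `dL/d e^{Qt}`.
#' @param t Non-negative branch length.
#' @return `n x n` matrix `dL/dQ`.
#' @export
expm_adjoint <- function(spec, g_p, t) {
  inner <- expm_adjoint_inner(spec, g_p, t)
  t(spec$a_inv) %*% inner %*% t(spec$a)
}

#' Inner factor of the matrix-exponential adjoint
#'
#' Returns only `A^T g_p A^{-T} ⊙ X(Lambda, t)`.  When many branches
#' share one rate matrix, the per-branch inner factors can be summed and
#' the two outermost multiplications `A^{-T} (.) A^T` applied once per
#' model rather than once per branch.
#'
#' @inheritParams expm_adjoint
#' @return `n x n` matrix.
#' @export
expm_adjoint_inner <- function(spec, g_p, t) {
  stopifnot(inherits(spec, "spectral_form"))
  n <- spec$n
  if (!is.matrix(g_p) || any(dim(g_p) != n)) {
    stop("g_p must be n x n", call. = FALSE)
  }
  if (any(!is.finite(g_p))) stop("g_p must be finite", call. = FALSE)
  x <- phi_core(spec$eigvals, t)
  (t(spec$a) %*% g_p %*% t(spec$a_inv)) * x
}
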
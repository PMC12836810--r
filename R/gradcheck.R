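#' Finite-difference gradients (test oracle)
#'
#' Central finite differences of the total log likelihood with respect to
#' every exchangeability, every `sqrt_pi` coordinate, and every branch
#' length.  O(#parameters) likelihood evaluations — this is the slow path
#' the reverse pass replaces, provided for verification only.
#'
#' @inheritParams pruning_forward
#' @param step Central-difference step (parameters are O(1)).
#' @return List of per-model `g_exch` / `g_sqrt_pi` and per-branch `g_t`,
#'   shaped like the analytic [reverse_pass()] output.
#' @export
fd_gradients <- function(tree, profiles, models, weights = NULL, step = 1e-6) {
  tree <- as_phylo_tree(tree)
  C <- profiles$n_col
  if (is.null(weights)) weights <- rep(1, C)
  eval_ll <- function(params_list, blen) {
    tr <- tree
    tr$blen <- blen
    m <- column_models(params_list, models$assignment)
    pruning_forward(tr, profiles, m, weights)$loglik
  }
  per_model <- list()
  for (mi in seq_along(models$params)) {
    p <- models$params[[mi]]
    k <- length(p$exch)
    g_exch <- numeric(k)
    for (j in seq_len(k)) {
      up <- p$exch; up[j] <- up[j] + step
      dn <- p$exch; dn[j] <- max(dn[j] - step, 0)
      h2 <- up[j] - dn[j]
      pl_up <- models$params; pl_up[[mi]] <- reversible_params(p$n, up, p$sqrt_pi)
      pl_dn <- models$params; pl_dn[[mi]] <- reversible_params(p$n, dn, p$sqrt_pi)
      g_exch[j] <- (eval_ll(pl_up, tree$blen) - eval_ll(pl_dn, tree$blen)) / h2
    }
    g_v <- numeric(p$n)
    for (j in seq_len(p$n)) {
      up <- p$sqrt_pi; up[j] <- up[j] + step
      dn <- p$sqrt_pi; dn[j] <- dn[j] - step
      pl_up <- models$params; pl_up[[mi]] <- reversible_params(p$n, p$exch, up)
      pl_dn <- models$params; pl_dn[[mi]] <- reversible_params(p$n, p$exch, dn)
      g_v[j] <- (eval_ll(pl_up, tree$blen) - eval_ll(pl_dn, tree$blen)) / (2 * step)
    }
    per_model[[mi]] <- list(g_exch = g_exch, g_sqrt_pi = g_v)
  }
  g_t <- rep(NA_real_, tree$n_node)
  for (u in seq_len(tree$n_node)) {
    if (u == tree$root) next
    up <- tree$blen; up[u] <- up[u] + step
    dn <- tree$blen; dn[u] <- max(dn[u] - step, 0)
    g_t[u] <- (eval_ll(models$params, up) - eval_ll(models$params, dn)) /
      (up[u] - dn[u])
  }
  list(models = per_model, g_t = g_t)
}

#' Compare analytic and finite-difference gradients
#'
#' Runs [loglik_and_grad()] and [fd_gradients()] on the same inputs and
#' reports the worst discrepancy over all gradient components.  Each
#' component is compared relative to `max(|fd|, 1)`: components of
#' magnitude one or more are held to a relative tolerance, near-zero
#' components to the same tolerance in absolute terms (a central
#' difference of a log likelihood carries round-off noise of order
#' `eps * |L| / step`, so a purely relative comparison of a tiny
#' component measures the oracle, not the gradient).
#'
#' @inheritParams fd_gradients
#' @return List with `max_rel_err` and the per-block errors.
#' @export
gradient_check <- function(tree, profiles, models, weights = NULL, step = 1e-6) {
  an <- loglik_and_grad(tree, profiles, models, weights = weights)
  fd <- fd_gradients(tree, profiles, models, weights = weights, step = step)
  rel <- function(a, f) abs(a - f) / pmax(abs(f), 1)
  errs <- list()
  for (mi in seq_along(models$params)) {
    errs[[mi]] <- c(
      exch = max(rel(an$models[[mi]]$g_exch, fd$models[[mi]]$g_exch)),
      sqrt_pi = max(rel(an$models[[mi]]$g_sqrt_pi, fd$models[[mi]]$g_sqrt_pi)))
  }
  keep <- !is.na(fd$g_t)
  err_t <- max(rel(an$g_t[keep], fd$g_t[keep]))
  list(max_rel_err = max(c(unlist(errs), err_t)),
       per_model = errs, branch = err_t, loglik = an$loglik)
}
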
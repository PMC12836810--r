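#' Map alignment columns to substitution models
#'
#' Holds a table of [reversible_params()] and an assignment from column
#' index to table entry.  A table of size one with no assignment is the
#' global-model case; a table with one entry per column gives fully
#' column-specific rate matrices; anything in between (shared matrices for
#' groups of columns) also works.
#'
#' @param params A single [reversible_params()] or a list of them.
#' @param assignment Optional integer vector, one entry per alignment
#'   column, indexing into the model table.  Default: all columns use
#'   model 1.
#' @return Object of class `"column_models"`.
#' @export
column_models <- function(params, assignment = NULL) {
  if (inherits(params, "reversible_params")) params <- list(params)
  if (!length(params) || !all(vapply(params, inherits, TRUE, "reversible_params"))) {
    stop("params must be reversible_params objects", call. = FALSE)
  }
  ns <- vapply(params, function(p) p$n, integer(1))
  if (length(unique(ns)) != 1L) stop("all models must share one state count", call. = FALSE)
  if (!is.null(assignment)) {
    assignment <- as.integer(assignment)
    if (any(is.na(assignment)) || any(assignment < 1L) ||
        any(assignment > length(params))) {
      stop("assignment indexes outside the model table", call. = FALSE)
    }
  }
  structure(list(params = params, assignment = assignment, n = ns[1]),
            class = "column_models")
}

#' @export
print.column_models <- function(x, ...) {
  cat(sprintf("column_models: %d model(s), %d states%s\n", length(x$params), x$n,
              if (is.null(x$assignment)) " (global)" else
                sprintf(", %d assigned columns", length(x$assignment))))
  invisible(x)
}

resolve_assignment <- function(models, n_col) {
  a <- models$assignment
  if (is.null(a)) a <- rep(1L, n_col)
  if (length(a) == 1L) a <- rep(a, n_col)
  if (length(a) != n_col) {
    stop(sprintf("model assignment has length %d but alignment has %d columns",
                 length(a), n_col), call. = FALSE)
  }
  a
}

# precompute everything reused across branches for one model
prepare_model <- function(params) {
  spec <- spectral_decompose(params)
  list(params = params, spec = spec, q = spec$q,
       pi = stationary_distribution(params))
}

check_taxa <- function(tree, profiles) {
  if (!setequal(tree$tip_labels, profiles$taxa)) {
    stop("taxon names in tree and profiles do not match; tree-only: [",
         paste(setdiff(tree$tip_labels, profiles$taxa), collapse = ", "),
         "], profile-only: [",
         paste(setdiff(profiles$taxa, tree$tip_labels), collapse = ", "), "]",
         call. = FALSE)
  }
}

# Forward pruning over one block of columns that share a model.  All
# column-wise work is n x C matrix algebra, so a block is one pass of
# small dense products regardless of the number of columns.
forward_block <- function(tree, profiles, model, cols) {
  n <- model$params$n
  C <- length(cols)
  spec <- model$spec
  lp <- vector("list", tree$n_node)
  P <- vector("list", tree$n_node)
  e <- vector("list", tree$n_node)
  pe <- vector("list", tree$n_node)
  for (u in tree$postorder) {
    if (u <= tree$n_tip) {
      lp_u <- log(profiles$x[[tree$tip_labels[u]]][, cols, drop = FALSE])
      lp[[u]] <- lp_u
    } else {
      if (is.null(lp[[u]])) lp[[u]] <- matrix(0, n, C)
      lp_u <- lp[[u]]
    }
    if (any(is.nan(lp_u))) stop("non-finite partial likelihood", call. = FALSE)
    if (u == tree$root) next
    Pu <- expm_spectral(spec, tree$blen[u])
    sh <- apply(lp_u, 2, max)
    sh[!is.finite(sh)] <- 0
    eu <- exp(sweep(lp_u, 2, sh, "-"))
    peu <- Pu %*% eu
    m_u <- sweep(log(peu), 2, sh, "+")
    P[[u]] <- Pu; e[[u]] <- eu; pe[[u]] <- peu
    p <- tree$parent[u]
    if (is.null(lp[[p]])) lp[[p]] <- matrix(0, n, C)
    lp[[p]] <- lp[[p]] + m_u
  }
  z <- log(model$pi) + lp[[tree$root]]
  sh <- apply(z, 2, max)
  sh[!is.finite(sh)] <- 0
  col_loglik <- log(colSums(exp(sweep(z, 2, sh, "-")))) + sh
  list(cols = cols, z = z, col_loglik = col_loglik,
       P = P, e = e, pe = pe)
}

# Reverse sweep over one forward block: per-edge dL/dP via the logsumexp
# recursions, accumulated into the shared inner adjoint factor (one outer
# transform per model), plus per-branch dL/dt and the root-prior dL/dpi.
reverse_block <- function(tree, model, fwd, weights) {
  n <- model$params$n
  spec <- model$spec
  at <- t(spec$a)
  ainv_t <- t(spec$a_inv)
  if (any(!is.finite(fwd$col_loglik))) {
    stop("column log likelihood is -Inf: gradients undefined", call. = FALSE)
  }
  r <- exp(sweep(fwd$z, 2, fwd$col_loglik, "-"))      # root-state posteriors
  rw <- sweep(r, 2, weights, "*")
  g <- vector("list", tree$n_node)
  g[[tree$root]] <- rw
  g_pi <- rowSums(rw) / model$pi
  inner <- matrix(0, n, n)
  g_t <- rep(NA_real_, tree$n_node)
  for (v in tree$preorder) {
    if (v <= tree$n_tip) next
    gv <- g[[v]]
    g[[v]] <- NA  # free
    for (u in tree$children[[v]]) {
      w <- gv / fwd$pe[[u]]
      w[gv == 0] <- 0
      w[!is.finite(w)] <- 0
      gp <- tcrossprod(w, fwd$e[[u]])                 # sum_c outer(w_c, e_c)
      inner <- inner + (at %*% gp %*% ainv_t) *
        phi_core(spec$eigvals, tree$blen[u])
      g_t[u] <- sum(gp * (model$q %*% fwd$P[[u]]))
      if (u > tree$n_tip) g[[u]] <- fwd$e[[u]] * crossprod(fwd$P[[u]], w)
    }
  }
  g_q <- ainv_t %*% inner %*% at
  list(g_q = g_q, g_pi = g_pi, g_t = g_t,
       loglik = sum(weights * fwd$col_loglik))
}

#' Forward pruning pass
#'
#' Computes per-column log likelihoods by post-order dynamic programming
#' over the tree.  Partial likelihoods are kept in log space and combined
#' with logsumexp, so deep trees and many columns cannot underflow.  The
#' returned cache stores the per-node partials and per-edge transition
#' matrices needed by [reverse_pass()].
#'
#' @param tree A [as_phylo_tree()] object.
#' @param profiles A [leaf_profiles()] object whose taxa match the tree's
#'   tip labels.
#' @param models A [column_models()] object.
#' @param weights Optional per-column positive weights (pattern
#'   multiplicities from [compress_columns()]); default 1.
#' @return Object of class `"pruning_cache"`; fields `col_loglik` and
#'   `loglik` hold the per-column and total (weighted) log likelihood.
#' @export
pruning_forward <- function(tree, profiles, models, weights = NULL) {
  tree <- as_phylo_tree(tree)
  stopifnot(inherits(profiles, "leaf_profiles"), inherits(models, "column_models"))
  if (profiles$n != models$n) {
    stop("state count of profiles and models differ", call. = FALSE)
  }
  check_taxa(tree, profiles)
  C <- profiles$n_col
  if (is.null(weights)) weights <- rep(1, C)
  if (length(weights) != C || any(weights <= 0)) {
    stop("weights must be positive, one per column", call. = FALSE)
  }
  assignment <- resolve_assignment(models, C)
  used <- sort(unique(assignment))
  prepared <- vector("list", length(models$params))
  blocks <- list()
  col_loglik <- numeric(C)
  for (m in used) {
    prepared[[m]] <- prepare_model(models$params[[m]])
    cols <- which(assignment == m)
    fwd <- forward_block(tree, profiles, prepared[[m]], cols)
    col_loglik[cols] <- fwd$col_loglik
    blocks[[length(blocks) + 1L]] <- list(model_idx = m, fwd = fwd)
  }
  structure(
    list(tree = tree, models = models, prepared = prepared, blocks = blocks,
         weights = weights, col_loglik = col_loglik,
         loglik = sum(weights * col_loglik)),
    class = "pruning_cache"
  )
}

new_gradient_bundle <- function(loglik, col_loglik, per_model, g_t) {
  structure(list(loglik = loglik, col_loglik = col_loglik,
                 models = per_model, g_t = g_t),
            class = "gradient_bundle")
}

#' @export
print.gradient_bundle <- function(x, ...) {
  cat(sprintf("gradient_bundle: loglik = %.6f, %d model(s), %d branch gradients\n",
              x$loglik, length(x$models), sum(!is.na(x$g_t))))
  invisible(x)
}

#' Reverse pass: gradients of the log likelihood
#'
#' Backpropagates through the logsumexp pruning recursions in one
#' pre-order sweep per column block (linear in the number of nodes),
#' producing `dL/dP` for every edge.  Per-edge contributions are converted
#' to `dL/dQ` through the inner adjoint factor of the matrix exponential,
#' summed over the edges sharing a model, with the two outermost
#' multiplications applied once per model.  Branch-length gradients are
#' `dL/dt_e = <dL/dP(t_e), Q P(t_e)>` under the trace inner product, and
#' the root-prior term `dL/dpi` is folded into the `sqrt_pi` gradient by
#' [backprop_params()].
#'
#' @param cache A [pruning_forward()] result.
#' @return A `"gradient_bundle"`: `loglik`, `col_loglik`, per-model
#'   `g_q` / `g_exch` / `g_sqrt_pi` / `g_pi`, and per-branch `g_t`
#'   (indexed by child node, `NA` at the root).
#' @export
reverse_pass <- function(cache) {
  stopifnot(inherits(cache, "pruning_cache"))
  tree <- cache$tree
  n_models <- length(cache$models$params)
  n <- cache$models$n
  per_model <- replicate(n_models, NULL, simplify = FALSE)
  g_t <- rep(NA_real_, tree$n_node)
  g_t[-tree$root] <- 0
  for (blk in cache$blocks) {
    m <- blk$model_idx
    model <- cache$prepared[[m]]
    rev <- reverse_block(tree, model, blk$fwd, cache$weights[blk$fwd$cols])
    if (is.null(per_model[[m]])) {
      per_model[[m]] <- list(g_q = rev$g_q, g_pi = rev$g_pi)
    } else {
      per_model[[m]]$g_q <- per_model[[m]]$g_q + rev$g_q
      per_model[[m]]$g_pi <- per_model[[m]]$g_pi + rev$g_pi
    }
    ge <- g_t[-tree$root]
    add <- rev$g_t[-tree$root]
    g_t[-tree$root] <- ge + add
  }
  for (m in seq_len(n_models)) {
    if (is.null(per_model[[m]])) {
      k <- n * (n - 1L) / 2L
      per_model[[m]] <- list(g_q = matrix(0, n, n), g_pi = numeric(n),
                             g_exch = numeric(k), g_sqrt_pi = numeric(n))
    } else {
      bp <- backprop_params(per_model[[m]]$g_q, cache$models$params[[m]],
                            per_model[[m]]$g_pi)
      per_model[[m]]$g_exch <- bp$g_exch
      per_model[[m]]$g_sqrt_pi <- bp$g_sqrt_pi
    }
  }
  new_gradient_bundle(cache$loglik, cache$col_loglik, per_model, g_t)
}

#' Log likelihood and all gradients in one call
#'
#' Composition of [pruning_forward()] and [reverse_pass()].  Work is
#' partitioned into fixed-size column chunks (within each model block) and
#' the chunks are reduced in deterministic order, so the result is
#' identical for any `threads` value; `threads > 1` distributes chunks
#' over forked workers.
#'
#' @inheritParams pruning_forward
#' @param threads Number of worker processes for column-parallel
#'   evaluation (forked; falls back to serial on Windows).
#' @param chunk_size Columns per work unit.  Fixed independently of
#'   `threads` so the floating-point reduction order never changes.
#' @return A `"gradient_bundle"` as from [reverse_pass()].
#' @export
loglik_and_grad <- function(tree, profiles, models, weights = NULL,
                            threads = 1L, chunk_size = 512L) {
  tree <- as_phylo_tree(tree)
  stopifnot(inherits(profiles, "leaf_profiles"), inherits(models, "column_models"))
  check_taxa(tree, profiles)
  C <- profiles$n_col
  if (is.null(weights)) weights <- rep(1, C)
  assignment <- resolve_assignment(models, C)
  n <- models$n
  k <- n * (n - 1L) / 2L
  units <- list()
  for (m in sort(unique(assignment))) {
    cols <- which(assignment == m)
    starts <- seq(1L, length(cols), by = chunk_size)
    for (s in starts) {
      idx <- cols[s:min(s + chunk_size - 1L, length(cols))]
      units[[length(units) + 1L]] <- list(model_idx = m, cols = idx)
    }
  }
  prepared <- vector("list", length(models$params))
  for (m in sort(unique(assignment))) prepared[[m]] <- prepare_model(models$params[[m]])
  run_unit <- function(un) {
    model <- prepared[[un$model_idx]]
    fwd <- forward_block(tree, profiles, model, un$cols)
    rev <- reverse_block(tree, model, fwd, weights[un$cols])
    list(model_idx = un$model_idx, cols = un$cols,
         col_loglik = fwd$col_loglik, g_q = rev$g_q, g_pi = rev$g_pi,
         g_t = rev$g_t)
  }
  threads <- max(1L, as.integer(threads))
  if (threads > 1L && .Platform$OS.type != "windows") {
    results <- parallel::mclapply(units, run_unit, mc.cores = threads,
                                  mc.preschedule = TRUE)
  } else {
    results <- lapply(units, run_unit)
  }
  col_loglik <- numeric(C)
  per_model <- replicate(length(models$params), NULL, simplify = FALSE)
  g_t <- rep(NA_real_, tree$n_node)
  g_t[-tree$root] <- 0
  for (res in results) {     # fixed unit order: deterministic reduction
    if (inherits(res, "try-error") || is.null(res$cols)) {
      stop("parallel worker failed: ", paste(res, collapse = " "), call. = FALSE)
    }
    col_loglik[res$cols] <- res$col_loglik
    m <- res$model_idx
    if (is.null(per_model[[m]])) {
      per_model[[m]] <- list(g_q = res$g_q, g_pi = res$g_pi)
    } else {
      per_model[[m]]$g_q <- per_model[[m]]$g_q + res$g_q
      per_model[[m]]$g_pi <- per_model[[m]]$g_pi + res$g_pi
    }
    g_t[-tree$root] <- g_t[-tree$root] + res$g_t[-tree$root]
  }
  for (m in seq_along(per_model)) {
    if (is.null(per_model[[m]])) {
      per_model[[m]] <- list(g_q = matrix(0, n, n), g_pi = numeric(n),
                             g_exch = numeric(k), g_sqrt_pi = numeric(n))
    } else {
      bp <- backprop_params(per_model[[m]]$g_q, models$params[[m]],
                            per_model[[m]]$g_pi)
      per_model[[m]]$g_exch <- bp$g_exch
      per_model[[m]]$g_sqrt_pi <- bp$g_sqrt_pi
    }
  }
  new_gradient_bundle(sum(weights * col_loglik), col_loglik, per_model, g_t)
}

#' Brute-force likelihood by ancestral-state enumeration
#'
#' Sums the equilibrium-weighted product of transition probabilities over
#' every assignment of states to the internal nodes.  Exponential in the
#' number of internal nodes, so it is restricted to small trees; it exists
#' as an independent check of the pruning recursion.
#'
#' @param tree A [as_phylo_tree()] object with at most 7 leaves.
#' @param profiles A [leaf_profiles()] object.
#' @param params A single [reversible_params()] used for every column.
#' @return Numeric vector of per-column log likelihoods.
#' @export
brute_force_likelihood <- function(tree, profiles, params) {
  tree <- as_phylo_tree(tree)
  if (tree$n_tip > 7) stop("brute-force enumeration limited to 7 leaves", call. = FALSE)
  check_taxa(tree, profiles)
  spec <- spectral_decompose(params)
  pi <- stationary_distribution(params)
  n <- params$n
  P <- vector("list", tree$n_node)
  for (u in seq_len(tree$n_node)) {
    if (u != tree$root) P[[u]] <- expm_spectral(spec, tree$blen[u])
  }
  internals <- (tree$n_tip + 1L):tree$n_node
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), length(internals))))
  C <- profiles$n_col
  out <- numeric(C)
  for (cc in seq_len(C)) {
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      st <- grid[g, ]
      p <- pi[st[match(tree$root, internals)]]
      for (u in seq_len(tree$n_node)) {
        if (u == tree$root) next
        a <- st[match(tree$parent[u], internals)]
        if (u <= tree$n_tip) {
          prof <- profiles$x[[tree$tip_labels[u]]][, cc]
          p <- p * sum(P[[u]][a, ] * prof)
        } else {
          p <- p * P[[u]][a, st[match(u, internals)]]
        }
      }
      tot <- tot + p
    }
    out[cc] <- log(tot)
  }
  out
}
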
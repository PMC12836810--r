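#' Random tree by sequential coalescence
#'
#' Starting from `num_taxa` lineages, repeatedly joins a uniformly random
#' pair under a new parent until one lineage remains; every edge then
#' receives an independent exponential branch length with the given mean.
#' This yields exchangeable random bifurcating topologies; the likelihood
#' engine itself is topology-agnostic, so nothing downstream depends on
#' this particular law.
#'
#' @param num_taxa Number of leaves (>= 2), labelled `t1 ... tN`.
#' @param branch_length_mean Mean of the exponential branch-length
#'   distribution, in expected substitutions per site.
#' @param seed Integer seed; the tree is a deterministic function of it.
#' @return A [as_phylo_tree()] object (the underlying `ape::phylo` is in
#'   field `phy`).
#' @export
random_tree <- function(num_taxa, branch_length_mean = 0.1, seed) {
  num_taxa <- as.integer(num_taxa)
  if (num_taxa < 2L) stop("num_taxa must be >= 2", call. = FALSE)
  if (branch_length_mean <= 0) stop("branch_length_mean must be positive", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  n_int <- num_taxa - 1L
  # tips 1..N; internal nodes numbered N+2, N+3, ... in join order except
  # the final join, which becomes the root N+1 (ape convention)
  active <- seq_len(num_taxa)
  next_id <- num_taxa + 2L
  edges <- matrix(0L, nrow = 2L * n_int, ncol = 2L)
  k <- 0L
  for (j in seq_len(n_int)) {
    pick <- sample.int(length(active), 2L)
    pair <- active[pick]
    parent <- if (j == n_int) num_taxa + 1L else next_id
    next_id <- next_id + 1L
    edges[k + 1L, ] <- c(parent, pair[1]); edges[k + 2L, ] <- c(parent, pair[2])
    k <- k + 2L
    active <- c(active[-pick], parent)
  }
  phy <- structure(
    list(edge = edges,
         edge.length = stats::rexp(nrow(edges), rate = 1 / branch_length_mean),
         tip.label = paste0("t", seq_len(num_taxa)),
         Nnode = n_int),
    class = "phylo", order = "cladewise")
  as_phylo_tree(phy)
}

#' Simulate an alignment along a tree under the CTMC model
#'
#' For every column, draws the root state from the equilibrium
#' distribution of the column's model and propagates states down the tree,
#' sampling each child from the parent's row of `P(t_edge) = e^{Q t}`.
#' Leaves are returned both as residue characters and as one-hot profiles.
#'
#' @param tree A [as_phylo_tree()] object (or `ape::phylo`).
#' @param models A [column_models()] object; its assignment (or
#'   `n_columns`) fixes the number of simulated columns.
#' @param seed Integer seed; output is a deterministic function of
#'   (tree, models, seed).
#' @param n_columns Number of columns when `models` has no per-column
#'   assignment.
#' @return List with `chars` (taxa x columns character matrix),
#'   `profiles` ([leaf_profiles()]), `states` (node x column integer
#'   states) and `alphabet`.
#' @export
simulate_alignment <- function(tree, models, seed, n_columns = NULL) {
  tree <- as_phylo_tree(tree)
  stopifnot(inherits(models, "column_models"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  n <- models$n
  if (is.null(models$assignment)) {
    if (is.null(n_columns)) stop("supply n_columns for a global model", call. = FALSE)
    assignment <- rep(1L, n_columns)
  } else {
    assignment <- models$assignment
    if (!is.null(n_columns) && n_columns != length(assignment)) {
      stop("n_columns conflicts with the model assignment length", call. = FALSE)
    }
  }
  C <- length(assignment)
  alphabet <- residue_alphabet(if (n == 4) "dna" else "aa")
  if (n != alphabet$n) stop("only n = 4 or n = 20 alignments can be emitted", call. = FALSE)
  states <- matrix(0L, tree$n_node, C)
  used <- sort(unique(assignment))
  prepared <- vector("list", length(models$params))
  for (m in used) prepared[[m]] <- prepare_model(models$params[[m]])
  # root states, per model block in fixed column order
  for (m in used) {
    cols <- which(assignment == m)
    states[tree$root, cols] <- sample.int(n, length(cols), replace = TRUE,
                                          prob = prepared[[m]]$pi)
  }
  P <- lapply(seq_len(tree$n_node), function(u) {
    if (u == tree$root) return(NULL)
    lapply(prepared, function(pm) {
      if (is.null(pm)) NULL else expm_spectral(pm$spec, tree$blen[u])
    })
  })
  for (u in tree$preorder) {
    if (u == tree$root) next
    pa <- states[tree$parent[u], ]
    for (m in used) {
      Pm <- P[[u]][[m]]
      cols_m <- which(assignment == m)
      for (a in seq_len(n)) {
        sel <- cols_m[pa[cols_m] == a]
        if (length(sel)) {
          states[u, sel] <- sample.int(n, length(sel), replace = TRUE,
                                       prob = Pm[a, ])
        }
      }
    }
  }
  chars <- matrix("", tree$n_tip, C,
                  dimnames = list(tree$tip_labels, NULL))
  for (u in seq_len(tree$n_tip)) {
    chars[tree$tip_labels[u], ] <- alphabet$letters[states[u, ]]
  }
  list(chars = chars, profiles = profiles_from_chars(chars, alphabet),
       states = states, alphabet = alphabet)
}

#' A fixed 20-state reversible test model (synthetic)
#'
#' A seeded random amino-acid exchangeability/frequency set, rate
#' normalized, shipped as the package's standard 20-state test model.  It
#' is synthetic: it is not any empirically estimated matrix, merely a
#' generic well-conditioned reversible generator of realistic shape
#' (log-normal exchangeabilities, Dirichlet-like frequencies).
#'
#' @return A [reversible_params()] object with `n = 20`.
#' @export
synthetic_aa_model <- function() {
  state <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(state)) assign(".Random.seed", state, envir = globalenv()))
  set.seed(20200526L)
  s <- exp(stats::rnorm(190, sd = 1.2))
  v <- sqrt(stats::rgamma(20, shape = 2, rate = 1))
  normalize_params(reversible_params(20L, s, v / sqrt(sum(v^2))))
}

#' Draw random reversible model parameters
#'
#' Log-normal exchangeabilities and gamma-derived equilibrium frequencies,
#' optionally rate normalized.  Used throughout the test-bed to generate
#' well-conditioned generic models.
#'
#' @param n State count.
#' @param seed Integer seed.
#' @param normalize Rescale so the mean substitution rate is 1.
#' @return A [reversible_params()] object.
#' @export
random_reversible_params <- function(n, seed, normalize = TRUE) {
  set.seed(as.integer(seed))
  k <- n * (n - 1L) / 2L
  s <- exp(stats::rnorm(k, sd = 1))
  v <- sqrt(stats::rgamma(n, shape = 5, rate = 1))
  p <- reversible_params(n, s, v / sqrt(sum(v^2)))
  if (normalize) normalize_params(p) else p
}
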
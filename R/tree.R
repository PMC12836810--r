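#' Internal rooted-tree representation
#'
#' Converts an `ape` `"phylo"` object into the node-indexed structure the
#' likelihood engine traverses: parent pointers, child lists, the branch
#' length above each node, and a traversal order with children before
#' parents.  `ape`'s node numbering is kept (tips `1..n_tip`, root
#' `n_tip + 1`).  Unrooted (basal-trifurcation) trees are accepted as-is
#' and treated as rooted at `ape`'s root node; for reversible models the
#' likelihood does not depend on that choice (pulley principle).
#' Multifurcations are allowed.
#'
#' @param phy An `ape::phylo` object, or an object already converted.
#' @param default_branch_length If the tree lacks branch lengths (or has
#'   `NA` entries), this value is substituted; by default missing lengths
#'   are an error, since silently defaulting corrupts likelihoods.
#' @return An object of class `"phylo_tree"`.
#' @export
as_phylo_tree <- function(phy, default_branch_length = NULL) {
  if (inherits(phy, "phylo_tree")) return(phy)
  if (!inherits(phy, "phylo")) stop("expected an ape 'phylo' object", call. = FALSE)
  n_tip <- length(phy$tip.label)
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate taxon names in tree: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  n_node <- n_tip + phy$Nnode
  root <- n_tip + 1L
  blen <- rep(NA_real_, n_node)
  parent <- rep(NA_integer_, n_node)
  children <- vector("list", n_node)
  el <- phy$edge.length
  if (is.null(el)) el <- rep(NA_real_, nrow(phy$edge))
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
    parent[ch] <- p
    children[[p]] <- c(children[[p]], ch)
    blen[ch] <- el[e]
  }
  missing_bl <- is.na(blen[-root])
  if (any(missing_bl)) {
    if (is.null(default_branch_length)) {
      stop("tree has missing branch lengths; supply default_branch_length to override",
           call. = FALSE)
    }
    blen[-root][missing_bl] <- default_branch_length
  }
  if (any(blen[-root] < 0) || any(!is.finite(blen[-root]))) {
    stop("branch lengths must be finite and >= 0", call. = FALSE)
  }
  # preorder by explicit stack; reversed it puts children before parents
  pre <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    pre <- c(pre, v)
    stack <- c(stack, children[[v]])
  }
  structure(
    list(phy = phy, n_tip = n_tip, n_node = n_node, root = root,
         parent = parent, children = children, blen = blen,
         preorder = pre, postorder = rev(pre),
         tip_labels = phy$tip.label),
    class = "phylo_tree"
  )
}

#' @export
print.phylo_tree <- function(x, ...) {
  cat(sprintf("phylo_tree: %d tips, %d nodes, total branch length %.4g\n",
              x$n_tip, x$n_node, sum(x$blen, na.rm = TRUE)))
  invisible(x)
}

is_tip <- function(tree, v) v <= tree$n_tip
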
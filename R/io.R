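#' Read a Newick tree
#'
#' Parses standard Newick (branch lengths, optional internal labels,
#' multifurcations, trailing whitespace) via `ape` and converts to the
#' engine's representation.  Trees with missing branch lengths are
#' rejected unless `default_branch_length` is given, because silently
#' defaulted lengths corrupt likelihoods.
#'
#' @param path File containing one Newick tree.
#' @param default_branch_length Optional substitute for missing lengths.
#' @return A [as_phylo_tree()] object.
#' @export
read_newick <- function(path, default_branch_length = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  phy <- tryCatch(
    suppressWarnings(ape::read.tree(path)),
    error = function(e) NULL
  )
  if (is.null(phy) || !inherits(phy, "phylo")) {
    stop("failed to parse Newick in '", path,
         "': unbalanced parentheses or malformed tree text", call. = FALSE)
  }
  as_phylo_tree(phy, default_branch_length = default_branch_length)
}

#' Write a tree as Newick
#'
#' @param tree A [as_phylo_tree()] object (or `ape::phylo`).
#' @param path Output file.
#' @export
write_newick <- function(tree, path) {
  phy <- if (inherits(tree, "phylo_tree")) {
    p <- tree$phy
    # branch lengths may have been filled from a default
    el <- tree$blen[p$edge[, 2L]]
    p$edge.length <- el
    p
  } else tree
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Read a FASTA alignment as leaf profiles
#'
#' Residues become one-hot profiles; IUPAC ambiguity codes become
#' indicator profiles over the compatible states; gaps (`-`, `.`, `?`)
#' and `N`/`X` become all-ones.  Case-insensitive.  All sequences must
#' have equal length.
#'
#' @param path FASTA file.
#' @param alphabet `"dna"`, `"aa"`, or `"auto"` (detect: DNA if every
#'   character is a nucleotide or IUPAC code).
#' @return A [leaf_profiles()] object.
#' @export
read_alignment <- function(path, alphabet = c("auto", "dna", "aa")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  seqs <- Biostrings::readBStringSet(path)
  if (!length(seqs)) stop("no sequences in ", path, call. = FALSE)
  chars_list <- strsplit(as.character(seqs), "")
  lens <- lengths(chars_list)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: sequence lengths ",
         paste(unique(lens), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence names in ", path, call. = FALSE)
  }
  chars <- do.call(rbind, chars_list)
  rownames(chars) <- names(seqs)
  if (alphabet == "auto") {
    dna_ok <- all(toupper(chars) %in% names(residue_alphabet("dna")$map))
    alphabet <- if (dna_ok) "dna" else "aa"
  }
  profiles_from_chars(chars, alphabet)
}

#' Write sequences to FASTA
#'
#' @param chars Character matrix (taxa in rows, named) of residues, e.g.
#'   from [simulate_alignment()].
#' @param path Output file.
#' @param width Line width for wrapping.
#' @export
write_fasta <- function(chars, path, width = 70L) {
  if (!is.matrix(chars) || is.null(rownames(chars))) {
    stop("chars must be a character matrix with taxon rownames", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (tx in rownames(chars)) {
    writeLines(paste0(">", tx), con)
    s <- paste(chars[tx, ], collapse = "")
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write reversible-model parameters to a plain-text file
#'
#' Format: a header line with the state count `n`, then the
#' `n(n-1)/2` exchangeabilities (row-major upper triangle), then the `n`
#' `sqrt_pi` values, whitespace-separated.  Several parameter blocks may
#' be concatenated in one file (used for column-specific fits).  The
#' layout mirrors PAML/IQ-TREE rate-matrix files closely enough for
#' manual conversion but is its own dialect; note IQ-TREE parametrizes
#' `Q = R diag(pi)`, which maps to this one via `s_ij = r_ij
#' sqrt(pi_i pi_j)` (up to overall scale).
#'
#' @param params A [reversible_params()] or a list of them.
#' @param path Output file.
#' @export
write_params <- function(params, path) {
  if (inherits(params, "reversible_params")) params <- list(params)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in params) {
    writeLines(as.character(p$n), con)
    writeLines(paste(format(p$exch, digits = 17), collapse = " "), con)
    writeLines(paste(format(p$sqrt_pi, digits = 17), collapse = " "), con)
  }
  invisible(path)
}

#' Read reversible-model parameters
#'
#' @param path File written by [write_params()].
#' @param all Return every block in the file (list) instead of just the
#'   first.
#' @return A [reversible_params()] object, or a list of them if
#'   `all = TRUE`.
#' @export
read_params <- function(path, all = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tok <- scan(path, what = numeric(), quiet = TRUE)
  out <- list()
  i <- 1L
  while (i <= length(tok)) {
    n <- as.integer(tok[i])
    k <- n * (n - 1L) / 2L
    if (i + k + n > length(tok)) {
      stop("truncated parameter file: ", path, call. = FALSE)
    }
    out[[length(out) + 1L]] <- reversible_params(
      n, tok[i + seq_len(k)], tok[i + k + seq_len(n)])
    i <- i + 1L + k + n
  }
  if (!length(out)) stop("empty parameter file: ", path, call. = FALSE)
  if (all) out else out[[1L]]
}

#' Write a log-likelihood trace as CSV
#'
#' @param fit A [fit_model()] result.
#' @param path Output CSV (`iteration, loglik`; iteration counts outer
#'   L-BFGS rounds).
#' @export
write_loglik_trace <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  utils::write.csv(
    data.frame(iteration = seq_along(fit$trace) - 1L, loglik = fit$trace),
    path, row.names = FALSE)
  invisible(path)
}
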
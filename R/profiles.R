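#' Residue alphabets
#'
#' The nucleotide alphabet (n = 4, order A C G T) with the IUPAC ambiguity
#' codes, and the amino-acid alphabet (n = 20, order
#' A R N D C Q E G H I L K M F P S T W Y V) with B (Asx), Z (Glx) and X.
#' Gaps (`-`, `.`, `?`) and fully ambiguous codes map to the all-ones
#' indicator profile; partial ambiguity codes map to indicator profiles
#' with 1 on every compatible state.  Profiles are indicators, not
#' renormalized distributions, matching standard pruning practice: a gap
#' contributes a factor of exactly 1 to the column likelihood.
#'
#' @param name `"dna"` or `"aa"`.
#' @return List with `name`, `n`, `letters` (state order) and `map`
#'   (named list from character to indicator vector).
#' @export
residue_alphabet <- function(name = c("dna", "aa")) {
  name <- match.arg(name)
  if (name == "dna") {
    letters <- c("A", "C", "G", "T")
    amb <- list(U = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = letters)
  } else {
    letters <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
    amb <- list(B = c("D", "N"), Z = c("E", "Q"), X = letters)
  }
  n <- length(letters)
  map <- list()
  for (i in seq_len(n)) {
    v <- numeric(n); v[i] <- 1
    map[[letters[i]]] <- v
  }
  for (code in names(amb)) {
    v <- numeric(n)
    v[match(amb[[code]], letters)] <- 1
    map[[code]] <- v
  }
  for (gap in c("-", ".", "?")) map[[gap]] <- rep(1, n)
  list(name = name, n = n, letters = letters, map = map)
}

#' Leaf residue profiles
#'
#' Per-taxon, per-column non-negative `n`-vectors: one-hot for observed
#' residues, indicator profiles for ambiguity codes, all-ones for gaps.
#' Arbitrary non-negative profiles (e.g. basecall uncertainty) are also
#' accepted; every profile must have at least one strictly positive entry.
#'
#' @param x Named list (one entry per taxon) of `n x C` numeric matrices.
#' @param alphabet A [residue_alphabet()], or `NULL` for generic profiles.
#' @return Object of class `"leaf_profiles"` with fields `x`, `taxa`, `n`,
#'   `n_col`, `alphabet`.
#' @export
leaf_profiles <- function(x, alphabet = NULL) {
  if (!is.list(x) || is.null(names(x)) || any(names(x) == "")) {
    stop("x must be a named list of per-taxon profile matrices", call. = FALSE)
  }
  dims <- vapply(x, dim, integer(2))
  if (length(unique(dims[1, ])) != 1L || length(unique(dims[2, ])) != 1L) {
    stop("all profile matrices must share the same dimensions", call. = FALSE)
  }
  for (tx in names(x)) {
    m <- x[[tx]]
    if (any(!is.finite(m)) || any(m < 0)) {
      stop("profiles must be finite and non-negative (taxon ", tx, ")", call. = FALSE)
    }
    if (any(colSums(m) == 0)) {
      stop("all-zero profile column for taxon ", tx, call. = FALSE)
    }
  }
  structure(
    list(x = x, taxa = names(x), n = unname(dims[1, 1]),
         n_col = unname(dims[2, 1]), alphabet = alphabet),
    class = "leaf_profiles"
  )
}

#' @export
print.leaf_profiles <- function(x, ...) {
  cat(sprintf("leaf_profiles: %d taxa, %d columns, %d states\n",
              length(x$taxa), x$n_col, x$n))
  invisible(x)
}

#' Build one-hot profiles from a character matrix
#'
#' @param chars Character matrix (taxa in rows, named, columns = alignment
#'   columns), single residue characters, case-insensitive.
#' @param alphabet `"dna"`, `"aa"`, or a [residue_alphabet()].
#' @return A [leaf_profiles()] object.
#' @export
profiles_from_chars <- function(chars, alphabet) {
  if (is.character(alphabet)) alphabet <- residue_alphabet(alphabet)
  if (!is.matrix(chars) || is.null(rownames(chars))) {
    stop("chars must be a character matrix with taxon rownames", call. = FALSE)
  }
  up <- toupper(chars)
  bad <- matrix(!(up %in% names(alphabet$map)), nrow(up))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("illegal %s character '%s' in record '%s'",
                 alphabet$name, chars[bad][1], rownames(chars)[idx[1]]),
         call. = FALSE)
  }
  out <- list()
  for (tx in rownames(chars)) {
    m <- vapply(up[tx, ], function(ch) alphabet$map[[ch]], numeric(alphabet$n))
    dim(m) <- c(alphabet$n, ncol(chars))
    out[[tx]] <- m
  }
  leaf_profiles(out, alphabet)
}

# subset columns of a leaf_profiles object
subset_profiles <- function(profiles, cols) {
  leaf_profiles(lapply(profiles$x, function(m) m[, cols, drop = FALSE]),
                profiles$alphabet)
}

#' Collapse identical alignment columns into weighted patterns
#'
#' Returns the profiles restricted to the unique column patterns together
#' with integer weights (pattern multiplicities).  The column log
#' likelihood of a pattern is multiplied by its weight, so the total log
#' likelihood and all gradients are unchanged.  Only meaningful when all
#' columns share one model.
#'
#' @param profiles A [leaf_profiles()] object.
#' @return List with `profiles` (unique patterns) and `weights`.
#' @export
compress_columns <- function(profiles) {
  stopifnot(inherits(profiles, "leaf_profiles"))
  key <- do.call(paste, c(lapply(profiles$x, function(m) {
    apply(m, 2, paste, collapse = ",")
  }), sep = "|"))
  first <- !duplicated(key)
  weights <- as.vector(table(factor(key, levels = key[first])))
  list(profiles = subset_profiles(profiles, which(first)),
       weights = as.numeric(weights))
}
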
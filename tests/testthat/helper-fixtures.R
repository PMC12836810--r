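# Shared fixture builders.  Everything is generated in code from seeds;
# no data files.

# random tree with a floor on branch lengths so central differences over
# t never cross zero
rand_tree <- function(n_tip, seed, bl_mean = 0.15, bl_floor = 0.02) {
  tr <- random_tree(n_tip, bl_mean, seed = seed)
  tr$blen[-tr$root] <- tr$blen[-tr$root] + bl_floor
  tr
}

# a (tree, params, simulated alignment) instance under one global model
rand_instance <- function(n, n_tip, n_col, seed, bl_mean = 0.15) {
  tr <- rand_tree(n_tip, seed, bl_mean)
  p <- random_reversible_params(n, seed = seed + 1000L)
  sim <- simulate_alignment(tr, column_models(p), seed = seed + 2000L,
                            n_columns = n_col)
  list(tree = tr, params = p, models = column_models(p),
       profiles = sim$profiles, chars = sim$chars)
}

# reference matrix exponential: Higham scaling-and-squaring (Matrix pkg),
# independent of the spectral path under test
expm_ref <- function(q, t) {
  as.matrix(Matrix::expm(Matrix::Matrix(q * t)))
}

# one-hot profile helper
one_hot <- function(i, n) { v <- numeric(n); v[i] <- 1; v }

# divided difference of exp via expm1: an independent high-precision
# formula, stable for small gaps (exact when the gap underflows to 0)
div_diff_ref <- function(l1, l2, t) {
  d <- t * (l1 - l2)
  if (d == 0) t * exp(t * l1) else exp(t * l2) * expm1(d) / (l1 - l2)
}
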
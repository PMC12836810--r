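cherry <- function(t1, t2) {
  as_phylo_tree(ape::read.tree(text = sprintf("(A:%g,B:%g);", t1, t2)))
}

test_that("pruning recovers closed forms on tiny trees", {
  p <- random_reversible_params(4, seed = 1)
  pi <- stationary_distribution(p)
  # observed leaf at distance 0, the other leaf fully unknown:
  # column likelihood is the root prior of the observed state
  tr <- cherry(0, 0.3)
  for (a in 1:4) {
    prof <- leaf_profiles(list(A = matrix(one_hot(a, 4), 4),
                               B = matrix(1, 4, 1)))
    fwd <- pruning_forward(tr, prof, column_models(p))
    expect_equal(fwd$col_loglik, log(pi[a]), tolerance = 1e-12)
  }
  # fully unknown column has likelihood exactly 1
  prof <- leaf_profiles(list(A = matrix(1, 4, 1), B = matrix(1, 4, 1)))
  fwd <- pruning_forward(cherry(0.1, 0.7), prof, column_models(p))
  expect_equal(fwd$col_loglik, 0, tolerance = 1e-12)
  # two observed leaves: direct summation over the root state
  sp <- spectral_decompose(p)
  t1 <- 0.23; t2 <- 0.61
  p1 <- expm_spectral(sp, t1); p2 <- expm_spectral(sp, t2)
  tr <- cherry(t1, t2)
  for (xy in list(c(1, 1), c(2, 4), c(3, 2))) {
    prof <- leaf_profiles(list(A = matrix(one_hot(xy[1], 4), 4),
                               B = matrix(one_hot(xy[2], 4), 4)))
    fwd <- pruning_forward(tr, prof, column_models(p))
    direct <- log(sum(pi * p1[, xy[1]] * p2[, xy[2]]))
    expect_equal(fwd$col_loglik, direct, tolerance = 1e-12)
  }
})

test_that("pruning equals brute-force ancestral enumeration", {
  for (seed in 1:30) {
    n_tip <- 3 + seed %% 4
    inst <- rand_instance(4, n_tip, 3, seed = 3000 + seed)
    fwd <- pruning_forward(inst$tree, inst$profiles, inst$models)
    bf <- brute_force_likelihood(inst$tree, inst$profiles, inst$params)
    expect_lt(max(abs(fwd$col_loglik - bf) / abs(bf)), 1e-10)
  }
  # degenerate corner: zero branch lengths, identical one-hot leaves
  p <- random_reversible_params(4, seed = 31)
  tr <- cherry(0, 0)
  prof <- leaf_profiles(list(A = matrix(one_hot(2, 4), 4),
                             B = matrix(one_hot(2, 4), 4)))
  expect_equal(brute_force_likelihood(tr, prof, p),
               log(stationary_distribution(p)[2]), tolerance = 1e-12)
  expect_error(brute_force_likelihood(rand_tree(8, 1), prof, p), "7 leaves")
})

test_that("reverse-pass gradients match central finite differences", {
  # global model over a mix of sizes and both alphabets
  cases <- list(list(n = 4, n_tip = 8, C = 20, seed = 41),
                list(n = 4, n_tip = 12, C = 5, seed = 42),
                list(n = 20, n_tip = 5, C = 2, seed = 43))
  for (cs in cases) {
    inst <- rand_instance(cs$n, cs$n_tip, cs$C, seed = cs$seed)
    chk <- gradient_check(inst$tree, inst$profiles, inst$models,
                          step = if (cs$n == 20L) 1e-5 else 1e-6)
    expect_lt(chk$max_rel_err, 1e-6)
  }
  # independent per-column models
  plist <- lapply(1:3, function(i) random_reversible_params(4, seed = 50 + i))
  models <- column_models(plist, 1:3)
  tr <- rand_tree(6, seed = 44)
  sim <- simulate_alignment(tr, models, seed = 45)
  chk <- gradient_check(tr, sim$profiles, models)
  expect_lt(chk$max_rel_err, 1e-6)
})

test_that("an all-unknown column contributes zero gradient", {
  p <- random_reversible_params(4, seed = 61)
  tr <- rand_tree(5, seed = 62)
  prof <- leaf_profiles(setNames(
    replicate(5, matrix(1, 4, 1), simplify = FALSE), tr$tip_labels))
  gb <- loglik_and_grad(tr, prof, column_models(p))
  expect_equal(gb$loglik, 0, tolerance = 1e-12)
  # dL/dQ over unconstrained entries is nonzero (breaking the generator
  # structure changes L), but every free-parameter and branch gradient
  # vanishes because L is constant on the model manifold
  expect_lt(max(abs(gb$models[[1]]$g_exch)), 1e-12)
  expect_lt(max(abs(gb$models[[1]]$g_sqrt_pi)), 1e-12)
  expect_lt(max(abs(gb$g_t), na.rm = TRUE), 1e-12)
})

test_that("columns with independent models do not leak gradients", {
  tr <- rand_tree(6, seed = 71)
  plist <- lapply(1:2, function(i) random_reversible_params(4, seed = 80 + i))
  models <- column_models(plist, 1:2)
  sim <- simulate_alignment(tr, models, seed = 72)
  joint <- reverse_pass(pruning_forward(tr, sim$profiles, models))
  for (m in 1:2) {
    solo_prof <- leaf_profiles(lapply(sim$profiles$x,
                                      function(x) x[, m, drop = FALSE]))
    solo <- reverse_pass(pruning_forward(tr, solo_prof,
                                         column_models(plist[[m]])))
    expect_equal(joint$models[[m]]$g_q, solo$models[[1]]$g_q, tolerance = 1e-12)
    expect_equal(joint$models[[m]]$g_exch, solo$models[[1]]$g_exch,
                 tolerance = 1e-12)
  }
  # total loglik and branch gradients are column sums
  expect_equal(joint$loglik, sum(joint$col_loglik), tolerance = 1e-12)
})

test_that("global fast path agrees with the per-column path", {
  inst <- rand_instance(4, 8, 12, seed = 91)
  global <- loglik_and_grad(inst$tree, inst$profiles, inst$models)
  percol <- loglik_and_grad(
    inst$tree, inst$profiles,
    column_models(replicate(12, inst$params, simplify = FALSE), 1:12))
  expect_equal(percol$loglik, global$loglik, tolerance = 1e-12)
  expect_equal(percol$col_loglik, global$col_loglik, tolerance = 1e-12)
  g_sum <- Reduce(`+`, lapply(percol$models, function(m) m$g_q))
  expect_equal(g_sum, global$models[[1]]$g_q, tolerance = 1e-10)
  expect_equal(percol$g_t, global$g_t, tolerance = 1e-10)
})

test_that("likelihood is invariant under re-rooting (pulley principle)", {
  inst <- rand_instance(4, 8, 10, seed = 101)
  ll0 <- pruning_forward(inst$tree, inst$profiles, inst$models)$loglik
  f <- tempfile(fileext = ".nwk")
  write_newick(inst$tree, f)
  phy <- ape::read.tree(f)
  set.seed(102)
  nodes <- sample(setdiff(2:(phy$Nnode + length(phy$tip.label)),
                          length(phy$tip.label) + 1), 4)
  for (nd in nodes) {
    el <- phy$edge.length[which(phy$edge[, 2] == nd)]
    rr <- phytools::reroot(phy, node.number = nd, position = 0.37 * el)
    ll <- pruning_forward(as_phylo_tree(rr), inst$profiles, inst$models)$loglik
    expect_lt(abs(ll - ll0) / abs(ll0), 1e-10)
  }
})

test_that("pattern compression with weights preserves likelihood and gradients", {
  inst <- rand_instance(4, 6, 60, seed = 111)
  full <- loglik_and_grad(inst$tree, inst$profiles, inst$models)
  cc <- compress_columns(inst$profiles)
  expect_lt(cc$profiles$n_col, 60)
  expect_equal(sum(cc$weights), 60)
  packed <- loglik_and_grad(inst$tree, cc$profiles, inst$models,
                            weights = cc$weights)
  expect_equal(packed$loglik, full$loglik, tolerance = 1e-12)
  expect_equal(packed$models[[1]]$g_exch, full$models[[1]]$g_exch,
               tolerance = 1e-10)
  expect_equal(packed$models[[1]]$g_sqrt_pi, full$models[[1]]$g_sqrt_pi,
               tolerance = 1e-10)
  expect_equal(packed$g_t, full$g_t, tolerance = 1e-10)
})

test_that("multifurcations and trifurcating roots are handled", {
  p <- random_reversible_params(4, seed = 121)
  phy <- ape::read.tree(text = "(A:0.1,B:0.2,C:0.15,D:0.05);")
  tr <- as_phylo_tree(phy)
  expect_equal(tr$n_node, 5L)
  prof <- leaf_profiles(list(A = matrix(one_hot(1, 4), 4),
                             B = matrix(one_hot(2, 4), 4),
                             C = matrix(one_hot(2, 4), 4),
                             D = matrix(one_hot(4, 4), 4)))
  fwd <- pruning_forward(tr, prof, column_models(p))
  bf <- brute_force_likelihood(tr, prof, p)
  expect_equal(fwd$col_loglik, bf, tolerance = 1e-12)
  chk <- gradient_check(tr, prof, column_models(p))
  expect_lt(chk$max_rel_err, 1e-6)
})

test_that("mismatched taxa and malformed profiles are rejected", {
  inst <- rand_instance(4, 4, 2, seed = 131)
  bad <- inst$profiles
  names(bad$x)[1] <- "zz"
  bad$taxa[1] <- "zz"
  expect_error(pruning_forward(inst$tree, bad, inst$models), "taxon names")
  expect_error(leaf_profiles(list(A = matrix(0, 4, 1))), "all-zero")
  expect_error(pruning_forward(inst$tree, inst$profiles, inst$models,
                               weights = c(1, -1)), "positive")
})

test_that("reverse-pass cost grows about linearly with tree size", {
  p <- random_reversible_params(4, seed = 141)
  time_for <- function(n_tip) {
    tr <- rand_tree(n_tip, seed = 142)
    sim <- simulate_alignment(tr, column_models(p), seed = 143, n_columns = 50)
    # warm-up, then best of three
    loglik_and_grad(tr, sim$profiles, column_models(p))
    min(vapply(1:3, function(i) {
      system.time(loglik_and_grad(tr, sim$profiles, column_models(p)))[["elapsed"]]
    }, numeric(1)))
  }
  t64 <- time_for(64)
  t128 <- time_for(128)
  expect_lt(t128 / t64, 2.5)
})
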
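test_that("sqrt_pi clamping floors tiny entries and rejects bad input", {
  expect_equal(as.numeric(clamp_sqrt_pi(rep(0.5, 4))), rep(0.5, 4))
  out <- clamp_sqrt_pi(c(0.5, 1e-12, 0.5, 0.5))
  expect_equal(as.numeric(out), c(0.5, 1e-10, 0.5, 0.5))
  expect_equal(attr(out, "clamped"), c(FALSE, TRUE, FALSE, FALSE))
  expect_error(clamp_sqrt_pi(c(-0.1, 0.5, 0.5, 0.5)), "non-negative")
  expect_error(clamp_sqrt_pi(c(NaN, 1)), "finite")
})

test_that("rate matrix construction: closed forms and invariants", {
  # symmetric two-state chain
  p2 <- reversible_params(2, 1, c(1, 1))
  expect_equal(unclass(build_rate_matrix(p2)),
               matrix(c(-1, 1, 1, -1), 2, byrow = TRUE))
  # absorbing chain
  p0 <- reversible_params(4, rep(0, 6), rep(0.5, 4))
  expect_equal(unclass(build_rate_matrix(p0)), matrix(0, 4, 4))
  # random instances: zero row sums and detailed balance, entrywise
  for (seed in 1:25) {
    p <- random_reversible_params(4, seed = seed, normalize = FALSE)
    q <- unclass(build_rate_matrix(p))
    expect_lt(max(abs(rowSums(q))), 1e-12)
    expect_true(all(q[row(q) != col(q)] >= 0))
    pi <- stationary_distribution(p)
    db <- pi * q            # pi_i q_ij
    expect_lt(max(abs(db - t(db))) / max(abs(db)), 1e-10)
  }
})

test_that("stationary distribution: normalization, scale invariance, left null vector", {
  p <- reversible_params(4, rep(1, 6), rep(1, 4))
  expect_equal(stationary_distribution(p), rep(0.25, 4))
  base <- reversible_params(4, rep(1, 6), c(2, 1, 1, 1))
  for (c in c(0.1, 3, 1e4)) {
    scaled <- reversible_params(4, rep(1, 6), c * c(2, 1, 1, 1))
    expect_equal(stationary_distribution(scaled), stationary_distribution(base))
    expect_lt(max(abs(build_rate_matrix(scaled) - build_rate_matrix(base))), 1e-12)
  }
  for (seed in 1:10) {
    p <- random_reversible_params(4, seed = seed)
    v <- stationary_distribution(p)
    expect_lt(max(abs(v %*% unclass(build_rate_matrix(p)))), 1e-12)
  }
})

test_that("spectral decomposition reconstructs Q with a proper spectrum", {
  for (n in c(2L, 4L, 20L)) {
    for (seed in 1:34) {
      p <- random_reversible_params(n, seed = 7000L + 100L * n + seed)
      sp <- spectral_decompose(p)
      q <- unclass(build_rate_matrix(p))
      rec <- sp$a %*% (sp$eigvals * sp$a_inv)
      expect_lt(norm(rec - q, "F") / norm(q, "F"), 1e-10)
      expect_lte(max(sp$eigvals), 1e-8)
      expect_equal(sum(abs(sp$eigvals) < 1e-8), 1L)
      # right eigenvector of the zero eigenvalue is constant
      k <- which.max(sp$eigvals)
      col <- sp$a[, k]
      expect_lt(max(abs(col / col[1] - 1)), 1e-8)
    }
  }
})

test_that("uniform frequencies give an orthogonal-up-to-scale transform", {
  p <- random_reversible_params(4, seed = 3)
  pu <- reversible_params(4, p$exch, rep(1, 4))
  sp <- spectral_decompose(pu)
  expect_equal(sp$a_inv %*% sp$a, diag(4), tolerance = 1e-12)
  expect_equal(t(sp$a) %*% sp$a, diag(4), tolerance = 1e-12)
})

test_that("parameter backprop matches finite differences of smooth functionals", {
  set.seed(99)
  for (rep in 1:5) {
    p <- random_reversible_params(4, seed = 400 + rep, normalize = FALSE)
    g0 <- matrix(rnorm(16), 4)           # fixed linear functional L = <g0, Q>
    bp <- backprop_params(g0, p)
    h <- 1e-6
    for (j in seq_along(p$exch)) {
      up <- p$exch; up[j] <- up[j] + h
      dn <- p$exch; dn[j] <- dn[j] - h
      fd <- (sum(g0 * build_rate_matrix(reversible_params(4, up, p$sqrt_pi))) -
             sum(g0 * build_rate_matrix(reversible_params(4, dn, p$sqrt_pi)))) / (2 * h)
      expect_equal(bp$g_exch[j], fd, tolerance = 1e-6)
    }
    for (j in 1:4) {
      up <- p$sqrt_pi; up[j] <- up[j] + h
      dn <- p$sqrt_pi; dn[j] <- dn[j] - h
      fd <- (sum(g0 * build_rate_matrix(reversible_params(4, p$exch, up))) -
             sum(g0 * build_rate_matrix(reversible_params(4, p$exch, dn)))) / (2 * h)
      expect_equal(bp$g_sqrt_pi[j], fd, tolerance = 1e-6)
    }
    # root-prior chain: L = <w, pi>
    w <- rnorm(4)
    bp2 <- backprop_params(matrix(0, 4, 4), p, g_pi = w)
    expect_equal(bp2$g_exch, rep(0, 6))
    for (j in 1:4) {
      up <- p$sqrt_pi; up[j] <- up[j] + h
      dn <- p$sqrt_pi; dn[j] <- dn[j] - h
      fd <- (sum(w * stationary_distribution(reversible_params(4, p$exch, up))) -
             sum(w * stationary_distribution(reversible_params(4, p$exch, dn)))) / (2 * h)
      expect_equal(bp2$g_sqrt_pi[j], fd, tolerance = 1e-6)
    }
  }
})

test_that("gradients vanish along the sqrt_pi scale direction", {
  set.seed(17)
  for (rep in 1:5) {
    p <- random_reversible_params(4, seed = 500 + rep, normalize = FALSE)
    g0 <- matrix(rnorm(16), 4)
    w <- rnorm(4)
    bp <- backprop_params(g0, p, g_pi = w)
    expect_lt(abs(sum(bp$g_sqrt_pi * p$sqrt_pi)), 1e-8)
  }
  p <- random_reversible_params(4, seed = 1)
  expect_equal(backprop_params(matrix(0, 4, 4), p),
               list(g_exch = rep(0, 6), g_sqrt_pi = rep(0, 4)))
})

test_that("clamped coordinates get zero gradient", {
  p <- reversible_params(4, rep(1, 6), c(0.5, 1e-14, 0.5, 0.5))
  expect_equal(p$sqrt_pi[2], 1e-10)
  bp <- backprop_params(matrix(rnorm(16), 4), p, g_pi = rnorm(4))
  expect_identical(bp$g_sqrt_pi[2], 0)
})

test_that("rate scale and normalization behave and differentiate correctly", {
  p <- random_reversible_params(4, seed = 11, normalize = FALSE)
  rs <- rate_scale(p)
  q <- build_rate_matrix(p)
  pi <- stationary_distribution(p)
  expect_equal(rs$mu, -sum(pi * diag(q)), tolerance = 1e-12)
  expect_equal(rate_scale(normalize_params(p))$mu, 1, tolerance = 1e-12)
  h <- 1e-6
  for (j in seq_along(p$exch)) {
    up <- p$exch; up[j] <- up[j] + h; dn <- p$exch; dn[j] <- dn[j] - h
    fd <- (rate_scale(reversible_params(4, up, p$sqrt_pi))$mu -
           rate_scale(reversible_params(4, dn, p$sqrt_pi))$mu) / (2 * h)
    expect_equal(rs$d_exch[j], fd, tolerance = 1e-6)
  }
  for (j in 1:4) {
    up <- p$sqrt_pi; up[j] <- up[j] + h; dn <- p$sqrt_pi; dn[j] <- dn[j] - h
    fd <- (rate_scale(reversible_params(4, p$exch, up))$mu -
           rate_scale(reversible_params(4, p$exch, dn))$mu) / (2 * h)
    expect_equal(rs$d_sqrt_pi[j], fd, tolerance = 1e-6)
  }
})

test_that("parameter validation rejects malformed input", {
  expect_error(reversible_params(4, rep(1, 5), rep(1, 4)), "length")
  expect_error(reversible_params(4, c(-1, rep(1, 5)), rep(1, 4)), "non-negative")
  expect_error(reversible_params(4, rep(1, 6), rep(1, 3)), "length")
  expect_error(backprop_params(matrix(0, 3, 3),
                               reversible_params(4, rep(1, 6), rep(1, 4))),
               "n x n")
})
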
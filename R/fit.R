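#' Number of free parameters of a model kind
#'
#' Under rate normalization one exchangeability scale is absorbed (branch
#' lengths carry the rate), and the equilibrium distribution has `n - 1`
#' free degrees.  For `n = 20` the global model therefore has
#' `190 - 1 + 19 = 208` free parameters.
#'
#' @param n State count (>= 2).
#' @param model_kind One of `"global_gtr"`, `"shared_S_column_pi"`,
#'   `"per_column_gtr"`.
#' @param n_columns Number of alignment columns (used by the
#'   column-specific kinds).
#' @return Integer count.
#' @export
count_free_parameters <- function(n, model_kind, n_columns = 1L) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  k <- (n * (n - 1L)) %/% 2L
  c_cols <- as.integer(n_columns)
  switch(model_kind,
    global_gtr = k - 1L + (n - 1L),
    shared_S_column_pi = k - 1L + c_cols * (n - 1L),
    per_column_gtr = c_cols * (k - 1L + (n - 1L)),
    stop("unknown model kind: ", model_kind, call. = FALSE)
  )
}

# pack/unpack the free parameters (log space) for each model kind
pack_theta <- function(params_list, model_kind) {
  if (model_kind == "global_gtr") {
    p <- params_list[[1]]
    c(log(p$exch), log(p$sqrt_pi))
  } else if (model_kind == "shared_S_column_pi") {
    c(log(params_list[[1]]$exch),
      unlist(lapply(params_list, function(p) log(p$sqrt_pi))))
  } else {
    unlist(lapply(params_list, function(p) c(log(p$exch), log(p$sqrt_pi))))
  }
}

unpack_theta <- function(theta, n, n_models, model_kind) {
  k <- n * (n - 1L) / 2L
  if (model_kind == "global_gtr") {
    list(reversible_params(n, exp(theta[seq_len(k)]),
                           exp(theta[k + seq_len(n)])))
  } else if (model_kind == "shared_S_column_pi") {
    s <- exp(theta[seq_len(k)])
    lapply(seq_len(n_models), function(m) {
      reversible_params(n, s, exp(theta[k + (m - 1L) * n + seq_len(n)]))
    })
  } else {
    lapply(seq_len(n_models), function(m) {
      off <- (m - 1L) * (k + n)
      reversible_params(n, exp(theta[off + seq_len(k)]),
                        exp(theta[off + k + seq_len(n)]))
    })
  }
}

# gradient bundle -> gradient w.r.t. theta (log-space free parameters),
# chaining through optional rate normalization of the global model
theta_gradient <- function(bundle, params_list, model_kind, normalize_rate) {
  n <- params_list[[1]]$n
  k <- n * (n - 1L) / 2L
  if (model_kind == "global_gtr") {
    p <- params_list[[1]]
    g_s <- bundle$models[[1]]$g_exch
    g_v <- bundle$models[[1]]$g_sqrt_pi
    if (normalize_rate) {
      rs <- rate_scale(p)
      s_eff <- p$exch / rs$mu
      d <- sum(g_s * s_eff)
      g_s <- g_s / rs$mu - d * rs$d_exch / rs$mu
      g_v <- g_v - d * rs$d_sqrt_pi / rs$mu
    }
    c(g_s * p$exch, g_v * p$sqrt_pi)
  } else if (model_kind == "shared_S_column_pi") {
    g_s <- Reduce(`+`, lapply(bundle$models, function(m) m$g_exch))
    g_vs <- unlist(lapply(seq_along(params_list), function(m) {
      bundle$models[[m]]$g_sqrt_pi * params_list[[m]]$sqrt_pi
    }))
    c(g_s * params_list[[1]]$exch, g_vs)
  } else {
    unlist(lapply(seq_along(params_list), function(m) {
      p <- params_list[[m]]
      c(bundle$models[[m]]$g_exch * p$exch,
        bundle$models[[m]]$g_sqrt_pi * p$sqrt_pi)
    }))
  }
}

# apply global rate normalization before likelihood evaluation
effective_models <- function(params_list, model_kind, normalize_rate, assignment) {
  if (model_kind == "global_gtr") {
    p <- params_list[[1]]
    if (normalize_rate) {
      mu <- rate_scale(p)$mu
      p <- reversible_params(p$n, p$exch / mu, p$sqrt_pi)
    }
    column_models(p)
  } else {
    column_models(params_list, assignment)
  }
}

#' Maximum-likelihood fitting by L-BFGS
#'
#' Maximizes the total log likelihood over the free parameters of the
#' chosen model kind, using the analytic reverse-mode gradients from
#' [loglik_and_grad()].  All positive parameters (exchangeabilities and
#' `sqrt_pi`) are optimized in log space, which enforces positivity
#' without box constraints and keeps the gradients smooth.  Under
#' `normalize_rate` (default for the global model) the rate matrix is
#' rescaled to mean rate 1 on every build and the gradient is projected
#' through the rescaling, so the exchangeability scale is not a free
#' degree.
#'
#' Optimization runs L-BFGS in outer rounds of up to 10 iterations and
#' stops when a round improves the log likelihood by less than
#' `rel_improve_tol * |L|` (default 1e-6, i.e. 0.0001 percent) or when
#' `max_iters` total iterations are spent.  An optional L2 penalty on the
#' log-parameters is subtracted from the objective; a penalty of exactly 0
#' takes the unpenalized code path.
#'
#' @param tree A [as_phylo_tree()] object (or `ape::phylo`).
#' @param profiles A [leaf_profiles()] object.
#' @param model_kind `"global_gtr"` (one rate matrix for all columns),
#'   `"shared_S_column_pi"` (one exchangeability set, per-column
#'   equilibrium), or `"per_column_gtr"` (independent matrix per column).
#' @param init Optional initial parameters: a [reversible_params()] for
#'   the global model, or a list (one per column) otherwise.  Default:
#'   equal exchangeabilities and uniform equilibrium.
#' @param max_iters Maximum total L-BFGS iterations.
#' @param rel_improve_tol Relative log-likelihood improvement below which
#'   optimization stops.
#' @param l2_penalty Non-negative ridge weight on the log-parameters.
#' @param normalize_rate Rescale the global model to mean rate 1
#'   (ignored, with a message, for the column-specific kinds where
#'   rescaling would redefine the shared exchangeabilities).
#' @param seed Optional seed controlling a small log-normal jitter of the
#'   initial parameters; the optimization itself is deterministic.
#' @param weights Optional per-column pattern weights.
#' @param threads Worker processes for the likelihood evaluations.
#' @return Object of class `"fit_result"`: `params` (fitted model list),
#'   `models` ([column_models()] of the fitted parameters, normalized if
#'   requested), `loglik`, `trace` (log likelihood per outer round),
#'   `iterations`, `termination`, `n_free`.
#' @export
fit_model <- function(tree, profiles, model_kind = c("global_gtr",
                        "shared_S_column_pi", "per_column_gtr"),
                      init = NULL, max_iters = 500L, rel_improve_tol = 1e-6,
                      l2_penalty = 0, normalize_rate = NULL, seed = NULL,
                      weights = NULL, threads = 1L) {
  model_kind <- match.arg(model_kind)
  tree <- as_phylo_tree(tree)
  stopifnot(inherits(profiles, "leaf_profiles"))
  if (rel_improve_tol <= 0) stop("rel_improve_tol must be positive", call. = FALSE)
  if (max_iters < 1L) stop("max_iters must be >= 1", call. = FALSE)
  if (l2_penalty < 0) stop("l2_penalty must be non-negative", call. = FALSE)
  n <- profiles$n
  C <- profiles$n_col
  k <- n * (n - 1L) / 2L
  if (is.null(normalize_rate)) normalize_rate <- model_kind == "global_gtr"
  if (normalize_rate && model_kind != "global_gtr") {
    message("normalize_rate applies to the global model only; ignoring")
    normalize_rate <- FALSE
  }
  n_models <- if (model_kind == "global_gtr") 1L else C
  assignment <- if (model_kind == "global_gtr") NULL else seq_len(C)
  if (is.null(init)) {
    base <- reversible_params(n, rep(1, k), rep(1 / sqrt(n), n))
    init <- replicate(n_models, base, simplify = FALSE)
  } else if (inherits(init, "reversible_params")) {
    init <- replicate(n_models, init, simplify = FALSE)
  }
  if (length(init) != n_models) {
    stop("init must supply one parameter set per model", call. = FALSE)
  }
  theta <- pack_theta(init, model_kind)
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
    theta <- theta + stats::rnorm(length(theta), sd = 0.01)
  }

  last <- new.env(parent = emptyenv())
  evaluate <- function(theta) {
    if (!is.null(last$theta) && identical(theta, last$theta)) return(last$res)
    params_list <- unpack_theta(theta, n, n_models, model_kind)
    models <- effective_models(params_list, model_kind, normalize_rate, assignment)
    bundle <- loglik_and_grad(tree, profiles, models, weights = weights,
                              threads = threads)
    g <- theta_gradient(bundle, params_list, model_kind, normalize_rate)
    value <- -bundle$loglik
    grad <- -g
    if (l2_penalty > 0) {
      value <- value + l2_penalty * sum(theta^2)
      grad <- grad + 2 * l2_penalty * theta
    }
    res <- list(value = value, grad = grad, loglik = bundle$loglik)
    last$theta <- theta
    last$res <- res
    res
  }
  fn <- function(par) evaluate(par)$value
  gr <- function(par) evaluate(par)$grad

  inner <- 10L
  trace <- evaluate(theta)$loglik
  obj_prev <- evaluate(theta)$value
  iterations <- 0L
  termination <- "max_iters"
  while (iterations < max_iters) {
    budget <- min(inner, max_iters - iterations)
    opt <- stats::optim(theta, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = budget, lmm = 10L))
    iterations <- iterations + budget
    theta <- opt$par
    cur <- evaluate(theta)
    trace <- c(trace, cur$loglik)
    if (opt$convergence == 52L) {
      termination <- paste("line-search failure:", opt$message)
      break
    }
    if (obj_prev - cur$value <= rel_improve_tol * abs(cur$value)) {
      termination <- "converged"
      break
    }
    obj_prev <- cur$value
  }
  params_list <- unpack_theta(theta, n, n_models, model_kind)
  fitted_models <- effective_models(params_list, model_kind, normalize_rate,
                                    assignment)
  final <- evaluate(theta)
  structure(
    list(params = fitted_models$params, models = fitted_models,
         loglik = final$loglik, trace = trace, iterations = iterations,
         termination = termination, model_kind = model_kind,
         normalize_rate = normalize_rate,
         n_free = count_free_parameters(n, model_kind, C)),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result (%s): loglik = %.6f after %d iterations (%s)\n",
              x$model_kind, x$loglik, x$iterations, x$termination))
  cat(sprintf("free parameters: %d; %d model(s)\n", x$n_free, length(x$params)))
  invisible(x)
}
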
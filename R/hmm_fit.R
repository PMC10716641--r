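working_names <- function(spec) {
  N <- spec$n_states; K <- spec$n_contexts; P <- spec$n_cov_cols
  st <- seq_len(N)
  nm <- c(paste0("log_shape_time.s", st), paste0("log_rate_time.s", st),
          paste0("log_shape_depth.s", st), paste0("log_rate_depth.s", st),
          paste0("log_lambda.s", st),
          paste0("log_shape_speed.s", st), paste0("log_rate_speed.s", st),
          paste0("mu.s", st), paste0("log_kappa.s", st))
  for (k in seq_len(K)) for (i in st) for (j in st[-i])
    nm <- c(nm, sprintf("eta0.k%d.%d->%d", k, i, j))
  if (P > 0) {
    Kb <- if (spec$covariate_sharing == "per_context") K else 1L
    for (k in seq_len(Kb)) for (p in seq_len(P)) for (i in st) for (j in st[-i])
      nm <- c(nm, sprintf("beta%s.p%d.%d->%d",
                          if (Kb > 1) paste0(".k", k) else "", p, i, j))
  }
  for (k in seq_len(K)) for (j in st[-1]) nm <- c(nm, sprintf("delta.k%d.s%d", k, j))
  if (K > 1) nm <- c(nm, sprintf("pi.%d", 2:K))
  nm
}

# moment-matched emission start values split by depth quantile, with jitter
random_start <- function(data, spec, jitter = 0.4) {
  N <- spec$n_states; K <- spec$n_contexts
  qs <- stats::quantile(data$max_depth, probs = (seq_len(N) - 0.5) / N)
  grp <- findInterval(data$max_depth, stats::quantile(data$max_depth,
                                                     probs = seq_len(N - 1) / N)) + 1L
  gs <- matrix(1, 3, N); gr <- matrix(1, 3, N)
  lambda <- numeric(N); mu <- numeric(N); kappa <- numeric(N)
  for (n in seq_len(N)) {
    sel <- grp == n
    if (sum(sel) < 5) sel <- rep(TRUE, nrow(data))
    for (s in 1:3) {
      v <- data[[c("dive_time", "max_depth", "speed")[s]]][sel]
      m <- mean(v); vv <- max(stats::var(v), 1e-6)
      gs[s, n] <- max(m^2 / vv, 0.2) * exp(stats::rnorm(1, 0, jitter))
      gr[s, n] <- gs[s, n] / m * exp(stats::rnorm(1, 0, jitter))
    }
    lambda[n] <- max(mean(data$lunges[sel]), 0.05) * exp(stats::rnorm(1, 0, jitter))
    mu[n] <- stats::rnorm(1, 0, 0.3)
    kappa[n] <- exp(stats::rnorm(1, 0, jitter))
  }
  eta0 <- array(stats::rnorm(K * N * N, -2, 0.7), c(K, N, N))
  beta <- NULL
  if (spec$covariate != "none") {
    Kb <- if (spec$covariate_sharing == "per_context") K else 1L
    beta <- array(stats::rnorm(spec$n_cov_cols * N * N * Kb, 0, 0.3),
                  c(spec$n_cov_cols, N, N, Kb))
  }
  delta <- matrix(stats::rgamma(K * N, 2, 1), K, N); delta <- delta / rowSums(delta)
  pi_k <- stats::rgamma(K, 2, 1); pi_k <- pi_k / sum(pi_k)
  structure(list(gamma_shape = gs, gamma_rate = gr, lambda = lambda, mu = mu,
                 kappa = kappa, eta0 = eta0, beta = beta, delta = delta,
                 pi = pi_k), class = "hmm_params")
}

# relabel states by descending mean maximum depth (state 1 = deepest) so that
# deep-feeding / non-feeding / shallow-feeding labels are reproducible
canonicalize_states <- function(params) {
  depth_mean <- params$gamma_shape[2, ] / params$gamma_rate[2, ]
  o <- order(depth_mean, decreasing = TRUE)
  if (all(o == seq_along(o))) return(params)
  params$gamma_shape <- params$gamma_shape[, o, drop = FALSE]
  params$gamma_rate <- params$gamma_rate[, o, drop = FALSE]
  params$lambda <- params$lambda[o]; params$mu <- params$mu[o]
  params$kappa <- params$kappa[o]
  params$eta0 <- params$eta0[, o, o, drop = FALSE]
  if (!is.null(params$beta)) params$beta <- params$beta[, o, o, , drop = FALSE]
  params$delta <- params$delta[, o, drop = FALSE]
  params
}

#' Fit a context hidden Markov model by maximum likelihood
#'
#' Maximizes the mixture log-likelihood over unconstrained working parameters
#' (log scale for positive parameters, multinomial logits for probability
#' vectors) with a quasi-Newton (BFGS) optimizer using analytic gradients
#' computed by the forward-backward recursion. Multiple random starts guard
#' against local maxima: all `n_starts` candidate starting points are scored
#' by their initial log-likelihood and the best `n_optim` are optimized fully;
#' the best converged solution is returned. Emission starting values can be
#' warm-started from a previously fitted baseline model via `init_emissions`.
#'
#' States of the returned fit are relabelled by descending mean maximum depth
#' (state 1 = deepest).
#'
#' @param data per-dive data frame (see [hmm_design()]).
#' @param spec an [hmm_spec()].
#' @param n_starts number of random starting points.
#' @param seed RNG seed for start generation (fits are deterministic given
#'   `seed` and `n_starts`).
#' @param init_emissions optional `hmm_params` (e.g. from a baseline fit)
#'   whose emission parameters seed every start.
#' @param init_params optional full `hmm_params` added as an extra start.
#' @param n_optim number of top-ranked starts to optimize fully.
#' @param maxit BFGS iteration cap per start.
#' @param reltol relative log-likelihood convergence tolerance.
#' @return an object of class `hmm_fit`: spec, natural- and working-scale
#'   estimates, log-likelihood, parameter count, AIC, start diagnostics,
#'   covariate scaling, and the design (for downstream decoding/inference).
#' @export
fit_hmm <- function(data, spec, n_starts = 50, seed = 1, init_emissions = NULL,
                    init_params = NULL, n_optim = min(5L, n_starts),
                    maxit = 500, reltol = 1e-8) {
  if (n_starts < 1) stop_invalid("n_starts must be >= 1")
  for (v in c("dive_time", "max_depth", "lunges", "speed", "angle")) {
    if (stats::var(as.numeric(data[[v]])) == 0) {
      stop_invalid("stream %s has no variation; dataset is degenerate", v)
    }
  }
  design <- hmm_design(data, spec)
  set.seed(seed)
  starts <- replicate(n_starts, {
    p <- random_start(data, spec)
    if (!is.null(init_emissions)) {
      for (f in c("gamma_shape", "gamma_rate", "lambda", "mu", "kappa")) {
        p[[f]] <- init_emissions[[f]]
      }
    }
    hmm_pack(p, spec)
  }, simplify = FALSE)
  if (!is.null(init_params)) starts <- c(list(hmm_pack(init_params, spec)), starts)

  nll0 <- vapply(starts, function(w) {
    v <- tryCatch(-core_call(w, spec, design)$loglik, error = function(e) Inf)
    if (!is.finite(v)) Inf else v
  }, numeric(1))
  ord <- order(nll0)[seq_len(min(n_optim, length(starts)))]

  fn <- function(w) {
    v <- core_call(w, spec, design)$loglik
    if (!is.finite(v)) return(1e10)
    -v
  }
  gr <- function(w) {
    res <- tryCatch(core_call(w, spec, design, want_grad = TRUE),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$loglik)) return(rep(0, length(w)))
    -res$grad
  }
  fits <- lapply(ord, function(i) {
    tryCatch(stats::optim(starts[[i]], fn, gr, method = "BFGS",
                          control = list(maxit = maxit, reltol = reltol)),
             error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  conv <- vapply(fits[ok], function(f) f$convergence %in% c(0L, 1L), logical(1))
  if (!any(ok) || !any(vapply(fits[ok], function(f) is.finite(f$value), logical(1)))) {
    stop_invalid("no start converged; %d starts attempted", length(ord))
  }
  vals <- vapply(fits, function(f) if (is.null(f)) Inf else f$value, numeric(1))
  best <- which.min(vals)
  w_hat <- fits[[best]]$par
  params <- canonicalize_states(hmm_unpack(w_hat, spec))
  w_hat <- hmm_pack(params, spec)
  names(w_hat) <- working_names(spec)
  np <- n_parameters(spec)
  ll <- core_call(w_hat, spec, design)$loglik
  structure(list(spec = spec, params = params, working = w_hat,
                 loglik = ll, n_parameters = as.integer(np),
                 aic = -2 * ll + 2 * as.integer(np),
                 scaling = design$scaling, design = design, data = data,
                 diagnostics = list(n_starts = length(starts),
                                    n_optimized = length(ord),
                                    best_start = ord[best],
                                    convergence = vapply(fits, function(f)
                                      if (is.null(f)) NA_integer_ else f$convergence,
                                      integer(1)),
                                    all_values = -vals)),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("Context-HMM fit: N=%d states, K=%d context(s), covariate=%s (%s)\n",
              x$spec$n_states, x$spec$n_contexts, x$spec$covariate,
              x$spec$covariate_sharing))
  cat(sprintf("  loglik = %.3f, parameters = %d, AIC = %.3f\n",
              x$loglik, x$n_parameters, x$aic))
  invisible(x)
}

#' AIC of a context-HMM fit
#' @param object an `hmm_fit`.
#' @param ... ignored.
#' @param k penalty per parameter (2 for AIC).
#' @export
AIC.hmm_fit <- function(object, ..., k = 2) -2 * object$loglik + k * object$n_parameters

#' @export
logLik.hmm_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_parameters, class = "logLik")
}

#' Fit and rank candidate model specifications by AIC
#'
#' Fits every candidate spec with a common seed and ranks by AIC; ties are
#' broken toward the model with fewer parameters. Candidate failures are
#' recorded, not fatal.
#'
#' @param data per-dive data frame.
#' @param candidate_specs list of [hmm_spec()] objects.
#' @param n_starts,seed passed to [fit_hmm()].
#' @param ... further arguments for [fit_hmm()] (e.g. `init_emissions`).
#' @return object of class `hmm_selection`: list with `table` (data frame of
#'   candidates, AIC, loglik, parameters, rank), `fits`, `best` (the
#'   top-ranked `hmm_fit`), `failures`.
#' @export
select_model <- function(data, candidate_specs, n_starts = 50, seed = 1, ...) {
  if (length(candidate_specs) < 2) stop_invalid("need at least 2 candidate specs")
  fits <- vector("list", length(candidate_specs))
  errs <- character(length(candidate_specs))
  for (i in seq_along(candidate_specs)) {
    fits[[i]] <- tryCatch(
      fit_hmm(data, candidate_specs[[i]], n_starts = n_starts, seed = seed, ...),
      error = function(e) { errs[i] <<- conditionMessage(e); NULL })
  }
  ok <- !vapply(fits, is.null, logical(1))
  tab <- data.frame(
    candidate = seq_along(candidate_specs),
    n_states = vapply(candidate_specs, `[[`, integer(1), "n_states"),
    n_contexts = vapply(candidate_specs, `[[`, integer(1), "n_contexts"),
    covariate = vapply(candidate_specs, `[[`, character(1), "covariate"),
    sharing = vapply(candidate_specs, `[[`, character(1), "covariate_sharing"),
    n_parameters = vapply(candidate_specs, function(s) as.integer(n_parameters(s)), integer(1)),
    loglik = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$loglik, numeric(1)),
    aic = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$aic, numeric(1)))
  o <- order(round(tab$aic, 9), tab$n_parameters, na.last = TRUE)
  tab$rank <- NA_integer_; tab$rank[o] <- seq_along(o)
  structure(list(table = tab[o, ], fits = fits,
                 best = fits[[o[1]]], failures = errs[!ok & nzchar(errs)]),
            class = "hmm_selection")
}

#' @export
print.hmm_selection <- function(x, ...) {
  cat("Context-HMM model selection (AIC-ranked):\n")
  print(x$table[, c("n_states", "n_contexts", "covariate", "sharing",
                    "n_parameters", "loglik", "aic", "rank")], row.names = FALSE)
  invisible(x)
}

#' Wald confidence intervals for context-HMM working parameters
#'
#' Intervals are computed on the working scale from the inverse of the
#' numerically differentiated Hessian of the negative log-likelihood
#' (observed Fisher information), using the analytic gradient of the fit:
#' \eqn{\hat\beta \pm z_{1-\alpha/2} \cdot se}. Coefficients whose interval
#' excludes zero are flagged. A singular Hessian triggers a warning and a
#' pseudo-inverse fallback (flagged in the result).
#'
#' @param fit an `hmm_fit`.
#' @param level confidence level (default 0.95).
#' @return data frame with estimate, se, lower, upper, `excludes_zero`, plus
#'   attributes `level`, `pseudo_inverse`, and `covariate_rows` (indices of
#'   the exposure-covariate coefficients).
#' @export
wald_ci <- function(fit, level = 0.95) {
  spec <- fit$spec; design <- fit$design
  w <- fit$working
  gr <- function(wv) -core_call(wv, spec, design, want_grad = TRUE)$grad
  H <- stats::optimHess(w, fn = function(wv) -core_call(wv, spec, design)$loglik,
                        gr = gr)
  H <- (H + t(H)) / 2
  pseudo <- FALSE
  V <- tryCatch(solve(H), error = function(e) NULL)
  ev_ok <- !is.null(V) && all(is.finite(V)) && all(diag(V) > 0)
  if (!ev_ok) {
    warning("singular observed-information matrix; using pseudo-inverse (non-identifiability)")
    e <- eigen(H, symmetric = TRUE)
    pos <- e$values > max(e$values) * 1e-10
    V <- e$vectors[, pos, drop = FALSE] %*%
      diag(1 / e$values[pos], sum(pos)) %*% t(e$vectors[, pos, drop = FALSE])
    pseudo <- TRUE
  }
  se <- sqrt(pmax(diag(V), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(parameter = names(w), estimate = unname(w), se = se,
                    lower = unname(w) - z * se, upper = unname(w) + z * se)
  out$excludes_zero <- out$lower > 0 | out$upper < 0
  attr(out, "level") <- level
  attr(out, "z") <- z
  attr(out, "pseudo_inverse") <- pseudo
  attr(out, "covariate_rows") <- grep("^beta", out$parameter)
  out
}

#' Jitter-restart a fitted model
#'
#' Re-optimizes from perturbed copies of the fitted working parameters
#' (emissions held fixed at the estimates) to probe for nearby better optima.
#'
#' @param fit an `hmm_fit`.
#' @param n_trials number of jittered restarts.
#' @param sd jitter standard deviation on the working scale.
#' @param seed RNG seed.
#' @return the best `hmm_fit` found (the input fit if no restart improves it).
#' @export
jitter_refit <- function(fit, n_trials = 10, sd = 0.3, seed = 1) {
  spec <- fit$spec
  n_emis <- 9L * spec$n_states
  set.seed(seed)
  best <- fit
  dat <- fit$data
  for (i in seq_len(n_trials)) {
    w <- fit$working
    idx <- seq_along(w) > n_emis
    w[idx] <- w[idx] + stats::rnorm(sum(idx), 0, sd)
    p0 <- hmm_unpack(unname(w), spec)
    f <- tryCatch(fit_hmm(dat, spec, n_starts = 1, seed = seed + i,
                          init_params = p0, n_optim = 1),
                  error = function(e) NULL)
    if (!is.null(f) && f$loglik > best$loglik) best <- f
  }
  best
}
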
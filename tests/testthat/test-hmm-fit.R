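sim_2state <- function(n_whales = 20, dives = 150, seed = 7) {
  spec <- hmm_spec(2, 1)
  p <- default_hmm_params(spec)
  list(spec = spec, params = p,
       sim = simulate_dives(p, spec, n_whales, dives, seed = seed))
}

test_that("fitting attains at least the likelihood of the generating values", {
  s <- sim_2state(10, 100, seed = 41)
  fit <- fit_hmm(s$sim$data, s$spec, n_starts = 6, seed = 1, n_optim = 2)
  expect_gte(fit$loglik, mixture_loglik(s$sim$data, s$params, s$spec))
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$n_parameters)
})

test_that("fits are deterministic given seed and start count", {
  s <- sim_2state(6, 60, seed = 42)
  f1 <- fit_hmm(s$sim$data, s$spec, n_starts = 4, seed = 9, n_optim = 2)
  f2 <- fit_hmm(s$sim$data, s$spec, n_starts = 4, seed = 9, n_optim = 2)
  expect_identical(f1$working, f2$working)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("well-separated two-state emissions are recovered within 10%", {
  s <- sim_2state(20, 150, seed = 43)
  fit <- fit_hmm(s$sim$data, s$spec, n_starts = 8, seed = 3, n_optim = 2)
  true_means <- list(
    time = s$params$gamma_shape[1, ] / s$params$gamma_rate[1, ],
    depth = s$params$gamma_shape[2, ] / s$params$gamma_rate[2, ],
    speed = s$params$gamma_shape[3, ] / s$params$gamma_rate[3, ],
    lambda = s$params$lambda)
  est_means <- list(
    time = fit$params$gamma_shape[1, ] / fit$params$gamma_rate[1, ],
    depth = fit$params$gamma_shape[2, ] / fit$params$gamma_rate[2, ],
    speed = fit$params$gamma_shape[3, ] / fit$params$gamma_rate[3, ],
    lambda = fit$params$lambda)
  # tolerance: 10% relative, widened to 3 Monte-Carlo standard errors of the
  # stream mean for rare streams (the non-feeding lunge rate is ~0.05, so its
  # sampling error dominates a fixed relative band at this sample size)
  n_state <- table(factor(s$sim$truth$states, levels = 1:2))
  mc_se <- list(
    time = sqrt(s$params$gamma_shape[1, ]) / s$params$gamma_rate[1, ] / sqrt(n_state),
    depth = sqrt(s$params$gamma_shape[2, ]) / s$params$gamma_rate[2, ] / sqrt(n_state),
    speed = sqrt(s$params$gamma_shape[3, ]) / s$params$gamma_rate[3, ] / sqrt(n_state),
    lambda = sqrt(s$params$lambda / n_state))
  for (f in names(true_means)) {
    tol <- pmax(0.10 * true_means[[f]], 3 * as.numeric(mc_se[[f]]))
    expect_true(all(abs(est_means[[f]] - true_means[[f]]) < tol), info = f)
  }
  # canonical ordering: state 1 is the deepest
  expect_gt(est_means$depth[1], est_means$depth[2])
})

test_that("degenerate data and zero starts are rejected", {
  d <- toy_dives(30)
  d$speed <- 1.5
  expect_error(fit_hmm(d, hmm_spec(2, 1)), "no variation")
  expect_error(fit_hmm(toy_dives(30), hmm_spec(2, 1), n_starts = 0), "n_starts")
})

test_that("model selection ranks by AIC with ties broken by parsimony", {
  s <- sim_2state(8, 80, seed = 44)
  sel <- select_model(s$sim$data, list(hmm_spec(2, 1), hmm_spec(2, 1)),
                      n_starts = 3, seed = 5, n_optim = 1)
  # identical candidates: identical AIC, rank order by parameter count first
  expect_equal(sel$table$aic[1], sel$table$aic[2], tolerance = 1e-8)
  for (i in seq_along(sel$fits)) {
    f <- sel$fits[[i]]
    expect_equal(f$aic, -2 * f$loglik + 2 * f$n_parameters)
  }
  expect_error(select_model(s$sim$data, list(hmm_spec(2, 1))), "2 candidate")
})

test_that("Wald intervals match analytic Fisher information where known", {
  # one-state model: the likelihood factorizes and the information for the
  # log Poisson mean is n * lambda, so se(log lambda) = 1 / sqrt(n * lambda)
  spec <- hmm_spec(1, 1)
  p <- default_hmm_params(spec)
  sim <- simulate_dives(p, spec, 1, 400, seed = 51)
  fit <- fit_hmm(sim$data, spec, n_starts = 3, seed = 2, n_optim = 1)
  ci <- wald_ci(fit)
  lam_hat <- fit$params$lambda[1]
  expect_equal(mean(sim$data$lunges), lam_hat, tolerance = 1e-5)
  se_hat <- ci$se[ci$parameter == "log_lambda.s1"]
  expect_equal(se_hat, 1 / sqrt(400 * lam_hat), tolerance = 1e-3)
  # interval always contains the estimate; normal quantile at 0.95
  expect_true(all(ci$lower <= ci$estimate & ci$estimate <= ci$upper))
  expect_equal(attr(ci, "z"), qnorm(0.975))
  expect_equal(attr(ci, "z"), 1.959964, tolerance = 1e-6)
})

test_that("jitter restarts never return a worse fit", {
  s <- sim_2state(5, 50, seed = 45)
  fit <- fit_hmm(s$sim$data, s$spec, n_starts = 3, seed = 4, n_optim = 1)
  jf <- jitter_refit(fit, n_trials = 2, seed = 6)
  expect_gte(jf$loglik, fit$loglik - 1e-6)
})
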
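test_that("transition rows follow the multinomial-logit link", {
  # softmax of zeros
  expect_equal(tpm_from_logits(c(0, 0), state = 1), rep(1 / 3, 3))
  # closed-form softmax with the diagonal as reference
  expect_equal(tpm_from_logits(c(log(2), log(3)), state = 1),
               c(1 / 6, 2 / 6, 3 / 6))
  # x = 0 reduces to the intercept-only row regardless of beta
  b <- c(5, -7)
  expect_equal(tpm_from_logits(c(0.4, -1), b, covariate_value = 0, state = 2),
               tpm_from_logits(c(0.4, -1), state = 2))
  # reference slot sits on the diagonal
  r2 <- tpm_from_logits(c(log(2), log(3)), state = 3)
  expect_equal(r2, c(2 / 6, 3 / 6, 1 / 6))
  expect_error(tpm_from_logits(c(Inf, 0), state = 1), "standardize")
  # rows of a full matrix sum to 1 at any covariate value
  spec <- hmm_spec(3, 2, covariate = "max_rl")
  p <- toy_params(spec)
  G <- transition_matrix(p, 2, 1.7)
  expect_equal(rowSums(G), rep(1, 3))
})

test_that("transition probability is monotone in a positive covariate effect", {
  spec <- hmm_spec(3, 1, covariate = "exposure_binary")
  p <- toy_params(spec)
  p$beta[] <- 0
  p <- set_beta(p, 2, 1, 1.2)
  xs <- seq(-2, 2, by = 0.5)
  g21 <- vapply(xs, function(x) transition_matrix(p, 1, x)[2, 1], numeric(1))
  expect_true(all(diff(g21) > 0))
})

test_that("emission log density is the sum of the five stream densities", {
  spec <- hmm_spec(2, 1)
  p <- toy_params(spec)
  rec <- list(dive_time = 310, max_depth = 140, lunges = 3, speed = 1.7,
              angle = 0.8)
  # term-by-term hand evaluation (oracle_emission writes the formulas out)
  expect_equal(emission_logdensity(rec, state_emission(p, 1)),
               oracle_emission(rec, p, 1), tolerance = 1e-12)
  expect_equal(emission_logdensity(rec, state_emission(p, 2)),
               oracle_emission(rec, p, 2), tolerance = 1e-12)
  # kappa = 0: the angle contributes the circular uniform density
  sp <- state_emission(p, 1); sp$kappa <- 0
  base <- emission_logdensity(rec, sp)
  rec2 <- rec; rec2$angle <- -2.9
  expect_equal(emission_logdensity(rec2, sp), base)
  # non-positive gamma values are outside the support
  rec3 <- rec; rec3$dive_time <- 0
  expect_warning(v <- emission_logdensity(rec3, state_emission(p, 1)),
                 "non-positive")
  expect_identical(v, -Inf)
})

test_that("forward log-likelihood matches brute-force path enumeration", {
  # degenerate cases
  spec1 <- hmm_spec(2, 1)
  p1 <- toy_params(spec1)
  d1 <- toy_dives(1, seed = 4)
  lp1 <- vapply(1:2, function(n)
    oracle_emission(d1[1, ], p1, n), numeric(1))
  expect_equal(forward_loglik(d1, p1, spec1),
               logsumexp(log(p1$delta[1, ]) + lp1), tolerance = 1e-12)
  specN1 <- hmm_spec(1, 1)
  pN1 <- toy_params(specN1)
  dN <- toy_dives(5, seed = 6)
  expect_equal(forward_loglik(dN, pN1, specN1),
               sum(vapply(seq_len(5), function(t)
                 oracle_emission(dN[t, ], pN1, 1), numeric(1))),
               tolerance = 1e-12)
  # enumeration oracle across T, N, K and covariate settings
  for (N in 2:3) for (Tn in c(3, 6)) for (K in 1:2) {
    spec <- hmm_spec(N, K, covariate = "exposure_binary")
    p <- toy_params(spec)
    d <- toy_dives(Tn, seed = N * 10 + Tn + K, exposure = c(0, 1))
    for (k in seq_len(K)) {
      expect_lt(abs(forward_loglik(d, p, spec, context = k) -
                      oracle_forward_loglik(d, p, spec, k)), 1e-10)
    }
  }
})

test_that("mixture log-likelihood combines whales and contexts correctly", {
  spec <- hmm_spec(2, 2)
  p <- toy_params(spec)
  d <- rbind(toy_dives(3, seed = 1, whale = "w1"),
             toy_dives(4, seed = 2, whale = "w2"))
  # hand log-sum-exp over per-context forward logliks
  hand <- 0
  for (wh in c("w1", "w2")) {
    dw <- d[d$whale == wh, ]
    lk <- vapply(1:2, function(k) oracle_forward_loglik(dw, p, spec, k),
                 numeric(1))
    hand <- hand + logsumexp(log(p$pi) + lk)
  }
  expect_equal(mixture_loglik(d, p, spec), hand, tolerance = 1e-10)
  # K = 1 degenerates to the sum of forward logliks
  spec1 <- hmm_spec(2, 1)
  p1 <- toy_params(spec1)
  expect_equal(mixture_loglik(d, p1, spec1),
               forward_loglik(d[d$whale == "w1", ], p1, spec1) +
                 forward_loglik(d[d$whale == "w2", ], p1, spec1),
               tolerance = 1e-12)
  # identical contexts: value independent of the mixing distribution
  p_same <- p
  p_same$eta0[2, , ] <- p_same$eta0[1, , ]
  p_same$delta[2, ] <- p_same$delta[1, ]
  v1 <- mixture_loglik(d, p_same, spec)
  p_same$pi <- c(0.9, 0.1)
  expect_equal(mixture_loglik(d, p_same, spec), v1, tolerance = 1e-12)
  # the C++ engine agrees with the R recursion
  dsg <- hmm_design(d, spec)
  expect_equal(sonarCEE:::core_call(hmm_pack(p, spec), spec, dsg)$loglik,
               hand, tolerance = 1e-10)
})

test_that("mixture likelihood is invariant to state and context relabelling", {
  spec <- hmm_spec(3, 2, covariate = "exposure_binary")
  p <- toy_params(spec)
  p <- set_beta(p, 2, 1, 0.7)
  d <- rbind(toy_dives(5, seed = 31, exposure = c(0, 1), whale = "w1"),
             toy_dives(5, seed = 32, exposure = c(1, 0), whale = "w2"))
  base <- mixture_loglik(d, p, spec)
  # permute states
  o <- c(3, 1, 2)
  ps <- p
  ps$gamma_shape <- p$gamma_shape[, o]; ps$gamma_rate <- p$gamma_rate[, o]
  ps$lambda <- p$lambda[o]; ps$mu <- p$mu[o]; ps$kappa <- p$kappa[o]
  ps$eta0 <- p$eta0[, o, o, drop = FALSE]
  ps$beta <- p$beta[, o, o, , drop = FALSE]
  ps$delta <- p$delta[, o, drop = FALSE]
  expect_equal(mixture_loglik(d, ps, spec), base, tolerance = 1e-10)
  # permute contexts together with the mixing probabilities
  pc <- p
  pc$eta0 <- p$eta0[c(2, 1), , , drop = FALSE]
  pc$delta <- p$delta[c(2, 1), , drop = FALSE]
  pc$pi <- p$pi[c(2, 1)]
  expect_equal(mixture_loglik(d, pc, spec), base, tolerance = 1e-10)
})

test_that("parameter counts match the stated breakdown", {
  # N = 3 with a shared continuous covariate: six covariate coefficients
  s <- hmm_spec(3, 5, covariate = "max_rl", covariate_sharing = "shared")
  expect_equal(unname(attr(n_parameters(s), "breakdown")["covariate"]), 6L)
  # N = 3, K = 1, no covariate: 27 + 6 + 2 = 35
  expect_equal(as.integer(n_parameters(hmm_spec(3, 1))), 35L)
  # N = 3, K = 5, shared covariate: 27 + 30 + 10 + 4 + 6 = 77
  expect_equal(as.integer(n_parameters(s)), 77L)
  # per-context and phase covariates scale as documented
  expect_equal(as.integer(n_parameters(
    hmm_spec(3, 2, covariate = "max_rl", covariate_sharing = "per_context"))),
    27L + 12L + 4L + 1L + 12L)
  expect_equal(as.integer(n_parameters(hmm_spec(3, 1, covariate = "phase_categorical"))),
               27L + 6L + 2L + 0L + 12L)
  # pack/unpack round trip has exactly that length and inverts
  spec <- hmm_spec(3, 2, covariate = "exposure_binary")
  p <- toy_params(spec)
  w <- hmm_pack(p, spec)
  expect_length(w, as.integer(n_parameters(spec)))
  p2 <- hmm_unpack(w, spec)
  for (f in c("gamma_shape", "gamma_rate", "lambda", "mu", "kappa", "eta0",
              "beta", "delta", "pi")) {
    expect_equal(p2[[f]], p[[f]], tolerance = 1e-12, info = f)
  }
})
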
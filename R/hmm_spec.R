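#' Specify a context hidden Markov model
#'
#' The model is an N-state HMM over per-dive observation vectors
#' (dive time, maximum depth, lunge count, speed over ground, turning angle)
#' with emission families gamma / gamma / Poisson / gamma / von Mises.
#' Whale-to-whale heterogeneity in state switching is captured by K discrete
#' random-effect "contexts": each whale belongs to one latent context, drawn
#' from mixing probabilities, and contexts have their own transition intercepts
#' and initial state distributions. Emission parameters are shared across
#' contexts. A sound-exposure covariate can act on the off-diagonal transition
#' logits, with its coefficients either shared across contexts or
#' context-specific.
#'
#' @param n_states number of behavioural states N (default 3).
#' @param n_contexts number of discrete random-effect contexts K (1 to 6).
#' @param covariate transition covariate: `"none"`, `"exposure_binary"`,
#'   `"phase_categorical"` (two dummies, reference = before), `"avg_rl"`, or
#'   `"max_rl"`.
#' @param covariate_sharing `"shared"` (one coefficient set across contexts)
#'   or `"per_context"`.
#' @return an object of class `hmm_spec`.
#' @export
hmm_spec <- function(n_states = 3, n_contexts = 1,
                     covariate = c("none", "exposure_binary",
                                   "phase_categorical", "avg_rl", "max_rl"),
                     covariate_sharing = c("shared", "per_context")) {
  covariate <- match.arg(covariate)
  covariate_sharing <- match.arg(covariate_sharing)
  if (n_contexts < 1 || n_contexts > 6) stop_invalid("n_contexts must be in 1..6")
  if (n_states < 1) stop_invalid("n_states must be >= 1")
  if (covariate != "none" && n_states < 2) {
    stop_invalid("a transition covariate requires at least 2 states")
  }
  structure(list(n_states = as.integer(n_states),
                 n_contexts = as.integer(n_contexts),
                 covariate = covariate,
                 covariate_sharing = covariate_sharing,
                 n_cov_cols = switch(covariate, none = 0L,
                                     phase_categorical = 2L, 1L)),
            class = "hmm_spec")
}

#' @export
print.hmm_spec <- function(x, ...) {
  cat(sprintf("HMM spec: %d states, %d context(s), covariate = %s (%s)\n",
              x$n_states, x$n_contexts, x$covariate, x$covariate_sharing))
  invisible(x)
}

#' Count free parameters of a context-HMM specification
#'
#' Per state the five emission families contribute 2+2+1+2+2 = 9 parameters
#' (shared across contexts). Each context carries N(N-1) transition intercepts
#' and N-1 initial-distribution logits; the context mixture adds K-1 mixing
#' parameters. A covariate adds one coefficient per off-diagonal transition
#' entry and design column, times K when context-specific.
#'
#' @param spec an [hmm_spec()].
#' @return integer count, with a named `breakdown` attribute.
#' @export
n_parameters <- function(spec) {
  N <- spec$n_states; K <- spec$n_contexts; P <- spec$n_cov_cols
  br <- c(emission = 9L * N,
          transition = K * N * (N - 1L),
          initial = K * (N - 1L),
          mixing = K - 1L,
          covariate = P * N * (N - 1L) *
            (if (spec$covariate_sharing == "per_context") K else 1L))
  structure(sum(br), breakdown = br)
}

#' Transition-probability row from multinomial logits
#'
#' Builds one row of a covariate-dependent transition probability matrix with
#' the diagonal (self-transition) entry as the multinomial-logit reference:
#' \eqn{\gamma_{ij} \propto \exp(\eta_{ij} + \beta_{ij} x)} for \eqn{j \ne i}
#' and \eqn{\gamma_{ii} \propto 1}.
#'
#' @param intercepts_row numeric length N-1: intercepts for the off-diagonal
#'   destinations in increasing state order.
#' @param beta_row covariate coefficients: vector length N-1 or a
#'   P x (N-1) matrix for a P-column covariate design; `NULL` for none.
#' @param covariate_value covariate value(s), length P.
#' @param state the row's own state index i (the reference destination).
#' @return numeric row of length N summing to 1.
#' @export
#' @examples
#' tpm_from_logits(c(log(2), log(3)), state = 1)  # (1/6, 2/6, 3/6)
tpm_from_logits <- function(intercepts_row, beta_row = NULL,
                            covariate_value = 0, state = 1L) {
  N <- length(intercepts_row) + 1L
  eff <- intercepts_row
  if (!is.null(beta_row)) {
    b <- if (is.matrix(beta_row)) beta_row else matrix(beta_row, nrow = 1)
    eff <- eff + as.numeric(crossprod(matrix(covariate_value, ncol = 1), b))
  }
  logits <- append(eff, 0, after = state - 1L)
  if (any(!is.finite(logits))) {
    stop_invalid("non-finite transition logits; standardize the covariate")
  }
  e <- exp(logits - max(logits))
  e / sum(e)
}

#' Full transition matrix for one context at one covariate value
#'
#' @param params an `hmm_params` list (see [default_hmm_params()]).
#' @param context context index.
#' @param x covariate value(s) (length = number of design columns; ignored
#'   when the model has no covariate).
#' @return N x N transition probability matrix.
#' @export
transition_matrix <- function(params, context = 1L, x = 0) {
  N <- ncol(params$delta)
  G <- matrix(0, N, N)
  for (i in seq_len(N)) {
    eta <- params$eta0[context, i, -i]
    brow <- NULL
    if (!is.null(params$beta)) {
      kb <- if (dim(params$beta)[4] == 1L) 1L else context
      brow <- matrix(params$beta[, i, -i, kb],
                     nrow = dim(params$beta)[1])
    }
    G[i, ] <- tpm_from_logits(eta, brow, x, state = i)
  }
  G
}

#' Log density of one dive under one state's emission parameters
#'
#' The five observation streams are conditionally independent given the state,
#' so the joint log density is the sum of the gamma (dive time), gamma (max
#' depth), Poisson (lunges), gamma (speed) and von Mises (turning angle) log
#' densities. Non-positive values in a gamma stream yield `-Inf` with a
#' warning: they are outside the model's support and a data-cleaning concern.
#'
#' @param record list or one-row data frame with `dive_time`, `max_depth`,
#'   `lunges`, `speed`, `angle`.
#' @param state_params list with `shape`, `rate` (each length 3, in stream
#'   order dive time / max depth / speed), `lambda`, `mu`, `kappa`.
#' @return scalar log density.
#' @export
emission_logdensity <- function(record, state_params) {
  y <- c(record$dive_time, record$max_depth, record$speed)
  if (any(y <= 0)) {
    warning("non-positive value in a gamma stream; log density is -Inf")
    return(-Inf)
  }
  sum(stats::dgamma(y, shape = state_params$shape,
                    rate = state_params$rate, log = TRUE)) +
    stats::dpois(record$lunges, state_params$lambda, log = TRUE) +
    dvonmises(record$angle, state_params$mu, state_params$kappa)
}

#' Extract one state's emission parameters from an `hmm_params` object
#' @param params `hmm_params`.
#' @param state state index.
#' @return list(shape, rate, lambda, mu, kappa).
#' @export
state_emission <- function(params, state) {
  list(shape = params$gamma_shape[, state], rate = params$gamma_rate[, state],
       lambda = params$lambda[state], mu = params$mu[state],
       kappa = params$kappa[state])
}

validate_hmm_params <- function(params, spec) {
  N <- spec$n_states; K <- spec$n_contexts
  stopifnot(dim(params$gamma_shape) == c(3, N), dim(params$gamma_rate) == c(3, N),
            length(params$lambda) == N, length(params$mu) == N,
            length(params$kappa) == N, dim(params$delta) == c(K, N),
            length(params$pi) == K, dim(params$eta0) == c(K, N, N))
  if (any(params$gamma_shape <= 0) || any(params$gamma_rate <= 0) ||
      any(params$lambda <= 0) || any(params$kappa < 0)) {
    stop_invalid("emission parameters out of range (need positive gamma/Poisson parameters, kappa >= 0)")
  }
  if (any(abs(rowSums(params$delta) - 1) > 1e-8) || abs(sum(params$pi) - 1) > 1e-8) {
    stop_invalid("delta rows and pi must sum to 1")
  }
  if (spec$covariate != "none") {
    stopifnot(!is.null(params$beta),
              dim(params$beta) == c(spec$n_cov_cols, N, N,
                                    if (spec$covariate_sharing == "per_context") K else 1L))
  }
  invisible(params)
}

#' Pack natural-scale parameters into the working vector
#'
#' Working scale: log for gamma shapes/rates, Poisson means and von Mises
#' concentrations; identity for the von Mises mean, transition intercepts and
#' covariate coefficients; multinomial logits (reference = first level) for
#' initial distributions and context mixing probabilities. Order: emissions
#' (9N), transition intercepts (K blocks, row-major off-diagonals), covariate
#' coefficients, initial logits, mixing logits.
#'
#' @param params natural-scale `hmm_params`.
#' @param spec matching [hmm_spec()].
#' @return numeric working vector of length [n_parameters()].
#' @export
hmm_pack <- function(params, spec) {
  N <- spec$n_states; K <- spec$n_contexts
  w <- c(log(params$gamma_shape[1, ]), log(params$gamma_rate[1, ]),
         log(params$gamma_shape[2, ]), log(params$gamma_rate[2, ]),
         log(params$lambda),
         log(params$gamma_shape[3, ]), log(params$gamma_rate[3, ]),
         params$mu, log(params$kappa))
  for (k in seq_len(K)) for (i in seq_len(N)) w <- c(w, params$eta0[k, i, -i])
  if (spec$covariate != "none") {
    Kb <- dim(params$beta)[4]
    for (k in seq_len(Kb)) for (p in seq_len(spec$n_cov_cols))
      for (i in seq_len(N)) w <- c(w, params$beta[p, i, -i, k])
  }
  for (k in seq_len(K)) w <- c(w, log(params$delta[k, -1] / params$delta[k, 1]))
  if (K > 1) w <- c(w, log(params$pi[-1] / params$pi[1]))
  stopifnot(length(w) == n_parameters(spec))
  w
}

#' Unpack a working vector into natural-scale parameters
#'
#' Inverse of [hmm_pack()].
#'
#' @param w working vector.
#' @param spec matching [hmm_spec()].
#' @return natural-scale `hmm_params` list.
#' @export
hmm_unpack <- function(w, spec) {
  N <- spec$n_states; K <- spec$n_contexts; P <- spec$n_cov_cols
  stopifnot(length(w) == n_parameters(spec))
  pos <- 0L
  take <- function(n) { v <- w[pos + seq_len(n)]; pos <<- pos + n; v }
  gs <- matrix(0, 3, N); gr <- matrix(0, 3, N)
  gs[1, ] <- exp(take(N)); gr[1, ] <- exp(take(N))
  gs[2, ] <- exp(take(N)); gr[2, ] <- exp(take(N))
  lambda <- exp(take(N))
  gs[3, ] <- exp(take(N)); gr[3, ] <- exp(take(N))
  mu <- wrap_angle(take(N)); kappa <- exp(take(N))
  eta0 <- array(0, c(K, N, N))
  for (k in seq_len(K)) for (i in seq_len(N)) eta0[k, i, -i] <- take(N - 1L)
  beta <- NULL
  if (spec$covariate != "none") {
    Kb <- if (spec$covariate_sharing == "per_context") K else 1L
    beta <- array(0, c(P, N, N, Kb))
    for (k in seq_len(Kb)) for (p in seq_len(P))
      for (i in seq_len(N)) beta[p, i, -i, k] <- take(N - 1L)
  }
  delta <- matrix(0, K, N)
  for (k in seq_len(K)) {
    e <- exp(c(0, take(N - 1L))); delta[k, ] <- e / sum(e)
  }
  pi_k <- if (K > 1) { e <- exp(c(0, take(K - 1L))); e / sum(e) } else 1
  rownames(gs) <- rownames(gr) <- c("dive_time", "max_depth", "speed")
  structure(list(gamma_shape = gs, gamma_rate = gr, lambda = lambda,
                 mu = mu, kappa = kappa, eta0 = eta0, beta = beta,
                 delta = delta, pi = pi_k),
            class = "hmm_params")
}
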
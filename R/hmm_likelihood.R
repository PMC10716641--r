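#' Build the numeric design for the context-HMM from a dive table
#'
#' Expects one row per dive with columns `whale`, `dive_time`, `max_depth`,
#' `lunges`, `speed`, `angle`, plus whatever covariate the spec names
#' (`exposure`, `phase`, `avg_rl`, `max_rl`). Dives are kept in input order;
#' rows of one whale must be contiguous. Continuous received-level covariates
#' are standardized using the mean and standard deviation over exposed dives
#' (RL > 0) only, with unexposed dives kept exactly at 0 so that the
#' "no exposure" baseline of the transition model is preserved.
#'
#' Non-positive values in a gamma stream (dive time, depth, speed) are floored
#' at a tiny positive value with a warning: they are outside the emission
#' families' support.
#'
#' @param data per-dive data frame.
#' @param spec an [hmm_spec()].
#' @param scaling optional list(center, scale) to reuse a previous
#'   standardization (e.g. when evaluating held-out data).
#' @return list with `y` (T x 5 matrix), `wid` (integer whale index),
#'   `X` (covariate design), `whales` (id levels), `scaling`.
#' @export
hmm_design <- function(data, spec, scaling = NULL) {
  need <- c("whale", "dive_time", "max_depth", "lunges", "speed", "angle")
  if (!all(need %in% names(data))) {
    stop_invalid("dive table must have columns %s", paste(need, collapse = ", "))
  }
  whales <- unique(as.character(data$whale))
  wid <- match(as.character(data$whale), whales)
  if (any(diff(wid) < 0)) stop_invalid("rows of each whale must be contiguous")
  y <- as.matrix(data[, c("dive_time", "max_depth", "lunges", "speed", "angle")])
  bad <- y[, c(1, 2, 4)] <= 0
  if (any(bad)) {
    warning(sprintf("%d non-positive gamma-stream values floored at 1e-6", sum(bad)))
    yy <- y[, c(1, 2, 4)]; yy[bad] <- 1e-6; y[, c(1, 2, 4)] <- yy
  }
  P <- spec$n_cov_cols
  X <- matrix(0, nrow(y), max(P, 1L))
  if (spec$covariate == "exposure_binary") {
    X[, 1] <- as.numeric(data$exposure)
  } else if (spec$covariate == "phase_categorical") {
    X[, 1] <- as.numeric(data$phase == "during")
    X[, 2] <- as.numeric(data$phase == "after")
  } else if (spec$covariate %in% c("avg_rl", "max_rl")) {
    x <- as.numeric(data[[spec$covariate]])
    exposed <- x > 0
    if (is.null(scaling)) {
      if (sum(exposed) >= 2) {
        scaling <- list(center = mean(x[exposed]), scale = stats::sd(x[exposed]))
      } else {
        scaling <- list(center = 0, scale = 1)
      }
      if (!is.finite(scaling$scale) || scaling$scale == 0) scaling$scale <- 1
    }
    X[exposed, 1] <- (x[exposed] - scaling$center) / scaling$scale
  }
  list(y = y, wid = as.integer(wid), X = X, whales = whales, scaling = scaling)
}

core_call <- function(w, spec, design, want_grad = FALSE, want_post = FALSE) {
  hmm_core_cpp(w, spec$n_states, spec$n_contexts, spec$n_cov_cols,
               spec$covariate_sharing == "per_context",
               design$y, design$wid, design$X, want_grad, want_post)
}

#' Forward log-likelihood of one whale's dive sequence under one context
#'
#' Exact HMM log-likelihood via the scaled forward recursion, with the
#' per-dive transition matrix evaluated at that dive's covariate value (the
#' covariate on dive t acts on the transition into dive t).
#'
#' @param sequence data frame of one whale's dives (columns as in
#'   [hmm_design()]; a `whale` column is optional).
#' @param params natural-scale `hmm_params`.
#' @param spec an [hmm_spec()].
#' @param context context index whose switching regime is used.
#' @param scaling optional standardization to apply to RL covariates.
#' @return scalar log-likelihood.
#' @export
forward_loglik <- function(sequence, params, spec, context = 1L, scaling = NULL) {
  if (nrow(sequence) == 0) stop_invalid("sequence must be non-empty")
  sequence$whale <- "w"
  d <- hmm_design(sequence, spec, scaling = scaling)
  N <- spec$n_states
  lp <- matrix(0, nrow(d$y), N)
  for (n in seq_len(N)) {
    sp <- state_emission(params, n)
    lp[, n] <- stats::dgamma(d$y[, 1], sp$shape[1], sp$rate[1], log = TRUE) +
      stats::dgamma(d$y[, 2], sp$shape[2], sp$rate[2], log = TRUE) +
      stats::dpois(d$y[, 3], sp$lambda, log = TRUE) +
      stats::dgamma(d$y[, 4], sp$shape[3], sp$rate[3], log = TRUE) +
      dvonmises(d$y[, 5], sp$mu, sp$kappa)
  }
  la <- log(params$delta[context, ]) + lp[1, ]
  for (t in seq_len(nrow(d$y))[-1]) {
    G <- transition_matrix(params, context, d$X[t, ])
    la <- apply(log(G) + la, 2, logsumexp) + lp[t, ]
  }
  logsumexp(la)
}

#' Mixture log-likelihood of a multi-whale dataset
#'
#' Whales are independent; each whale's likelihood is a mixture over the K
#' discrete random-effect contexts weighted by the mixing probabilities,
#' evaluated with log-sum-exp:
#' \deqn{\ell = \sum_w \log \sum_k \pi_k \exp(\ell_{wk})}
#'
#' @param data per-dive data frame for all whales.
#' @param params natural-scale `hmm_params`.
#' @param spec an [hmm_spec()].
#' @param scaling optional RL standardization.
#' @return scalar log-likelihood.
#' @export
mixture_loglik <- function(data, params, spec, scaling = NULL) {
  if (length(unique(data$whale)) < 1) stop_invalid("need at least one whale")
  if (is.null(scaling) && spec$covariate %in% c("avg_rl", "max_rl")) {
    scaling <- hmm_design(data, spec)$scaling
  }
  ll <- 0
  for (wh in unique(as.character(data$whale))) {
    seqw <- data[as.character(data$whale) == wh, , drop = FALSE]
    lk <- vapply(seq_len(spec$n_contexts), function(k) {
      forward_loglik(seqw, params, spec, context = k, scaling = scaling)
    }, numeric(1))
    ll <- ll + logsumexp(log(params$pi) + lk)
  }
  ll
}
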
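# Independent oracles: brute-force enumeration of the HMM likelihood and
# posteriors over all state paths and contexts, plus small fixed parameter
# sets. These never call the package's forward/backward code paths.

toy_params <- function(spec) {
  N <- spec$n_states; K <- spec$n_contexts
  m_time <- seq(400, 100, length.out = max(N, 2))[seq_len(N)]
  m_dep <- seq(200, 20, length.out = max(N, 2))[seq_len(N)]
  gs <- rbind(dive_time = rep(9, N), max_depth = rep(16, N), speed = rep(9, N))
  gr <- gs / rbind(m_time, m_dep, seq(1.2, 2, length.out = max(N, 2))[seq_len(N)])
  rownames(gr) <- rownames(gs)
  eta0 <- array(0, c(K, N, N))
  for (k in seq_len(K)) for (i in seq_len(N)) for (j in seq_len(N))
    if (i != j) eta0[k, i, j] <- -1 - 0.3 * k + 0.2 * j
  beta <- NULL
  if (spec$covariate != "none") {
    Kb <- if (spec$covariate_sharing == "per_context") K else 1L
    beta <- array(0.3, c(spec$n_cov_cols, N, N, Kb))
    for (k in seq_len(Kb)) for (i in seq_len(N)) beta[, i, i, k] <- 0
  }
  delta <- matrix(seq_len(N) + 1, K, N, byrow = TRUE)
  delta <- delta / rowSums(delta)
  pik <- (seq_len(K) + 2); pik <- pik / sum(pik)
  structure(list(gamma_shape = gs, gamma_rate = gr,
                 lambda = seq(0.5, 3, length.out = max(N, 2))[seq_len(N)],
                 mu = seq(-0.5, 0.5, length.out = max(N, 2))[seq_len(N)],
                 kappa = seq(0.5, 2, length.out = max(N, 2))[seq_len(N)],
                 eta0 = eta0, beta = beta, delta = delta, pi = pik),
            class = "hmm_params")
}

# per-record emission log density written out long-hand (no package calls)
oracle_emission <- function(rec, params, n) {
  g <- function(y, a, b) a * log(b) - lgamma(a) + (a - 1) * log(y) - b * y
  vm <- function(x, mu, k) k * cos(x - mu) - log(2 * pi * besselI(k, 0))
  unname(g(rec$dive_time, params$gamma_shape[1, n], params$gamma_rate[1, n]) +
    g(rec$max_depth, params$gamma_shape[2, n], params$gamma_rate[2, n]) +
    rec$lunges * log(params$lambda[n]) - params$lambda[n] - lgamma(rec$lunges + 1) +
    g(rec$speed, params$gamma_shape[3, n], params$gamma_rate[3, n]) +
    vm(rec$angle, params$mu[n], params$kappa[n]))
}

oracle_tpm <- function(params, k, i, x) {
  N <- ncol(params$delta)
  lg <- numeric(N)
  for (j in seq_len(N)) {
    if (j == i) next
    lg[j] <- params$eta0[k, i, j]
    if (!is.null(params$beta)) {
      kb <- if (dim(params$beta)[4] > 1) k else 1
      lg[j] <- lg[j] + sum(params$beta[, i, j, kb] * x)
    }
  }
  exp(lg) / sum(exp(lg))
}

# joint weight of (context, path) for one whale's records; xmat: T x P design
oracle_path_weight <- function(dw, params, k, path, xmat) {
  lw <- log(params$pi[k]) + log(params$delta[k, path[1]]) +
    oracle_emission(dw[1, ], params, path[1])
  for (t in seq_along(path)[-1]) {
    p_row <- oracle_tpm(params, k, path[t - 1], xmat[t, ])
    lw <- lw + log(p_row[path[t]]) + oracle_emission(dw[t, ], params, path[t])
  }
  lw
}

oracle_xmat <- function(dw, spec) {
  X <- matrix(0, nrow(dw), max(spec$n_cov_cols, 1))
  if (spec$covariate == "exposure_binary") X[, 1] <- dw$exposure
  X
}

# brute-force mixture loglik over all whales
oracle_mixture_loglik <- function(data, params, spec) {
  tot <- 0
  N <- spec$n_states
  for (wh in unique(data$whale)) {
    dw <- data[data$whale == wh, , drop = FALSE]
    xmat <- oracle_xmat(dw, spec)
    lws <- c()
    for (k in seq_len(spec$n_contexts)) {
      paths <- as.matrix(expand.grid(rep(list(seq_len(N)), nrow(dw))))
      lws <- c(lws, apply(paths, 1, function(p)
        oracle_path_weight(dw, params, k, p, xmat)))
    }
    m <- max(lws)
    tot <- tot + m + log(sum(exp(lws - m)))
  }
  tot
}

# brute-force forward loglik for one whale under one fixed context
oracle_forward_loglik <- function(dw, params, spec, k) {
  N <- spec$n_states
  xmat <- oracle_xmat(dw, spec)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), nrow(dw))))
  lws <- apply(paths, 1, function(p)
    oracle_path_weight(dw, params, k, p, xmat)) - log(params$pi[k])
  m <- max(lws)
  m + log(sum(exp(lws - m)))
}

# brute-force per-dive state posteriors (mixture over contexts) for one whale
oracle_state_posteriors <- function(dw, params, spec) {
  N <- spec$n_states
  Tn <- nrow(dw)
  xmat <- oracle_xmat(dw, spec)
  post <- matrix(0, Tn, N)
  ctx <- numeric(spec$n_contexts)
  all_w <- list()
  for (k in seq_len(spec$n_contexts)) {
    paths <- as.matrix(expand.grid(rep(list(seq_len(N)), Tn)))
    lw <- apply(paths, 1, function(p) oracle_path_weight(dw, params, k, p, xmat))
    all_w[[k]] <- list(paths = paths, lw = lw)
  }
  m <- max(unlist(lapply(all_w, `[[`, "lw")))
  Z <- sum(unlist(lapply(all_w, function(a) exp(a$lw - m))))
  for (k in seq_len(spec$n_contexts)) {
    wgt <- exp(all_w[[k]]$lw - m) / Z
    ctx[k] <- sum(wgt)
    for (t in seq_len(Tn)) for (n in seq_len(N))
      post[t, n] <- post[t, n] + sum(wgt[all_w[[k]]$paths[, t] == n])
  }
  list(state_post = post, context_post = ctx)
}

# small synthetic dive record table with optional exposure column
toy_dives <- function(n, seed = 1, exposure = NULL, whale = "w1") {
  set.seed(seed)
  d <- data.frame(
    whale = whale,
    dive_time = stats::rgamma(n, 9, 9 / 250),
    max_depth = stats::rgamma(n, 16, 16 / 100),
    lunges = stats::rpois(n, 1.5),
    speed = stats::rgamma(n, 9, 9 / 1.5),
    angle = wrap_angle(stats::runif(n, -pi, pi)))
  if (!is.null(exposure)) d$exposure <- rep_len(exposure, n)
  d
}
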
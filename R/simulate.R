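#' Default generating parameters for the context-HMM simulator
#'
#' Emission parameters describe three behavioural states of a foraging fin
#' whale, ordered by descending depth: state 1 "deep feeding" (long, deep,
#' lunge-rich dives), state 2 "non-feeding" (intermediate travel dives, fast
#' and directed), state 3 "shallow feeding" (short, shallow dives with some
#' lunges and more turning). Means/dispersions are desk-scale choices typical
#' of biologging records of rorquals. Contexts differ in their switching
#' regime: context k favours transitions into (and persistence of) state
#' `((k - 1) mod N) + 1`, and in its initial state distribution; the context
#' mixture is uniform by default.
#'
#' @param spec an [hmm_spec()].
#' @param context_strength logit boost applied to transitions into each
#'   context's favoured state.
#' @return natural-scale `hmm_params`.
#' @export
default_hmm_params <- function(spec, context_strength = 1.5) {
  N <- spec$n_states; K <- spec$n_contexts
  # per-state (deep feeding, non-feeding, shallow feeding) means and sds
  m_time <- c(420, 180, 120); s_time <- c(120, 60, 48)
  m_dep <- c(250, 60, 25);   s_dep <- c(60, 20, 8)
  lam <- c(4, 0.05, 1.5)
  m_sp <- c(1.5, 2.0, 1.2);  s_sp <- c(0.5, 0.6, 0.4)
  kap <- c(1, 4, 0.5)
  idx <- rep_len(seq_len(3), N)
  gs <- rbind(dive_time = (m_time / s_time)^2,
              max_depth = (m_dep / s_dep)^2,
              speed = (m_sp / s_sp)^2)[, idx, drop = FALSE]
  gr <- gs / rbind(m_time, m_dep, m_sp)[, idx, drop = FALSE]
  rownames(gr) <- rownames(gs)
  eta0 <- array(-2.2, c(K, N, N))
  delta <- matrix(1 / N, K, N)
  for (k in seq_len(K)) {
    f <- (k - 1L) %% N + 1L
    eta0[k, , f] <- eta0[k, , f] + context_strength
    delta[k, ] <- 0.4 / (N - 1 + (N == 1))
    delta[k, f] <- if (N > 1) 0.6 else 1
    for (i in seq_len(N)) eta0[k, i, i] <- 0
  }
  delta <- delta / rowSums(delta)
  beta <- NULL
  if (spec$covariate != "none") {
    Kb <- if (spec$covariate_sharing == "per_context") K else 1L
    beta <- array(0, c(spec$n_cov_cols, N, N, Kb))
  }
  structure(list(gamma_shape = gs, gamma_rate = gr, lambda = lam[idx],
                 mu = rep(0, N), kappa = kap[idx], eta0 = eta0, beta = beta,
                 delta = delta, pi = rep(1 / K, K)),
            class = "hmm_params")
}

#' Set a transition-covariate coefficient
#'
#' @param params `hmm_params` with a covariate slot.
#' @param from,to origin and destination states of the affected transition.
#' @param value coefficient value.
#' @param col covariate design column (1 except for the phase covariate).
#' @param context context index for context-specific coefficients; `NULL`
#'   targets the shared slab.
#' @return modified `hmm_params`.
#' @export
set_beta <- function(params, from, to, value, col = 1L, context = NULL) {
  if (is.null(params$beta)) stop_invalid("params carry no covariate coefficients")
  k <- context %||% 1L
  params$beta[col, from, to, k] <- value
  params
}

# covariate design used by the generator: values are taken exactly as given
# (no standardization; the generating beta is defined on this scale)
sim_design_X <- function(covariates, spec, n) {
  X <- matrix(0, n, max(spec$n_cov_cols, 1L))
  if (spec$covariate == "none" || is.null(covariates)) return(X)
  if (spec$covariate == "exposure_binary") {
    X[, 1] <- as.numeric(covariates$exposure)
  } else if (spec$covariate == "phase_categorical") {
    X[, 1] <- as.numeric(covariates$phase == "during")
    X[, 2] <- as.numeric(covariates$phase == "after")
  } else {
    X[, 1] <- as.numeric(covariates[[spec$covariate]])
  }
  X
}

#' Simulate per-dive observations from a context hidden Markov model
#'
#' For each whale a context is drawn from the mixing probabilities, a state
#' path is simulated from that context's covariate-dependent transition
#' matrices (the covariate on dive t acts on the transition into dive t), and
#' the five observation streams are drawn from the state's emission
#' distributions (gamma dive time, gamma max depth, Poisson lunges, gamma
#' speed, von Mises turning angle). Identical seeds give identical output.
#'
#' @param params natural-scale `hmm_params` (generating values).
#' @param spec an [hmm_spec()].
#' @param n_whales number of whales.
#' @param dives_per_whale dives per whale (scalar or vector).
#' @param covariates `NULL`, a data frame with `dives_per_whale` rows recycled
#'   to every whale, or a list of per-whale data frames. Covariate values are
#'   used exactly as given; the generating coefficients are defined on that
#'   scale.
#' @param seed RNG seed.
#' @return list with `data` (per-dive data frame including any covariate
#'   columns) and `truth` (list: `contexts` per whale, `states` per dive,
#'   `params`, `seed`).
#' @export
simulate_dives <- function(params, spec, n_whales, dives_per_whale,
                           covariates = NULL, seed = 1) {
  validate_hmm_params(params, spec)
  set.seed(seed)
  N <- spec$n_states
  Tw <- rep_len(dives_per_whale, n_whales)
  cov_list <- if (is.data.frame(covariates) || is.null(covariates)) {
    rep(list(covariates), n_whales)
  } else covariates
  out <- vector("list", n_whales)
  contexts <- integer(n_whales)
  states_all <- vector("list", n_whales)
  for (w in seq_len(n_whales)) {
    Tn <- Tw[w]
    cw <- cov_list[[w]]
    if (!is.null(cw)) cw <- cw[rep_len(seq_len(nrow(cw)), Tn), , drop = FALSE]
    X <- sim_design_X(cw, spec, Tn)
    k <- sample.int(spec$n_contexts, 1, prob = params$pi)
    st <- integer(Tn)
    st[1] <- sample.int(N, 1, prob = params$delta[k, ])
    for (t in seq_len(Tn)[-1]) {
      G <- transition_matrix(params, k, X[t, ])
      st[t] <- sample.int(N, 1, prob = G[st[t - 1], ])
    }
    d <- data.frame(
      whale = sprintf("sim%02d", w),
      dive_time = rgamma(Tn, params$gamma_shape[1, st], params$gamma_rate[1, st]),
      max_depth = rgamma(Tn, params$gamma_shape[2, st], params$gamma_rate[2, st]),
      lunges = rpois(Tn, params$lambda[st]),
      speed = rgamma(Tn, params$gamma_shape[3, st], params$gamma_rate[3, st]),
      angle = vapply(st, function(s) rvonmises(1, params$mu[s], params$kappa[s]),
                     numeric(1)))
    if (!is.null(cw)) d <- cbind(d, cw[setdiff(names(cw), names(d))])
    contexts[w] <- k
    states_all[[w]] <- st
    out[[w]] <- d
  }
  list(data = do.call(rbind, c(out, list(make.row.names = FALSE))),
       truth = list(contexts = contexts, states = unlist(states_all),
                    params = params, seed = seed))
}

#' Render a sampled depth/orientation/speed series from a dive sequence
#'
#' Produces a regularly sampled tag series whose dives reproduce each input
#' dive's duration and maximum depth to within one sample step: each dive is
#' a U-shaped excursion (linear descent, flat bottom at the maximum depth,
#' linear ascent) that stays below the 3 m surface threshold for its whole
#' duration, separated by surface intervals at 0 m. Pitch is derived from the
#' vertical rate and horizontal speed, heading rotates through the dive's
#' turning angle, the speed channel carries the dive's speed over ground, and
#' roll is zero. Lunge events are placed evenly through the bottom phase and
#' one breath per surface interval; both are attached as the `events`
#' attribute.
#'
#' @param dive_sequence data frame with `dive_time`, `max_depth` and
#'   optionally `lunges`, `speed`, `angle`, `post_surface_s`.
#' @param sampling_hz sampling rate (Hz).
#' @param surface_s default surface interval between dives (seconds).
#' @param bottom_frac fraction of the dive spent in the flat bottom phase.
#' @return an object of class `tag_series`: data frame with columns `time_s`,
#'   `depth_m`, `pitch_rad`, `roll_rad`, `heading_rad`, `speed_ms`;
#'   attributes `sampling_hz` and `events`.
#' @export
render_depth_series <- function(dive_sequence, sampling_hz = 1,
                                surface_s = 60, bottom_frac = 0.4) {
  if (sampling_hz <= 0) stop_invalid("sampling_hz must be positive")
  dt <- 1 / sampling_hz
  nd <- nrow(dive_sequence) %||% 0
  if (nd == 0 || is.null(dive_sequence)) {
    n <- round(2 * surface_s * sampling_hz)
    ts <- data.frame(time_s = (seq_len(n) - 1) * dt, depth_m = 0,
                     pitch_rad = 0, roll_rad = 0, heading_rad = 0,
                     speed_ms = 1)
    return(structure(ts, sampling_hz = sampling_hz,
                     events = list(lunge_times = numeric(0),
                                   breath_times = numeric(0)),
                     class = c("tag_series", "data.frame")))
  }
  depth <- pitch <- heading <- speed <- numeric(0)
  lunge_times <- breath_times <- numeric(0)
  h0 <- 0
  push_surface <- function(sec) {
    n <- max(round(sec * sampling_hz), 1L)
    depth <<- c(depth, rep(0, n)); pitch <<- c(pitch, rep(0, n))
    heading <<- c(heading, rep(h0, n)); speed <<- c(speed, rep(1, n))
    breath_times <<- c(breath_times, (length(depth) - n / 2) * dt)
  }
  push_surface(surface_s)
  for (i in seq_len(nd)) {
    Td <- dive_sequence$dive_time[i]
    md <- dive_sequence$max_depth[i]
    n <- round(Td * sampling_hz)
    if (n < 2) stop_invalid("dive %d shorter than 2 samples at %g Hz", i, sampling_hz)
    if (md <= 3) stop_invalid("dive %d max depth must exceed the 3 m surface threshold", i)
    nb <- max(round(bottom_frac * n), 1L)
    ndesc <- max((n - nb) %/% 2L, 1L)
    nasc <- n - nb - ndesc
    start_depth <- min(4, 0.9 * md)
    prof <- c(seq(start_depth, md, length.out = ndesc + 1)[-1],
              rep(md, nb),
              if (nasc > 0) seq(md, start_depth, length.out = nasc + 1)[-1])
    prof <- c(start_depth, prof)[seq_len(n)]
    sp <- if (!is.null(dive_sequence$speed)) dive_sequence$speed[i] else 1.5
    ang <- if (!is.null(dive_sequence$angle)) dive_sequence$angle[i] else 0
    dz <- c(diff(prof), 0) / dt
    pitch_i <- atan2(-dz, sp)
    head_i <- h0 + seq(0, ang, length.out = n)
    t_off <- length(depth) * dt
    nl <- if (!is.null(dive_sequence$lunges)) dive_sequence$lunges[i] else 0
    if (nl > 0) {
      bt <- t_off + (ndesc + seq_len(nl) * nb / (nl + 1)) * dt
      lunge_times <- c(lunge_times, bt)
    }
    depth <- c(depth, prof); pitch <- c(pitch, pitch_i)
    heading <- c(heading, head_i); speed <- c(speed, rep(sp, n))
    h0 <- h0 + ang
    gap <- if (!is.null(dive_sequence$post_surface_s)) {
      dive_sequence$post_surface_s[i]
    } else surface_s
    push_surface(gap)
  }
  ts <- data.frame(time_s = (seq_along(depth) - 1) * dt, depth_m = depth,
                   pitch_rad = pitch, roll_rad = 0,
                   heading_rad = wrap_angle(heading), speed_ms = speed)
  structure(ts, sampling_hz = sampling_hz,
            events = list(lunge_times = lunge_times, breath_times = breath_times),
            class = c("tag_series", "data.frame"))
}
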
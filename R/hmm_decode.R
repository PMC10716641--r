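#' Local decoding under discrete random effects
#'
#' Posterior context membership per whale,
#' \eqn{P(c_w = k \mid y_w) \propto \pi_k \exp(\ell_{wk})}, and per-dive
#' state posteriors mixture-weighted over contexts,
#' \eqn{P(s_t = n \mid y_w) = \sum_k P(c_w = k \mid y_w)
#' P(s_t = n \mid y_w, c_w = k)}, the inner term from the forward-backward
#' recursion. The most probable state per dive is the posterior argmax, ties
#' resolved toward the lower state index.
#'
#' @param fit an `hmm_fit` from [fit_hmm()].
#' @param data optional per-dive data frame; defaults to the data the model
#'   was fitted to.
#' @return an object of class `hmm_decoding`: list with `context_post`
#'   (whales x K matrix), `state_post` (dives x N matrix), `states`
#'   (most-probable state per dive), `whales`.
#' @export
local_decode <- function(fit, data = NULL) {
  spec <- fit$spec
  design <- if (is.null(data)) fit$design else hmm_design(data, spec, scaling = fit$scaling)
  res <- core_call(fit$working, spec, design, want_post = TRUE)
  ctx <- res$context_post
  rownames(ctx) <- design$whales
  colnames(ctx) <- paste0("context", seq_len(spec$n_contexts))
  sp <- res$state_post
  colnames(sp) <- paste0("state", seq_len(spec$n_states))
  structure(list(context_post = ctx, state_post = sp,
                 states = max.col(sp, ties.method = "first"),
                 whales = design$whales, wid = design$wid),
            class = "hmm_decoding")
}

#' @export
print.hmm_decoding <- function(x, ...) {
  cat(sprintf("Local decoding: %d whales, %d dives\n",
              nrow(x$context_post), length(x$states)))
  cat("State occupancy:\n")
  print(table(factor(x$states, levels = seq_len(ncol(x$state_post)))))
  invisible(x)
}

#' Count decoded state switches by CEE phase
#'
#' Tabulates decoded transitions from one state to another within whales,
#' split by the phase of the destination dive. Used to examine whether
#' switches into the deep-feeding state become more frequent during exposure.
#'
#' @param decoding an `hmm_decoding`.
#' @param data the per-dive data frame with a `phase` column aligned with
#'   the decoded dives.
#' @param from,to state indices of the switch of interest.
#' @return data frame with per-phase counts of the `from -> to` switch, the
#'   number of opportunities (dives whose previous dive was in `from`), and
#'   the switch rate.
#' @export
switch_rates <- function(decoding, data, from = 2L, to = 1L) {
  st <- decoding$states
  wid <- decoding$wid
  prev_same <- c(FALSE, diff(wid) == 0)
  opp <- prev_same & c(NA, head(st, -1)) == from
  sw <- opp & st == to
  phase <- factor(data$phase, levels = c("before", "during", "after"))
  out <- data.frame(phase = levels(phase))
  out$opportunities <- as.integer(tapply(opp, phase, sum, default = 0))
  out$switches <- as.integer(tapply(sw, phase, sum, default = 0))
  out$rate <- ifelse(out$opportunities > 0, out$switches / out$opportunities, NA)
  out
}
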
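#' Simulate a population of tagged whales through a CEE protocol
#'
#' For each whale a CEE is laid out on a common clock (exposure start = 0):
#' a ping schedule (MFAS or PRN ramp, or a silent control), a slowly drifting
#' source-whale range around 1 km, per-ping received levels by spherical
#' spreading, and a per-dive timeline spanning the pre-exposure, exposure and
#' post-exposure phases. Per-dive exposure covariates (max/avg/min RL, cSEL,
#' phase) are attached with [attach_exposure()], and dive behaviour is then
#' generated from the context-HMM via [simulate_dives()], with the
#' received-level covariate entering the transition model standardized over
#' exposed dives (so the generating coefficient `beta21` is on the same
#' working scale that fitting reports).
#'
#' @param n_whales number of whales.
#' @param dives_per_whale dives per whale; the middle `exposure_frac` of the
#'   timeline falls in the exposure phase.
#' @param spec an [hmm_spec()]; its covariate governs which per-dive
#'   covariate drives transitions.
#' @param params generating `hmm_params`; default [default_hmm_params()].
#' @param beta21 coefficient of the covariate on the non-feeding (2) to
#'   deep-feeding (1) transition (standardized scale), applied when the spec
#'   has a covariate.
#' @param cee_types treatment labels recycled across whales.
#' @param mean_range_m nominal source-whale range.
#' @param seed master seed; per-whale sub-seeds are derived.
#' @return list with `data` (per-dive records: behaviour, covariates, phase,
#'   `cee_type`, `behavioural_state`) and `truth` (contexts, states, params,
#'   schedules).
#' @export
simulate_cee_population <- function(n_whales = 15, dives_per_whale = 120,
                                    spec = hmm_spec(3, 2, covariate = "max_rl"),
                                    params = NULL, beta21 = 1.0,
                                    cee_types = c("MFAS", "PRN", "CONTROL"),
                                    mean_range_m = 1000, seed = 1) {
  if (is.null(params)) params <- default_hmm_params(spec)
  if (spec$covariate != "none" && !is.null(params$beta)) {
    params <- set_beta(params, 2L, 1L, beta21)
  }
  types <- rep_len(cee_types, n_whales)
  states_lab <- rep_len(c("deep-feeding", "shallow-feeding", "non-feeding"),
                        n_whales)
  phase_s <- 1800
  all_data <- vector("list", n_whales)
  contexts <- integer(n_whales); states_true <- vector("list", n_whales)
  schedules <- vector("list", n_whales)
  for (w in seq_len(n_whales)) {
    sw <- derive_seed(seed, paste0("whale", w))
    set.seed(sw)
    sched <- make_cee_schedule(types[w])
    # dive timeline: equal shares of the record before / during / after,
    # evenly spaced so the exposure phase is covered by the middle block
    n_dur <- max(round(dives_per_whale / 3), 1L)
    n_pre <- ceiling((dives_per_whale - n_dur) / 2)
    n_post <- dives_per_whale - n_dur - n_pre
    gap <- phase_s / n_dur
    starts <- c(seq(-n_pre, -1) * gap, (seq_len(n_dur) - 1) * gap,
                phase_s + (seq_len(n_post) - 1) * gap)
    dv <- data.frame(start_s = starts, end_s = starts + gap - 1)
    expo <- NULL
    if (length(sched$ping_times)) {
      rng <- mean_range_m * exp(cumsum(rnorm(length(sched$ping_times), 0, 0.01)))
      expo <- received_levels(sched, range_m = pmax(rng, 200))
    }
    dv <- attach_exposure(dv, expo, sched)
    covs <- dv
    for (v in c("max_rl", "avg_rl")) {
      x <- covs[[v]]; ex <- x > 0
      if (sum(ex) >= 2 && stats::sd(x[ex]) > 0) {
        covs[[v]] <- ifelse(ex, (x - mean(x[ex])) / stats::sd(x[ex]), 0)
      }
    }
    sim <- simulate_dives(params, spec, n_whales = 1,
                          dives_per_whale = dives_per_whale,
                          covariates = covs, seed = derive_seed(sw, "dives"))
    d <- sim$data
    d$whale <- sprintf("whale%02d", w)
    # report covariates on their raw dB scale
    for (v in c("max_rl", "avg_rl")) d[[v]] <- dv[[v]]
    d$cee_type <- types[w]
    d$behavioural_state <- states_lab[w]
    all_data[[w]] <- d
    contexts[w] <- sim$truth$contexts
    states_true[[w]] <- sim$truth$states
    schedules[[w]] <- sched
  }
  list(data = do.call(rbind, c(all_data, list(make.row.names = FALSE))),
       truth = list(contexts = contexts, states = unlist(states_true),
                    params = params, schedules = schedules, seed = seed))
}

#' Assemble a pipeline configuration
#'
#' @param seed master seed; every stochastic stage receives a sub-seed
#'   derived from it.
#' @param n_whales,dives_per_whale synthetic population size.
#' @param beta21 generating covariate effect on the 2 to 1 transition.
#' @param k_grid context counts to compare by AIC.
#' @param covariate transition covariate for the candidate models.
#' @param n_starts random starts per HMM fit.
#' @param pca_threshold variance-fraction retention threshold.
#' @param out_dir optional directory for CSV/JSON artifacts (`NULL` = none).
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1, n_whales = 12, dives_per_whale = 100,
                       beta21 = 1.0, k_grid = c(1, 2), covariate = "max_rl",
                       n_starts = 10, pca_threshold = 0.10, out_dir = NULL) {
  cfg <- list(seed = seed, n_whales = n_whales,
              dives_per_whale = dives_per_whale, beta21 = beta21,
              k_grid = k_grid, covariate = covariate, n_starts = n_starts,
              pca_threshold = pca_threshold, out_dir = out_dir,
              ping_interval_s = 25, sl_initial_db = 160, ramp_step_db = 3)
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline on synthetic data plus packaged fixtures
#'
#' Stages: fixture validation, CEE population simulation, dive-metric
#' summaries, HMM model selection over the context grid, PCA + response
#' models, and the dose-as-time severity survival analysis on the packaged
#' severity-score table. A stage failure marks the stage failed and skips
#' downstream stages. The returned report carries a hash of the
#' configuration and of its own key numbers; identical configurations
#' reproduce identical report hashes.
#'
#' @param config a [run_config()].
#' @return object of class `run_report`.
#' @export
run_pipeline <- function(config = run_config()) {
  stages <- list()
  outputs <- list()
  failed <- FALSE
  run_stage <- function(name, f) {
    if (failed) {
      stages[[name]] <<- "skipped"
      return(NULL)
    }
    res <- tryCatch(f(), error = function(e) e)
    if (inherits(res, "error")) {
      stages[[name]] <<- paste("failed:", conditionMessage(res))
      failed <<- TRUE
      NULL
    } else {
      stages[[name]] <<- "ok"
      res
    }
  }

  fx <- run_stage("validate", function() load_cee_fixtures())

  pop <- run_stage("simulate", function() {
    simulate_cee_population(
      n_whales = config$n_whales, dives_per_whale = config$dives_per_whale,
      spec = hmm_spec(3, 2, covariate = config$covariate),
      beta21 = config$beta21, seed = derive_seed(config$seed, "simulate"))
  })

  met <- run_stage("metrics", function() {
    d1 <- pop$data[pop$data$whale == pop$data$whale[1], ][1:20, ]
    ts <- render_depth_series(d1)
    list(metric_table = dive_metric_table(ts),
         n_dives_rendered = nrow(segment_dives(ts)))
  })

  hmm <- run_stage("hmm", function() {
    specs <- lapply(config$k_grid, function(k)
      hmm_spec(3, k, covariate = config$covariate))
    select_model(pop$data, specs, n_starts = config$n_starts,
                 seed = derive_seed(config$seed, "hmm"))
  })

  pca <- run_stage("pca_gamm", function() {
    p <- run_pca(pop$data, category = "dive",
                 columns = c("dive_time", "max_depth", "lunges", "speed"))
    keep <- select_components(p, config$pca_threshold)
    dsg <- pop$data
    dsg$min_rl <- dsg$min_rl %||% 0
    m1 <- fit_response_model(p$scores[, 1], dsg, "phase_model")
    list(pca = p, retained = keep, model = m1)
  })

  surv <- run_stage("severity", function() {
    et <- build_event_table(fx$severity_table)
    null_fit <- fit_hazards(et, covariates = character(0))
    sig_fit <- fit_hazards(et, covariates = "signal_type")
    curves <- response_function(sig_fit,
                                newdata = data.frame(signal_type = c("MFAS", "PRN")))
    list(event_table = et, null_fit = null_fit, signal_fit = sig_fit,
         ph = ph_test(sig_fit), curves = curves,
         delta_aic = abs(null_fit$aic - sig_fit$aic))
  })

  outputs <- list(
    fixture_counts = if (!is.null(fx)) validate_tables(fx$cee_table, fx$severity_table)$counts,
    selected_model = if (!is.null(hmm)) hmm$table[1, c("n_states", "n_contexts", "covariate", "aic")],
    retained_axes = if (!is.null(pca)) pca$retained,
    rl_smooth_p = if (!is.null(pca)) {
      tr <- pca$model$terms
      tr$p_value[tr$term == "s(max_rl)"]
    },
    n_events = if (!is.null(surv)) sum(surv$event_table$event),
    delta_aic_signal = if (!is.null(surv)) surv$delta_aic,
    ph_global_p = if (!is.null(surv)) surv$ph$p[surv$ph$term == "GLOBAL"])

  key_numbers <- list(
    stages = stages,
    selected_k = if (!is.null(hmm)) hmm$table$n_contexts[1],
    best_aic = if (!is.null(hmm)) round(hmm$table$aic[1], 6),
    retained_axes = outputs$retained_axes,
    delta_aic_signal = if (!is.null(surv)) round(surv$delta_aic, 6),
    n_events = outputs$n_events)

  report <- structure(list(
    stages = stages, outputs = outputs,
    details = list(hmm = hmm, pca = pca, severity = surv, metrics = met,
                   population_truth = if (!is.null(pop)) pop$truth),
    config = config,
    config_hash = config_hash(unclass(config)),
    report_hash = config_hash(key_numbers),
    version = as.character(utils::packageVersion("sonarCEE"))),
    class = "run_report")

  if (!is.null(config$out_dir)) write_report_artifacts(report, config$out_dir)
  report
}

write_report_artifacts <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$details$severity)) {
    utils::write.csv(report$details$severity$event_table,
                     file.path(dir, "event_table.csv"), row.names = FALSE)
    utils::write.csv(report$details$severity$curves,
                     file.path(dir, "response_curves.csv"), row.names = FALSE)
  }
  if (!is.null(report$details$hmm)) {
    utils::write.csv(report$details$hmm$table,
                     file.path(dir, "hmm_selection.csv"), row.names = FALSE)
  }
  jsonlite::write_json(list(stages = report$stages,
                            config_hash = report$config_hash,
                            report_hash = report$report_hash),
                       file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("CEE analysis pipeline report\n")
  for (s in names(x$stages)) cat(sprintf("  %-10s %s\n", s, x$stages[[s]]))
  if (!is.null(x$outputs$selected_model)) {
    cat(sprintf("  selected HMM: K=%d contexts (AIC %.2f)\n",
                x$outputs$selected_model$n_contexts,
                x$outputs$selected_model$aic))
  }
  if (!is.null(x$outputs$delta_aic_signal)) {
    cat(sprintf("  severity |AIC(null)-AIC(signal)| = %.3f, PH global p = %.3f\n",
                x$outputs$delta_aic_signal, x$outputs$ph_global_p))
  }
  cat(sprintf("  config hash %s / report hash %s\n",
              x$config_hash, x$report_hash))
  invisible(x)
}
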
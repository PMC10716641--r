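#' Windowed Mahalanobis distance from a baseline behavioural profile
#'
#' Aggregates a multivariate metric series into non-overlapping windows and
#' measures each window's Mahalanobis distance
#' \eqn{\sqrt{(x-\bar\mu)^\top S^{-1} (x-\bar\mu)}} from the mean and
#' covariance of the baseline windows. When the baseline covariance is
#' near-singular (or there are fewer baseline windows than metrics) a ridge
#' proportional to the mean diagonal is added and flagged.
#'
#' @param metric_series data frame with `time_s` plus numeric metric columns.
#' @param baseline_interval length-2 numeric: start/end time of the baseline.
#' @param window_s window length in seconds.
#' @param regularization ridge fraction added to the covariance diagonal when
#'   needed (`"auto"` = 1e-6, applied only if near-singular; or a number
#'   always applied).
#' @return object of class `mahalanobis_series`: data frame with `time_s`
#'   (window centres) and `distance`; attributes `baseline_interval`,
#'   `metrics`, `regularized`.
#' @export
mahalanobis_series <- function(metric_series, baseline_interval, window_s,
                               regularization = "auto") {
  mcols <- setdiff(names(metric_series)[vapply(metric_series, is.numeric,
                                               logical(1))], "time_s")
  tt <- metric_series$time_s
  win <- floor((tt - min(tt)) / window_s)
  centres <- min(tt) + (sort(unique(win)) + 0.5) * window_s
  agg <- aggregate(metric_series[, mcols, drop = FALSE], by = list(win = win),
                   FUN = mean)
  xm <- as.matrix(agg[, mcols, drop = FALSE])
  base <- centres >= baseline_interval[1] & centres <= baseline_interval[2]
  if (sum(base) < 2) stop_invalid("baseline interval must contain at least 2 windows")
  mu <- colMeans(xm[base, , drop = FALSE])
  S <- stats::cov(xm[base, , drop = FALSE])
  regularized <- FALSE
  forced <- sum(base) <= length(mcols)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  near_sing <- forced || min(ev) < 1e-10 * max(max(ev), 1)
  ridge <- if (is.numeric(regularization)) regularization else 1e-6
  if (is.numeric(regularization) || near_sing) {
    if (forced) warning("fewer baseline windows than metrics; ridge regularization forced")
    S <- S + diag(ridge * mean(diag(S)) + 1e-12, ncol(S))
    regularized <- TRUE
  }
  d2 <- stats::mahalanobis(xm, mu, S)
  out <- data.frame(time_s = centres, distance = sqrt(pmax(d2, 0)))
  structure(out, baseline_interval = baseline_interval, metrics = mcols,
            regularized = regularized,
            class = c("mahalanobis_series", "data.frame"))
}

#' Build the dose-as-time severity event table
#'
#' Converts the expert severity-score table into the recurrent-event format
#' of the dose-as-time survival analysis. Only exposure (MFAS/PRN) CEEs are
#' used: the signal-type covariate is undefined for controls. Each exposure
#' CEE contributes exactly one row per severity stratum (low = scores 1-3,
#' moderate = 4-6; the high band 7-9 is empty in these data and omitted).
#' A stratum receives an event at the CEE's change-point cumulative SEL when
#' that severity band was reached, and a right-censored row at the CEE's
#' maximum recorded cSEL otherwise. A moderate response also marks the low
#' stratum as reached at the same dose (`low_event_on_moderate`). A CEE with
#' a change but no printed score whose description indicates a moderate
#' change is coded as a moderate-band event (`code_unscored_moderate`).
#'
#' @param severity_table data frame as in [load_cee_fixtures()].
#' @param dose_field column holding the dose (dB cSEL).
#' @param low_event_on_moderate logical, see above.
#' @param code_unscored_moderate logical, see above.
#' @return data frame with columns `whale`, `stratum`, `dose`, `event`,
#'   `signal_type`, `behavioural_state`.
#' @export
build_event_table <- function(severity_table, dose_field = "csel_db",
                              low_event_on_moderate = TRUE,
                              code_unscored_moderate = TRUE) {
  ex <- severity_table[severity_table$cee_type != "CONTROL", , drop = FALSE]
  rows <- vector("list", 0)
  for (i in seq_len(nrow(ex))) {
    r <- ex[i, ]
    dose <- r[[dose_field]]
    score <- r$severity_score
    if (is.na(score) && identical(r$change, "yes")) {
      if (code_unscored_moderate &&
          grepl("moderate", r$change_description %||% "", ignore.case = TRUE)) {
        score <- 5
      } else {
        warning(sprintf("responder %s has no usable severity score; excluded",
                        r$subject_id))
        next
      }
    }
    if (is.na(score)) score <- 0
    if (is.na(dose)) {
      warning(sprintf("responder %s has no usable dose; excluded", r$subject_id))
      next
    }
    low_hit <- score >= 1 && (score <= 3 || low_event_on_moderate)
    mod_hit <- score >= 4 && score <= 6
    for (stratum in c("low", "moderate")) {
      ev <- if (stratum == "low") low_hit else mod_hit
      rows[[length(rows) + 1]] <- data.frame(
        whale = r$subject_id, stratum = stratum, dose = dose,
        event = as.integer(ev), signal_type = r$cee_type,
        behavioural_state = r$behavioural_state)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the dose-as-time stratified proportional-hazards model
#'
#' Marginal (WLW-style) stratified Cox model with the cumulative sound
#' exposure level playing the role of time. The partial likelihood is
#' maximized with Breslow tie handling (Efron available); strata share
#' coefficients unless an interaction with the stratum is requested.
#' Standard errors are reported both from the model information matrix and
#' from a grouped (leave-one-whale-out) jackknife that honours the
#' within-whale correlation of the two stratum rows.
#'
#' @param event_table a [build_event_table()] data frame.
#' @param covariates character vector of covariate columns (empty for the
#'   null model).
#' @param strata stratification column (default `"stratum"`).
#' @param interaction logical: interact covariates with the stratum.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return object of class `hazards_fit`: list with the `survival::coxph`
#'   fit, `coefficients` (estimate, model SE, jackknife SE), partial
#'   log-likelihood, `aic`, and the data used.
#' @export
fit_hazards <- function(event_table, covariates = "signal_type",
                        strata = "stratum", interaction = FALSE,
                        ties = "breslow") {
  et <- event_table
  et$.strat <- factor(et[[strata]])
  rhs <- if (length(covariates) == 0) {
    "strata(.strat)"
  } else if (interaction) {
    paste(paste0(covariates, ":.strat", collapse = " + "),
          paste(covariates, collapse = " + "), "strata(.strat)", sep = " + ")
  } else {
    paste(paste(covariates, collapse = " + "), "strata(.strat)", sep = " + ")
  }
  fml <- stats::as.formula(paste("survival::Surv(dose, event) ~", rhs))
  fit <- survival::coxph(fml, data = et, ties = ties, x = TRUE,
                         y = TRUE, model = TRUE)
  npar <- length(stats::coef(fit))
  pll <- if (npar == 0) fit$loglik[1] else fit$loglik[2]
  coefs <- NULL
  if (npar > 0) {
    if (any(!is.finite(sqrt(diag(fit$var))))) {
      warning("possible monotone partial likelihood (perfect separation)")
    }
    jk <- grouped_jackknife(et, fml, ties, names(stats::coef(fit)))
    coefs <- data.frame(term = names(stats::coef(fit)),
                        estimate = unname(stats::coef(fit)),
                        se_model = sqrt(diag(fit$var)),
                        se_jackknife = jk)
  }
  structure(list(coxph = fit, coefficients = coefs, loglik = pll,
                 n_coefficients = npar, aic = -2 * pll + 2 * npar,
                 data = et, ties = ties, strata = levels(et$.strat)),
            class = "hazards_fit")
}

grouped_jackknife <- function(et, fml, ties, coef_names) {
  whales <- unique(et$whale)
  g <- length(whales)
  est <- matrix(NA_real_, g, length(coef_names))
  for (i in seq_len(g)) {
    sub <- et[et$whale != whales[i], , drop = FALSE]
    # leave-one-out replicates on small tables can be degenerate (monotone
    # likelihood); their warnings are expected and the replicate still counts
    f <- tryCatch(suppressWarnings(survival::coxph(fml, data = sub, ties = ties)),
                  error = function(e) NULL)
    if (!is.null(f)) {
      cf <- stats::coef(f)
      est[i, ] <- cf[coef_names]
    }
  }
  ok <- stats::complete.cases(est)
  m <- colMeans(est[ok, , drop = FALSE])
  n_ok <- sum(ok)
  sqrt((n_ok - 1) / n_ok * colSums((est[ok, , drop = FALSE] -
                                      rep(m, each = n_ok))^2))
}

#' @export
print.hazards_fit <- function(x, ...) {
  cat(sprintf("Dose-as-time stratified Cox model (%s ties): loglik = %.4f, AIC = %.4f\n",
              x$ties, x$loglik, x$aic))
  if (!is.null(x$coefficients)) print(x$coefficients, row.names = FALSE)
  else cat("  (null model, no covariates)\n")
  invisible(x)
}

#' @export
AIC.hazards_fit <- function(object, ..., k = 2) {
  -2 * object$loglik + k * object$n_coefficients
}

#' Proportional-hazards assumption test
#'
#' Scaled Schoenfeld-residual association with the rank of the dose,
#' per-term and global chi-square statistics with p-values.
#'
#' @param fit a [fit_hazards()] result (with at least one covariate).
#' @param transform dose transform for the test (default `"rank"`).
#' @return data frame of per-term and GLOBAL chi-square statistics, df and
#'   p-values.
#' @export
ph_test <- function(fit, transform = "rank") {
  if (fit$n_coefficients == 0) stop_invalid("PH test needs a covariate")
  if (sum(fit$data$event) == 0) stop_invalid("PH test undefined without events")
  z <- survival::cox.zph(fit$coxph, transform = transform)
  tab <- as.data.frame(z$table)
  tab$term <- rownames(z$table)
  tab[, c("term", "chisq", "df", "p")]
}

#' Exposure-response functions from a fitted hazards model
#'
#' Breslow baseline cumulative hazard per severity stratum, converted to the
#' probability of response by dose \eqn{p(d) = 1 - S(d)} for each requested
#' covariate profile. Pointwise confidence intervals use the grouped
#' (leave-one-whale-out) jackknife variance of the log cumulative hazard.
#' Curves are evaluated on a dose grid clamped to the observed dose range
#' (constant beyond the last observed dose).
#'
#' @param fit a [fit_hazards()] result.
#' @param newdata data frame of covariate profiles (one row per curve, e.g.
#'   `data.frame(signal_type = c("MFAS", "PRN"))`); ignored for the null
#'   model.
#' @param doses dose grid (dB cSEL); default the observed range.
#' @param level confidence level.
#' @return data frame with `stratum`, profile columns, `dose`, `response`
#'   (probability), `lower`, `upper`.
#' @export
response_function <- function(fit, newdata = NULL, doses = NULL, level = 0.95) {
  et <- fit$data
  if (is.null(doses)) {
    doses <- seq(min(et$dose), max(et$dose), length.out = 101)
  }
  doses <- pmin(doses, max(et$dose))  # constant beyond the last observed dose
  profiles <- if (fit$n_coefficients == 0 || is.null(newdata)) {
    data.frame(.profile = "baseline")
  } else newdata
  z <- stats::qnorm(1 - (1 - level) / 2)
  whales <- unique(et$whale)
  curves <- list()
  for (p in seq_len(nrow(profiles))) {
    nd <- profiles[p, , drop = FALSE]
    H <- cumhaz_at(fit$coxph, et, nd, doses, fit$n_coefficients)
    # jackknife replicates of log cumulative hazard
    reps <- array(NA_real_, c(length(whales), length(doses), length(fit$strata)))
    for (i in seq_along(whales)) {
      sub <- et[et$whale != whales[i], , drop = FALSE]
      f <- tryCatch(survival::coxph(stats::formula(fit$coxph), data = sub,
                                    ties = fit$ties, x = TRUE, y = TRUE,
                                    model = TRUE),
                    error = function(e) NULL)
      if (is.null(f)) next
      reps[i, , ] <- cumhaz_at(f, sub, nd, doses, fit$n_coefficients)
    }
    g <- dim(reps)[1]
    for (s in seq_along(fit$strata)) {
      h <- H[, s]
      lh <- log(pmax(h, 1e-300))
      rs <- reps[, , s, drop = FALSE][, , 1]
      lrs <- log(pmax(rs, 1e-300))
      ok <- stats::complete.cases(lrs)
      vj <- if (sum(ok) > 1) {
        (sum(ok) - 1) / sum(ok) * colSums((lrs[ok, , drop = FALSE] -
          rep(colMeans(lrs[ok, , drop = FALSE]), each = sum(ok)))^2)
      } else rep(0, length(doses))
      se <- sqrt(vj)
      lo <- ifelse(h > 0, 1 - exp(-h * exp(-z * se)), 0)
      hi <- ifelse(h > 0, 1 - exp(-h * exp(z * se)), 0)
      cur <- data.frame(stratum = fit$strata[s], dose = doses,
                        response = 1 - exp(-h),
                        lower = pmin(lo, hi), upper = pmax(lo, hi))
      cur <- cbind(cur, nd[rep(1, nrow(cur)), , drop = FALSE])
      rownames(cur) <- NULL
      curves[[length(curves) + 1]] <- cur
    }
  }
  do.call(rbind, curves)
}

# stratum-wise cumulative hazard at the requested doses for one profile
cumhaz_at <- function(cox, et, nd, doses, n_coef) {
  # survfit re-evaluates the model frame from the stored call; pin the data
  # object itself into the call so jackknife refits resolve correctly
  cox$call$data <- et
  sf <- if (n_coef == 0) {
    survival::survfit(cox)
  } else {
    survival::survfit(cox, newdata = nd)
  }
  strat <- if (is.null(sf$strata)) {
    rep(1L, length(sf$time))
  } else {
    rep(seq_along(sf$strata), sf$strata)
  }
  n_strata <- max(strat)
  out <- matrix(0, length(doses), n_strata)
  ch <- if (is.matrix(sf$cumhaz)) sf$cumhaz[, 1] else sf$cumhaz
  for (s in seq_len(n_strata)) {
    sel <- strat == s
    out[, s] <- stats::approx(c(-Inf, sf$time[sel]), c(0, ch[sel]),
                              xout = doses, method = "constant",
                              f = 0, rule = 2)$y
  }
  out
}
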
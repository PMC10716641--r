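test_that("Mahalanobis distances match hand evaluation and its invariances", {
  # baseline windows with sample covariance exactly diag(4, 9) and mean 0
  base_x <- c(2, 2, -2, -2, 0)
  base_y <- c(3, -3, 3, -3, 0)
  ms <- data.frame(time_s = seq(0.5, 6.5, by = 1),
                   mx = c(base_x, 0, 2), my = c(base_y, 0, 3))
  out <- mahalanobis_series(ms, baseline_interval = c(0, 5), window_s = 1)
  # window equal to the baseline mean: distance 0
  expect_equal(out$distance[6], 0, tolerance = 1e-12)
  # deviation (2, 3) against S = diag(4, 9): sqrt(4/4 + 9/9) = sqrt(2)
  expect_equal(out$distance[7], sqrt(2), tolerance = 1e-12)
  # affine rescaling of a metric leaves distances unchanged
  ms2 <- ms; ms2$mx <- 10 * ms$mx - 7
  out2 <- mahalanobis_series(ms2, c(0, 5), 1)
  expect_equal(out2$distance, out$distance, tolerance = 1e-10)
  expect_true(all(out$distance >= 0))
  # fewer baseline windows than metrics forces regularization
  ms3 <- data.frame(time_s = seq(0.5, 4.5), a = rnorm(5), b = rnorm(5),
                    c = rnorm(5), d = rnorm(5), e = rnorm(5))
  expect_warning(o3 <- mahalanobis_series(ms3, c(0, 2), 1), "forced")
  expect_true(attr(o3, "regularized"))
  expect_error(mahalanobis_series(ms, c(0, 0.6), 1), "at least 2")
})

test_that("the severity event table has the dose-as-time structure", {
  fx <- load_cee_fixtures()
  et <- build_event_table(fx$severity_table)
  # 15 exposure CEEs x 2 strata, controls excluded
  expect_equal(nrow(et), 30)
  expect_equal(length(unique(et$whale)), 15)
  expect_true(all(table(et$whale) == 2))
  expect_equal(sum(et$event[et$stratum == "low"]), 5)
  expect_equal(sum(et$event[et$stratum == "moderate"]), 4)
  # a score of 6 at cSEL 111 gives a moderate event and (by the same-dose
  # convention) a low event at 111
  r247 <- et[et$whale == "bp10_247a", ]
  expect_equal(r247$dose, c(111, 111))
  expect_equal(r247$event, c(1L, 1L))
  # idempotent and count-conserving
  expect_identical(et, build_event_table(fx$severity_table))
  # all-censored input: zero events, doses at the recorded maximum
  cens <- fx$severity_table
  cens$change <- "no"; cens$severity_score <- NA
  et0 <- build_event_table(cens)
  expect_equal(sum(et0$event), 0)
  expect_equal(nrow(et0), 30)
  # switchable conventions
  et_nolow <- build_event_table(fx$severity_table, low_event_on_moderate = FALSE)
  expect_equal(sum(et_nolow$event[et_nolow$stratum == "low"]), 1)
  expect_warning(
    et_nomod <- build_event_table(fx$severity_table,
                                  code_unscored_moderate = FALSE),
    "excluded")
  expect_equal(nrow(et_nomod), 28)
})

test_that("the partial likelihood matches the hand-written risk-set expression", {
  # two events, no ties, one binary covariate, single stratum
  et <- data.frame(whale = paste0("w", 1:4), stratum = "low",
                   dose = c(100, 120, 140, 150), event = c(1L, 1L, 0L, 0L),
                   signal_type = c("PRN", "MFAS", "PRN", "MFAS"))
  fit <- fit_hazards(et, covariates = "signal_type")
  b <- fit$coefficients$estimate
  x <- c(0, 1, 0, 1)  # PRN is the second factor level
  x <- as.integer(et$signal_type == "PRN")
  hand_pl <- function(beta) {
    (x[1] * beta - log(sum(exp(x * beta)))) +
      (x[2] * beta - log(sum(exp(x[2:4] * beta))))
  }
  expect_equal(fit$loglik, hand_pl(b), tolerance = 1e-8)
  # the reported maximum beats nearby values
  expect_gt(hand_pl(b), hand_pl(b + 0.1))
  expect_gt(hand_pl(b), hand_pl(b - 0.1))
  # null model: AIC = -2 * pl(0) with zero coefficients
  null_fit <- fit_hazards(et, covariates = character(0))
  expect_equal(null_fit$aic, -2 * hand_pl(0), tolerance = 1e-10)
  expect_equal(null_fit$n_coefficients, 0L)
})

test_that("duplicating the dataset preserves coefficient estimates", {
  fx <- load_cee_fixtures()
  et <- build_event_table(fx$severity_table)
  f1 <- fit_hazards(et, covariates = "signal_type")
  et2 <- rbind(et, et)
  f2 <- fit_hazards(et2, covariates = "signal_type")
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-6)
  # jackknife SEs are non-negative and reported alongside model SEs
  expect_true(all(f1$coefficients$se_jackknife >= 0))
  expect_true(all(f1$coefficients$se_model > 0))
})

test_that("the proportional-hazards test behaves like a score identity", {
  fx <- load_cee_fixtures()
  et <- build_event_table(fx$severity_table)
  fit <- fit_hazards(et, covariates = "signal_type")
  tab <- ph_test(fit)
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_true("GLOBAL" %in% tab$term)
  # Schoenfeld residuals sum to ~0 at the MLE
  sch <- residuals(fit$coxph, type = "schoenfeld")
  expect_lt(abs(sum(sch)), 1e-8)
  null_fit <- fit_hazards(et, covariates = character(0))
  expect_error(ph_test(null_fit), "covariate")
})

test_that("exposure-response curves follow the Breslow estimator", {
  # single event at dose 120 among 3 at risk, null model:
  # cumulative hazard steps from 0 to 1/3
  et <- data.frame(whale = paste0("w", 1:3), stratum = "low",
                   dose = c(120, 150, 160), event = c(1L, 0L, 0L),
                   signal_type = "MFAS")
  fit <- fit_hazards(et, covariates = character(0))
  rf <- response_function(fit, doses = c(100, 119, 120, 150))
  expect_equal(rf$response[1:2], c(0, 0))
  expect_equal(rf$response[3], 1 - exp(-1 / 3), tolerance = 1e-10)
  expect_equal(rf$response[4], 1 - exp(-1 / 3), tolerance = 1e-10)
  # monotone non-decreasing in dose, for the fixture fit too
  fx <- load_cee_fixtures()
  etf <- build_event_table(fx$severity_table)
  ff <- fit_hazards(etf, covariates = "signal_type")
  curves <- response_function(ff, newdata = data.frame(signal_type = c("MFAS", "PRN")))
  for (key in split(curves, list(curves$stratum, curves$signal_type))) {
    expect_true(all(diff(key$response) >= -1e-12))
  }
  expect_true(all(curves$lower <= curves$response + 1e-12 &
                    curves$response <= curves$upper + 1e-12))
})

test_that("a null-coefficient response function matches the Kaplan-Meier complement", {
  set.seed(81)
  et <- data.frame(whale = paste0("w", 1:30), stratum = "low",
                   dose = sort(runif(30, 100, 160)),
                   event = rep(c(1L, 0L), 15), signal_type = "MFAS")
  fit <- fit_hazards(et, covariates = character(0))
  km <- survival::survfit(survival::Surv(dose, event) ~ 1, data = et)
  # compare where risk sets are still large; the Nelson-Aalen-type baseline
  # and KM differ by O(sum 1/n_i^2) which blows up in the tail
  grid <- et$dose[1:20]
  rf <- response_function(fit, doses = grid)
  s_km <- stats::approx(c(-Inf, km$time), c(1, km$surv), xout = grid,
                        method = "constant", rule = 2)$y
  expect_lt(max(abs(rf$response - (1 - s_km))), 0.02)
})
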
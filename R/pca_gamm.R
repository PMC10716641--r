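#' Principal component analysis of a dive-metric category
#'
#' Eigendecomposition of the correlation matrix of the category's metrics
#' (metrics are standardized because the categories mix incommensurate
#' units). Components are ordered by variance; each loading column's sign is
#' fixed so that its largest-magnitude entry is positive. Rows with missing
#' values are dropped listwise; constant columns are dropped with a warning.
#'
#' @param metric_table data frame of per-dive metrics.
#' @param category label stored with the result (e.g. `"dive"`,
#'   `"angular"`, `"horizontal"`); when the table carries `c1_`/`c2_`/`c3_`
#'   prefixed columns, the matching prefix selects the columns.
#' @param columns optional explicit metric columns.
#' @return object of class `cee_pca`: list with `loadings` (orthonormal
#'   columns), `variance_fraction`, `scores` (per-dive), `center`, `scale`,
#'   `category`, `dropped`.
#' @export
run_pca <- function(metric_table, category = "dive", columns = NULL) {
  if (is.null(columns)) {
    pref <- c(dive = "c1_", angular = "c2_", horizontal = "c3_")[category]
    columns <- if (!is.na(pref) && any(startsWith(names(metric_table), pref))) {
      names(metric_table)[startsWith(names(metric_table), pref)]
    } else {
      names(metric_table)[vapply(metric_table, is.numeric, logical(1))]
    }
  }
  x <- metric_table[, columns, drop = FALSE]
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 2) stop_invalid("need at least 2 complete dives for a PCA")
  sds <- vapply(x, stats::sd, numeric(1))
  dropped <- names(x)[sds == 0]
  if (length(dropped)) {
    warning(sprintf("dropping constant metric column(s): %s",
                    paste(dropped, collapse = ", ")))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) < 1) stop_invalid("no non-constant metrics left in category")
  xm <- as.matrix(x)
  ctr <- colMeans(xm); scl <- apply(xm, 2, stats::sd)
  z <- scale(xm, center = ctr, scale = scl)
  ee <- eigen(stats::cor(xm), symmetric = TRUE)
  L <- ee$vectors
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  rownames(L) <- colnames(xm)
  colnames(L) <- paste0("PC", seq_len(ncol(L)))
  ev <- pmax(ee$values, 0)
  structure(list(loadings = L, variance_fraction = ev / sum(ev),
                 scores = z %*% L, center = ctr, scale = scl,
                 category = category, dropped = dropped),
            class = "cee_pca")
}

#' @export
print.cee_pca <- function(x, ...) {
  cat(sprintf("PCA of %s metrics: %d components\n", x$category,
              ncol(x$loadings)))
  cat("Variance fractions:", paste(sprintf("%.3f", x$variance_fraction),
                                   collapse = " "), "\n")
  invisible(x)
}

#' Select PCA axes explaining more than a threshold of variance
#'
#' Strictly-greater-than rule (an axis at exactly the threshold is not
#' retained). Component 1 is always retained so a response model exists; a
#' message is emitted if it falls at or below the threshold.
#'
#' @param pca a [run_pca()] result.
#' @param threshold variance fraction in (0, 1); default 0.10.
#' @return integer vector of retained axis indices.
#' @export
select_components <- function(pca, threshold = 0.10) {
  if (threshold <= 0 || threshold >= 1) stop_invalid("threshold must be in (0,1)")
  keep <- which(pca$variance_fraction > threshold)
  if (!length(keep) || !(1 %in% keep)) {
    message("component 1 retained despite variance fraction at or below threshold")
    keep <- sort(unique(c(1L, keep)))
  }
  keep
}

#' Smooth-regression response model for one PCA axis
#'
#' Fits an additive model of the axis scores on categorical exposure terms
#' and penalized-spline smooths of the received-level covariates, with a
#' random whale intercept to account for repeated dives within individuals.
#' Two formula variants are provided. `phase_model` uses all dives:
#' \deqn{score \sim status \times type + state + s(maxRL) + s(cSEL) + s(avgRL)}
#' where `status` is the CEE phase (before/during/after) and `type` the
#' treatment (MFAS/PRN/CONTROL). `exposure_only_model` uses exposure-phase
#' dives only:
#' \deqn{score \sim type \times state + s(maxRL) + s(minRL) + s(cSEL)}
#'
#' Smooths use thin-plate bases with shrinkage (`select = TRUE`) and the
#' basis dimension is reduced automatically when a covariate has fewer
#' unique values than the requested basis size.
#'
#' @param scores numeric response (one PCA axis's per-dive scores).
#' @param design_table data frame aligned with `scores`, with columns
#'   `whale`, `phase`, `cee_type`, `behavioural_state`, `max_rl`, `avg_rl`,
#'   `min_rl`, `csel`.
#' @param formula_variant `"phase_model"` or `"exposure_only_model"`.
#' @param k basis dimension for each smooth.
#' @param sp optional fixed smoothing-parameter vector (otherwise chosen by
#'   generalized cross-validation / REML as per `method`).
#' @param method smoothing-parameter selection method (default `"REML"`).
#' @return object of class `cee_gamm`: list with the fitted `mgcv::gam`
#'   object, a `terms` data frame (per-term approximate p-values and smooth
#'   effective df), `r2_adj`, and the variant label.
#' @export
fit_response_model <- function(scores, design_table,
                               formula_variant = c("phase_model",
                                                   "exposure_only_model"),
                               k = 5, sp = NULL, method = "REML") {
  formula_variant <- match.arg(formula_variant)
  d <- design_table
  d$score <- as.numeric(scores)
  d$whale <- factor(d$whale)
  d$phase <- factor(d$phase, levels = c("before", "during", "after"))
  d$cee_type <- factor(d$cee_type)
  d$behavioural_state <- factor(d$behavioural_state)
  if (formula_variant == "exposure_only_model") {
    d <- d[d$phase == "during", , drop = FALSE]
    d$whale <- droplevels(d$whale)
  }
  kfor <- function(v) {
    ku <- length(unique(d[[v]]))
    if (ku <= 3) return(NA_integer_)  # too few values to support a smooth
    as.integer(min(k, ku - 1L))
  }
  smooths <- if (formula_variant == "phase_model") {
    c("max_rl", "csel", "avg_rl")
  } else {
    c("max_rl", "min_rl", "csel")
  }
  parametric <- if (formula_variant == "phase_model") {
    "phase * cee_type + behavioural_state"
  } else {
    "cee_type * behavioural_state"
  }
  # drop factors with a single level (e.g. one treatment type in simulations)
  for (f in c("phase", "cee_type", "behavioural_state")) {
    if (nlevels(droplevels(d[[f]])) < 2) {
      parametric <- gsub(paste0(f, " \\* "), "", parametric)
      parametric <- gsub(paste0(" \\* ", f), "", parametric)
      parametric <- gsub(paste0("\\+ ", f), "", parametric)
      parametric <- gsub(paste0(f, " \\+"), "+", parametric)
      parametric <- gsub(paste0("^", f, "$"), "", parametric)
    }
  }
  parametric <- gsub("\\+\\s*$|^\\s*\\+", "", trimws(parametric))
  if (parametric == "") parametric <- "1"
  ks <- vapply(smooths, kfor, integer(1))
  if (any(is.na(ks))) {
    warning(sprintf("dropping smooth term(s) with too few unique values: %s",
                    paste(smooths[is.na(ks)], collapse = ", ")))
    smooths <- smooths[!is.na(ks)]; ks <- ks[!is.na(ks)]
  }
  if (any(ks < k)) {
    warning(sprintf("basis dimension reduced for: %s",
                    paste(smooths[ks < k], collapse = ", ")))
  }
  sm <- vapply(seq_along(smooths), function(i)
    sprintf("s(%s, k = %d, bs = \"ts\")", smooths[i], ks[i]), character(1))
  if (!length(sm)) sm <- "1"
  re <- if (nlevels(d$whale) > 1) " + s(whale, bs = \"re\")" else ""
  fml <- stats::as.formula(paste("score ~", parametric, "+",
                                 paste(sm, collapse = " + "), re))
  fit <- mgcv::gam(fml, data = d, method = method, select = is.null(sp),
                   sp = sp)
  s <- summary(fit)
  sm_tab <- as.data.frame(s$s.table)
  sm_tab$term <- rownames(s$s.table)
  pt <- as.data.frame(s$pTerms.table)
  pt$term <- rownames(s$pTerms.table)
  terms <- data.frame(
    term = c(pt$term, sm_tab$term),
    type = c(rep("parametric", nrow(pt)), rep("smooth", nrow(sm_tab))),
    edf = c(rep(NA_real_, nrow(pt)), sm_tab$edf),
    p_value = c(pt$`p-value`, sm_tab$`p-value`))
  structure(list(fit = fit, terms = terms, r2_adj = s$r.sq,
                 variant = formula_variant, n = nrow(d), formula = fml),
            class = "cee_gamm")
}

#' @export
print.cee_gamm <- function(x, ...) {
  cat(sprintf("Response model (%s), n = %d, adj. R^2 = %.3f\n",
              x$variant, x$n, x$r2_adj))
  print(x$terms, row.names = FALSE)
  invisible(x)
}

#' Partial effect of a smooth term over a covariate grid
#'
#' @param model a [fit_response_model()] result.
#' @param term covariate name of the smooth (e.g. `"max_rl"`).
#' @param n grid size.
#' @return data frame with the covariate grid, fitted partial effect and
#'   standard error.
#' @export
partial_effect <- function(model, term, n = 100) {
  fit <- model$fit
  dat <- fit$model
  grid <- dat[rep(1, n), , drop = FALSE]
  v <- dat[[term]]
  grid[[term]] <- seq(min(v), max(v), length.out = n)
  lab <- paste0("s(", term, ")")
  pm <- stats::predict(fit, newdata = grid, type = "terms", se.fit = TRUE)
  data.frame(x = grid[[term]], effect = as.numeric(pm$fit[, lab]),
             se = as.numeric(pm$se.fit[, lab]))
}
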
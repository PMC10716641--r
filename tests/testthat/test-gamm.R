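# synthetic per-dive design: 12 whales cycling MFAS / PRN / CONTROL, received
# level only nonzero during the exposure phase of exposure CEEs
gamm_table <- function(seed, rl_effect = 0, n_whales = 12, n_dives = 40) {
  set.seed(seed)
  rows <- lapply(seq_len(n_whales), function(w) {
    ct <- c("MFAS", "PRN", "CONTROL")[(w - 1) %% 3 + 1]
    phase <- rep(c("before", "during", "after"), length.out = n_dives)
    max_rl <- if (ct == "CONTROL") rep(0, n_dives) else
      ifelse(phase == "during", runif(n_dives, 90, 160), 0)
    data.frame(whale = sprintf("w%02d", w), phase = phase, cee_type = ct,
               behavioural_state = c("deep-feeding", "shallow-feeding",
                                     "non-feeding")[(w - 1) %/% 3 %% 3 + 1],
               max_rl = max_rl, avg_rl = pmax(max_rl - 3, 0),
               min_rl = pmax(max_rl - 6, 0), csel = cumsum(max_rl) / 50,
               score = rnorm(n_dives) + rl_effect * pmax(max_rl - 90, 0) / 70)
  })
  do.call(rbind, rows)
}

test_that("a received-level-driven response is caught by the RL smooth only", {
  tab <- gamm_table(301, rl_effect = 1.5)
  m <- suppressWarnings(fit_response_model(tab$score, tab, "phase_model"))
  tr <- m$terms
  expect_lt(tr$p_value[tr$term == "s(max_rl)"], 0.05)
  expect_gt(tr$p_value[tr$term == "cee_type"], 0.05)
  # fitted partial effect is monotone increasing over the exposed IQR
  pe <- partial_effect(m, "max_rl")
  iqr <- stats::quantile(tab$max_rl[tab$max_rl > 0], c(0.25, 0.75))
  sel <- pe$x >= iqr[1] & pe$x <= iqr[2]
  expect_true(all(diff(pe$effect[sel]) > 0))
})

test_that("pure-noise responses leave the smooths unflagged", {
  # shrinkage smooths under the null: effective df near 0 and no smooth
  # term significant, across replicates
  flagged <- 0
  for (r in 1:5) {
    tab <- gamm_table(400 + r, rl_effect = 0)
    m <- suppressWarnings(fit_response_model(tab$score, tab, "phase_model"))
    sm <- m$terms[m$terms$type == "smooth" & m$terms$term != "s(whale)", ]
    expect_true(all(sm$edf < 1.5))
    if (any(sm$p_value < 0.05)) flagged <- flagged + 1
  }
  expect_lte(flagged, 1)
})

test_that("duplicating rows leaves fixed-penalty estimates unchanged", {
  tab <- gamm_table(305, rl_effect = 1)
  m1 <- suppressWarnings(fit_response_model(tab$score, tab, "phase_model"))
  sp <- m1$fit$sp
  m1f <- suppressWarnings(fit_response_model(tab$score, tab, "phase_model",
                                             sp = sp))
  # duplicating rows doubles the data term of the penalized objective, so the
  # equivalent fixed penalty doubles with it; estimates are then identical
  tab2 <- rbind(tab, tab)
  m2 <- suppressWarnings(fit_response_model(tab2$score, tab2, "phase_model",
                                            sp = 2 * sp))
  expect_equal(unname(fitted(m1f$fit)),
               unname(fitted(m2$fit)[seq_len(nrow(tab))]), tolerance = 1e-6)
  expect_equal(coef(m1f$fit), coef(m2$fit), tolerance = 1e-6)
})

test_that("the exposure-only variant restricts the data and swaps smooths", {
  tab <- gamm_table(306, rl_effect = 1)
  m <- suppressWarnings(fit_response_model(tab$score, tab,
                                           "exposure_only_model"))
  expect_equal(m$n, sum(tab$phase == "during"))
  expect_true(any(grepl("min_rl", m$terms$term)))
  expect_false(any(grepl("avg_rl", m$terms$term)))
})
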
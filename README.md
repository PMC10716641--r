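# sonarCEE

Behavioural response analysis for whale sonar controlled exposure
experiments (CEEs).

Tagged baleen whales are presented with mid-frequency active sonar (MFAS),
pseudorandom noise (PRN) of matched band/duration/level, or a silent
control, across a pre-exposure / exposure / post-exposure protocol, while
an archival tag records their diving behaviour. This package implements
the analysis chain used to quantify fin whale responses in such
experiments, for researchers in marine mammal bioacoustics and
biologging:

* **CEE sound field**: ping schedules (25 s interval, 3 dB ramp from
  160 dB RMS re 1 µPa·m to a 210/206 dB cap), received levels by log-range
  transmission loss, and cumulative sound exposure level
  (cSEL, dB re 1 µPa²·s).
* **Dive metrics**: segmentation of dives (> 3 m) from depth series and
  per-dive behavioural metrics in three categories (dive, angular,
  horizontal), with per-dive exposure covariates.
* **Context hidden Markov model** — the core. Per-dive observations
  `(dive time, max depth, lunges, speed, turning angle)` with
  gamma/gamma/Poisson/gamma/von Mises emissions given an N-state latent
  behavioural process. Each whale belongs to one of K latent "contexts"
  (discrete random effects drawn from mixing probabilities π) with its own
  transition intercepts and initial distribution, and exposure covariates
  act on the transition logits with the diagonal as reference:

  γ⁽ᵏ⁾ᵢⱼ(x) ∝ exp(η⁽ᵏ⁾ᵢⱼ + βᵢⱼ x) for j ≠ i, γᵢᵢ ∝ 1,

  with the dataset log-likelihood Σ_w log Σ_k π_k L_wk computed by exact
  forward recursions (C++/RcppArmadillo, analytic gradients). Multi-start
  BFGS maximum likelihood, AIC model selection over K and covariates, Wald
  intervals from the observed Fisher information, and local decoding under
  the discrete random effects.
* **Group-level response models**: correlation-matrix PCA per metric
  category (axes with > 10% variance retained) and `mgcv` additive models
  of axis scores on phase × treatment + behavioural state with shrinkage
  smooths of max RL, cumulative SEL and average RL, plus a random whale
  intercept.
* **Severity and dose-response**: windowed Mahalanobis change metrics, and
  a dose-as-time recurrent-event survival analysis of expert severity
  scores (low 1–3 / moderate 4–6 strata): stratified Cox partial
  likelihood with cSEL as the event axis, Breslow ties, grouped
  leave-one-whale-out jackknife standard errors, proportional-hazards
  checks, and exposure-response curves 1 − S(cSEL).

The package ships plain-text fixtures of the published CEE metadata and
adjudicated expert severity scores for the 21 tagged fin whales (11 MFAS,
4 PRN, 6 control CEEs), and a synthetic-data generator that emulates the
whole experiment so every stage is testable without raw tag records.

## Worked example

```r
library(sonarCEE)

## CEE sound field
sched <- make_cee_schedule("MFAS")
sched
#> CEE schedule: MFAS, 72 pings, SL 160-210 dB over 1775 s
expo <- received_levels(sched, range_m = 1000)
round(tail(expo$cumulative_sel, 1), 1)   # cSEL after the full ramp at 1 km
#> [1] 167.5

## synthetic CEE population and the context-HMM
spec <- hmm_spec(n_states = 3, n_contexts = 2, covariate = "max_rl")
pop <- simulate_cee_population(n_whales = 15, dives_per_whale = 120,
                               spec = spec, beta21 = 1.2, seed = 31)
fit <- fit_hmm(pop$data, spec, n_starts = 8, seed = 3, n_optim = 2)
fit
#> Context-HMM fit: N=3 states, K=2 context(s), covariate=max_rl (shared)
#>   loglik = -25375.724, parameters = 50, AIC = 50851.449

ci <- wald_ci(fit)
ci[ci$parameter == "beta.p1.2->1", ]
#>                 parameter estimate        se    lower   upper excludes_zero
#> beta.p1.2->1 beta.p1.2->1 2.342532 0.4773804 1.406883 3.27818          TRUE

dec <- local_decode(fit)
switch_rates(dec, pop$data, from = 2, to = 1)
#>    phase opportunities switches      rate
#> 1 before           281       31 0.1103203
#> 2 during           260       48 0.1846154
#> 3  after           269       36 0.1338290
```

The positive generating effect of maximum received level on the
non-feeding (2) → deep-feeding (1) transition is recovered with a Wald
interval excluding zero, and the decoded state sequences switch into deep
feeding almost twice as often during exposure (rate 0.185) as before it
(0.110).

```r
## dose-as-time severity survival on the packaged tables
fx <- load_cee_fixtures()
et <- build_event_table(fx$severity_table)
sig <- fit_hazards(et, covariates = "signal_type")
sig
#> Dose-as-time stratified Cox model (breslow ties): loglik = -22.0097, AIC = 46.0195
#>            term estimate  se_model se_jackknife
#>  signal_typePRN  1.08004 0.6746338     1.179614
nul <- fit_hazards(et, covariates = character(0))
abs(nul$aic - sig$aic)
#> [1] 0.3641842
ph_test(sig)
#>                    term    chisq df         p
#> signal_type signal_type 1.752664  1 0.1855422
#> GLOBAL           GLOBAL 1.752664  1 0.1855422
```

Among the 15 exposure CEEs there are 5 low-band and 4 moderate-band
severity events; the signal-type hazards model sits within 0.5 AIC of the
null (weak support for a signal-type effect) and passes the
proportional-hazards check. `response_function(sig,
newdata = data.frame(signal_type = c("MFAS", "PRN")))` returns the
exposure-response curves with jackknife confidence bands.

`run_pipeline(run_config(seed = 1))` executes the whole chain (fixture
validation → simulation → metrics → HMM selection → PCA/GAMM → severity
survival) and returns a report whose hash reproduces bit-identically for a
fixed configuration.

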
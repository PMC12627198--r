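# ambiddm

Drift-diffusion modelling of ambiguity preferences in intertemporal and
risky choice.

## What this package is for

When the delay of a future reward or the probability of a risky win is
given only as a range ("50–150 days", "25–75%"), choices reveal
*ambiguity preferences*: most people avoid options whose key attribute is
imprecise.  `ambiddm` is a complete, tested pipeline for studying time
ambiguity and probability ambiguity within one two-domain choice task
(a variable option against a constant EUR 5 now for sure), aimed at
researchers in decision science and mathematical psychology:

* **Task design** — the factorial trial grids (7 amounts × 9 exact
  delays/probabilities + 7 amounts × 5 ambiguity range widths per domain,
  98 unique trials each) and full 210-trial sessions with 14 alternating
  blocks and one catch trial per block.
* **Model family** — 21 drift-diffusion models (12 intertemporal, 9
  risky) whose drift rate encodes competing theories of valuation:
  hyperbolic and generalized hyperbolic discounting, expected utility and
  the Gilboa–Schmeidler model, and attribute-wise weighted comparison,
  each with additive, perception-based or attribute-based ambiguity
  terms.  The likelihood is the Wiener first-passage-time (WFPT)
  distribution over (RT, choice),

  `v = eta * (SV_variable - SV_constant)`,  `RT, choice ~ WFPT(A, t0, z, v)`,

  with preference-switch trials contributing choice-only likelihoods
  through the absorption probability
  `P(upper) = (exp(-2*A*z*v) - 1) / (exp(-2*A*v) - 1)`.
* **Synthetic cohorts** — participants with known ground-truth
  parameters (70% ambiguity-averse by default, aversion correlated
  across domains), DDM-simulated behaviour, realistic RT contaminants and
  switch trials, so every downstream stage is testable without data
  collection.
* **Preprocessing** — the exclusion cascade for online behavioural data
  (catch-trial errors, RT outliers outside [0.3 s, 10 s], preference
  switches).
* **Estimation** — per-participant Bayesian fits with wide priors on
  transformed scales, a built-in posterior engine (mode finding +
  rotated slice sampling), split-R-hat convergence checks (threshold
  1.005), and pointwise log-likelihood output.
* **Model comparison** — PSIS-LOO (generalized-Pareto-smoothed
  importance sampling with k-hat diagnostics), Akaike-type softmax model
  weights, pseudo-inclusion Bayes factors over model families, and
  random-effects Bayesian model selection with protected exceedance
  probabilities (PXP) and the Bayes omnibus risk (BOR).
* **Individual differences** — ambiguity-preference classification from
  the posterior sign of the ambiguity effect, robust Bayesian correlation
  (bivariate Student-t), and the ROPE+HDI decision rule.

See `vignettes/ambiguity-ddm-methods.Rmd` for the models, priors,
numerical choices and limitations.

## Worked example

Simulate one clean synthetic participant from the attribute-wise model
with ambiguity and a reward × delay interaction, fit it, and classify
the ambiguity preference:

```r
library(ambiddm)

pop <- population_spec(p_rt_outlier = 0, p_switch_trial = 0)
coh <- simulate_cohort(1, seed = 3, models = c(delay = "itc_aw_amb_rxd"),
                       pop = pop, domains = "delay")
fit <- fit_participant(coh$behavior, "itc_aw_amb_rxd",
                       mcmc_config(n_warmup = 1000, n_sampling = 1000,
                                   seed = 5), participant = 1)
fit
#> ddm_fit: itc_aw_amb_rxd | participant 1
#>   trials: 98  draws: 2000  max split-Rhat: 1.0014
#>   posterior means:
#>       A      t0       z     w_r     w_t w_inter   w_amb
#>  1.6657  0.2691  0.5766  0.0373 -0.0108 -0.0001 -0.0097

classify_ambiguity_preference(fit)
#> [1] "averse"
```

The posterior means sit close to the generating truth (A = 1.56,
t0 = 0.26, w_amb = -0.0125): boundary separation ~1.7 evidence units,
non-decision time ~0.27 s, and a negative ambiguity weight — every 2
days of range width reduces the drift toward the ambiguous option by
about 0.01 evidence units/s, i.e. this participant is time-ambiguity
averse.

The `analysis/` directory holds the full workflow as numbered scripts
(design → simulate a 24-participant cohort → exclusions → per-participant
fits of 4 models per domain → PSIS-LOO + RE-BMS + pseudo-inclusion Bayes
factors → cross-domain robust correlations), each printing what it finds
and writing its tables under `results/`.  On the default cohort the
delay domain recovers the ambiguity family decisively (family-level
PXP = 0.96, median PBF_inclusion = 2.7), while the probability domain —
where the generating Gilboa–Schmeidler ambiguity signal is weak at this
sample size — stays undecided (BOR = 0.92), and the n = 19 cross-domain
correlations are inconclusive, as expected at desk scale.

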
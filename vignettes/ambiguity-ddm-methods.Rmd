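---
title: "Modelling ambiguity preferences in intertemporal and risky choice with drift-diffusion models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ambiguity preferences in intertemporal and risky choice with drift-diffusion models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ambiddm)
```

## The scientific problem

People often face choices whose key attribute — a delivery delay or a win
probability — is only known as a range: "you will receive it in 50 to 150
days", "the chance of winning is 25–75%".  `ambiddm` implements a complete
analysis pipeline for studying such *time ambiguity* and *probability
ambiguity* within one task family: a variable option (a larger amount with
an exact or ambiguous delay / win probability) against a constant
alternative of EUR 5 now for sure.  The pipeline covers the factorial task
design, a family of drift-diffusion models (DDMs) whose drift rate encodes
competing theories of how ambiguity enters valuation, per-participant
Bayesian estimation, model comparison, and cross-domain
individual-difference analyses.  Because the pipeline is exercised on
synthetic cohorts that it generates itself, every stage is testable
without any external data.

## Task design

Each domain contributes 98 unique choice trials: 7 amounts (EUR 8–50)
crossed with 9 exact attribute levels (delays 10–190 days, or win
probabilities 5–95%), plus the 7 amounts crossed with 5 ambiguity range
widths (0–200 days around a fixed midpoint of 100 days; 0–100 percentage
points around 50%).  A zero-width range is included deliberately: it is
attribute-identical to the corresponding exact trial, which anchors the
ambiguity scale.  A session interleaves seven 15-trial blocks per domain,
each block containing one catch trial in which the variable amount equals
the constant EUR 5, so attentive participants should never prefer it.

One design cell required a decision: the exact-delay ladder is specified
as nine levels but only eight values are printed in the source design
(10, 26, 50, 76, 100, 150, 174, 190).  We insert 124, which restores the
ladder's symmetry around 100 days and mirrors the 76–124 ambiguity range
endpoints; nothing downstream depends on this cell beyond grid arithmetic.
Catch trials carry a mid-level exact attribute (100 days / 50%) because
the attention check depends only on the amount.

## The model family

Evidence accumulates from a relative starting point $z \in (0,1)$ between
absorbing boundaries at $0$ and $A$ with unit diffusion; hitting the upper
boundary selects the variable option, the lower boundary the constant
option, and the response time is the first-passage time plus a
non-decision time $t_0$.  The drift rate $v$ is a deterministic function
of the trial attributes, and the 21 candidate models differ only in that
function:

* **Integrated-value models** set
  $v = \eta\,(SV_\mathrm{variable} - SV_\mathrm{constant})$, with
  subjective values from hyperbolic discounting $V/(1+kD)$, its
  generalized form $V/(1+(kD)^s)$, or expected utility $P V^\alpha$.
  Ambiguity enters either additively ($-\beta\,\mathrm{Amb}/2$), through
  perceived time ($D - \beta\,\mathrm{Amb}$), or through perceived
  probability ($P - \beta\,\mathrm{Amb}/2$; the Gilboa–Schmeidler model).
* **Attribute-wise models** compare attributes directly,
  $v = w_r \Delta V + w_t \Delta D$ (or $w_p \Delta P$), optionally with a
  reward-by-attribute interaction, an ambiguity attribute
  ($w_\mathrm{amb}$), and a reward-by-ambiguity interaction.  For these
  models $\eta$ is fixed to 1: the weights absorb the scale, and a free
  $\eta$ would be multiplicatively unidentifiable.

Two printed-formula subtleties are implemented deliberately.  First, the
sooner-smaller term of the hyperbolic family is evaluated with the
constant option's amount ($V = 5$, $D = 0$); the printed source carries
the variable amount there, which with $D_{SS}=0$ would force non-positive
drift on every trial.  A `strict_printed` flag reproduces the printed form
for comparison.  Second, some rows scale the ambiguity main effect by the
half-range $\mathrm{Amb}/2$ and others by the full range; each row is
implemented exactly as printed, so parameter values are comparable with
the source's scale conventions.

Response times and choices of single-response trials enter the likelihood
through the Wiener first-passage-time (WFPT) density, evaluated with the
dual short-time/long-time series expansion with truncation error below
$10^{-9}$, switching regimes per evaluation by the standard precision
criterion.  Trials on which the participant switched preference before
confirming indicate multiple accumulation episodes; their RTs are not
DDM-distributed, so they contribute only the choice through the absorption
probability
$P(\mathrm{upper}) = \frac{e^{-2Azv}-1}{e^{-2Av}-1}$,
with the continuous limit $P \to z$ as $v \to 0$ handled by series
expansion.

## Synthetic cohorts

`simulate_cohort()` draws participants from truncated-normal population
distributions chosen so that drifts over the trial grids span roughly
$\pm 3$ evidence units/s and RTs fall mostly between 0.5 and 3 s
(boundary 1.5 ± 0.3, non-decision time 0.35 ± 0.08 s, mild start bias).
The ambiguity parameter is sampled as a magnitude and signed so that a
participant is ambiguity-averse with probability 0.70, matching the
majority aversion rate observed in large behavioural cohorts; across
domains the aversion indicators share a Gaussian copula with correlation
0.3, emulating a partially shared ambiguity attitude (empirical
cross-domain correlations of ambiguity measures fall between roughly 0.15
and 0.3).  Contaminants mirror what online data exhibit: 7.9% of RTs are
replaced by draws outside [0.3 s, 10 s] (half below, half above, so both
exclusion arms are exercised), 5% of trials are flagged as preference
switches (their choice redrawn from the absorption probability), and
catch trials are answered incorrectly with probability 0.02, independent
of the DDM parameters — attention, not evidence accumulation.

Decision times are drawn by sampling the boundary from the exact
absorption probability and inverting the conditional first-passage CDF
computed from the series density; a forward Euler–Maruyama simulator is
retained as an independent oracle in the tests.  What the generator does
*not* emulate: learning or order effects across blocks, the causal
process behind preference switches (they are flagged at random rather
than produced by a change of mind), and non-stationary attention.  Tests
passing on these cohorts therefore certify the estimation and comparison
machinery, not the behavioural completeness of the generative model.

## Preprocessing

The exclusion cascade reads the printed rules literally: RTs *shorter
than* 300 ms or *longer than* 10 s are outliers (strict inequalities;
boundary values are kept); two *or more* catch errors exclude a
participant from all analyses; 10% *or more* outlier trials or 100 *or
more* total switches additionally exclude from the DDM analyses
(inclusive bounds).  The outlier percentage is computed over all 210
trials including catch trials by default — the source is silent on the
denominator — and is configurable.

## Estimation

Parameters are sampled on unconstrained scales (log for positive
parameters, logit for the starting point) with independent normal(0, 5)
priors — wide enough to be effectively flat over the plausible range of
every parameter.  With no probabilistic-programming backend required, the
package ships its own posterior engine: the mode is located numerically
(Nelder–Mead, then BFGS) and each chain runs a short adaptive random-walk
warmup before switching to a rotated componentwise slice sampler along
the principal axes of the estimated posterior covariance, with the axes
re-estimated midway through warmup from the slice draws themselves.
Slice sampling is rejection-free and self-tuning, which keeps
autocorrelation low enough to meet a split-$\hat{R}$ threshold of 1.005
at moderate chain lengths.  Two chains with 3,500 warmup and 4,500
sampling iterations are the reference configuration; the recovery studies
and tests use 2 × 500/500 (and 1,000/1,000 for the convergence check),
which keeps a full 20-participant recovery under a minute while leaving
the posterior means stable to well within the population spread.

Parameter recovery under the default population (20 participants, full
98-trial intertemporal sessions, no contaminants) identifies the boundary,
non-decision time, reward weight and ambiguity weight with correlations
around or above 0.85; parameters whose population spread is small relative
to their posterior uncertainty (the interaction weight, the delay weight,
the start bias) recover more weakly, as expected from attenuation — their
population scales were fixed from plausibility, not tuned for
recoverability.

## Model comparison

Pointwise log-likelihood matrices feed PSIS-LOO, implemented in the
package: per-trial importance ratios are stabilised by replacing the
upper tail with expected order statistics of a generalized Pareto
distribution fitted by the profile-posterior method, and the tail-shape
diagnostic $\hat{k}$ is reported per trial.  The implementation is tested
against a closed-form leave-one-out oracle in a conjugate normal model.
Per-participant elpd values are converted to Akaike-type softmax weights;
the pseudo-inclusion Bayes factor for a model family (ambiguity vs
non-ambiguity, attribute-wise vs integrated-value) is the family's
posterior odds from those weights divided by its prior odds under a
uniform model prior — the prior correction matters because the families
are of unequal size.  Group-level inference uses random-effects Bayesian
model selection: a variational Dirichlet posterior over population model
frequencies, exceedance probabilities by Dirichlet Monte Carlo
($10^5$ draws; Monte-Carlo error about 0.003), the Bayes omnibus risk
from the free-energy comparison against the equal-frequency null, and
protected exceedance probabilities
$\mathrm{PXP} = (1-\mathrm{BOR})\,\mathrm{EP} + \mathrm{BOR}/K$.
RE-BMS consumes elpd values directly; since elpd approximates the log
predictive evidence, no rescaling is applied.

## Individual differences

A participant's ambiguity preference is classified from the posterior
sign of the oriented ambiguity effect $\partial v/\partial \mathrm{Amb}$
(negative = averse); the default criterion is the posterior median sign,
with an optional stricter posterior-probability threshold.  Cross-domain
association is quantified by a robust Bayesian correlation — a bivariate
Student-t likelihood with unknown degrees of freedom, uniform prior on
the correlation, shifted-exponential prior (mean 30) on $\nu - 1$, and
weakly informative location/scale priors — which is insensitive to the
outliers that least-squares correlations amplify.  Verdicts use the
ROPE+HDI rule with shortest-interval HDIs on pooled chains: significant
if the 95% HDI is disjoint from the region of practical equivalence,
practically equivalent if contained, inconclusive otherwise.  For
correlations the default ROPE is $\pm 0.05$; inputs are z-standardised
before correlating.

## Numerical choices and degenerate inputs

* WFPT series truncation: $10^{-9}$ absolute density error; observations
  at or below $t_0$ return $-\infty$ log density, distinct from parameter
  errors.
* Time-perception models floor the effective delay at zero before
  exponentiation (delays are non-negative by construction).
* The generalized-Pareto smoothing falls back to the exact pointwise
  log-likelihood, with a warning, when all draws are identical.
* A zero out-group weight mass makes the pseudo-inclusion Bayes factor
  infinite; it is returned as a capped sentinel with a flag.
* Degenerate ground-truth variance makes recovery correlations undefined;
  they are reported as `NA` with a flag rather than dropped.
* Fits with non-finite diagnostics or pathological acceptance are marked
  unusable instead of being returned silently.

## Known limitations

Fitting is per participant, matching the individual-level model
comparison design; hierarchical pooling is out of scope.  Across-trial
variability parameters of the full Ratcliff DDM ($s_v$, $s_{t0}$, $s_z$)
are not modelled — the canonical four parameters only.  The
regression-based (GLMM) analysis path of choice and RT data, and model
evidence via kernel density estimation, are outside the package's scope;
the cross-domain correlation targets here are the DDM-derived quantities
(log pseudo-inclusion Bayes factors and ambiguity parameters).
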
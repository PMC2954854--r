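---
title: "Methods: regret-based decision curve analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regret-based decision curve analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regretdca)
```

## The decision model

A binary treat/no-treat decision under an uncertain disease state has four
outcomes, with utilities U₁ (treat, diseased), U₂ (treat, healthy), U₃
(no treat, diseased) and U₄ (no treat, healthy). Regret is the utility gap
between the action taken and the action that hindsight would have chosen:
a false negative costs U₁−U₃ (the foregone benefit of treatment), a false
positive U₄−U₂ (the harm of unnecessary treatment), and correct decisions
cost nothing. The threshold probability at which treating and not treating
carry equal expected regret is

$$P_t = \frac{1}{1 + \dfrac{U_1-U_3}{U_4-U_2}}.$$

`regretdca` never asks for the four utilities separately. The two
*differences* are elicited directly as ratings on paired 0–100 visual
analog scales — the regret of omission (U₁−U₃) and of commission (U₄−U₂) —
because a decision maker can judge "how bad would a missed cancer feel"
far more reliably than an abstract utility. The ratings are treated as
linear and are not re-anchored or transformed; the threshold depends only
on their ratio. When the commission rating is zero the ratio is undefined
and `threshold_from_regrets()` returns Pₜ = 1 with an infinite odds
weight: treatment would be justified only at certainty of disease.
When both ratings are zero the decision maker is entirely indifferent and
no threshold exists; this input is rejected rather than defaulted.

## Expected regret and NERD

All regrets are rescaled so that the omission regret U₁−U₃ equals 1; the
commission regret then equals the threshold odds $w = P_t/(1-P_t)$. For a
cohort of $n$ patients with model-predicted risks $p_i$ and observed
outcomes, classifying "treat" when $p_i \ge P_t$ (ties treated) gives the
confusion counts, and

$$ERg[\text{model}] = \frac{FN}{n} + \frac{FP}{n}\,w, \qquad
ERg[\text{treat all}] = (1-\hat\pi)\,w, \qquad
ERg[\text{treat none}] = \hat\pi,$$

with $\hat\pi$ the cohort prevalence. We use the joint-count form
throughout — $FN/n$ estimates $P(p < P_t \cap D^+)$, $FP/n$ estimates
$P(p \ge P_t \cap D^-)$, and so on with the standard correspondence of
cells to labels — because it is the form the plug-in estimators define.
Prevalence is always estimated from the cohort itself; injecting an
external prevalence is deliberately unsupported in this version, keeping
every curve a pure function of the supplied data.

The net expected regret difference $NERD[s_1, s_2] = ERg[s_1] - ERg[s_2]$
is positive when $s_2$ is the lesser regret. `nerd_pair()` computes the
three canonical pairs from the count formulas directly:
$NERD[\text{none},\text{model}] = TP/n - (FP/n)\,w$ (identically the
classic decision-curve net benefit, which `net_benefit()` implements as a
separate code path so the identity can be *checked* rather than assumed),
$NERD[\text{none},\text{all}] = \hat\pi - (1-\hat\pi)\,w$, and
$NERD[\text{all},\text{model}] = (TN/n)\,w - FN/n$. The additivity
identity NERD[none, model] − NERD[none, all] = NERD[all, model] is exact
algebraically and holds to floating-point rounding (well below 1e−12) in
the implementation, which the test suite asserts on randomly generated
cohorts.

## Strategy selection and acceptable regret

At a given threshold the optimal strategy is the transitive minimum of the
three expected regrets, read off the NERD signs. Two numerical conventions
matter here:

* **Tie tolerance.** Strategies within 1e−12 (absolute) of the minimum are
  co-optimal. This separates algebraic ties (e.g. treat-all vs treat-none
  exactly at the prevalence) from float noise; genuinely coarse
  indifference is the job of the acceptable-regret budget, not of this
  tolerance.
* **Preference order.** When several strategies are equivalent — exactly
  tied, or within the acceptable-regret budget — the recommendation is the
  least burdensome: treat none, then treat all, then model. Running a
  prediction model has real costs (data collection, computation,
  explanation), so a model whose advantage fits inside the tolerable-loss
  budget is reported as *superfluous*. The full equivalence set is always
  returned alongside the recommendation.

The acceptable-regret budget is elicited through a concrete scenario
("out of the 20 patients who need treatment, how many missed treatments
could you tolerate?") rather than by asking for a fraction directly. The
answer gives $r = \text{tolerated}/\text{denominator}$, and the default
budget is $Rg_0 = r \times \text{rating}/100$, the rating being the
matching VAS answer (omission for a benefits-based scenario, commission
for harms). This *literal* convention mirrors the arithmetic a clinician
would do by hand, but it mixes scales: NERD curves live in units of the
omission regret, while a harms-based budget is built from the commission
rating. The *normalized* convention (`scale = "normalized"`, giving
$Rg_0 = r$) keeps budget and curves in the same rescaled units. Both are
exposed; literal is the default because it reproduces the hand
calculation exactly, and the discrepancy only matters when the two
ratings differ greatly. Comfort bounds are unit-free either way:
$P_{\text{treat none}} = r_b$ and $P_{\text{treat all}} = 1 - r_h$.

`decide()` chains the whole workflow — threshold, curve point, strategy,
budget, comfort bounds — and evaluates the curve at the elicited threshold
by exact reclassification of the cohort, not by grid interpolation:
elicited thresholds such as 6/13 rarely fall on a grid, and
reclassification costs only O(n).

## Numerical choices

* Thresholds at or above 1 − 1e−9 are rejected wherever an odds weight is
  needed; the weight diverges there and the expected regrets are
  undefined.
* Percent reporting truncates to the whole percent (1/6 → "16%") because
  that is how thresholds are conventionally read back to the decision
  maker; an epsilon of 1e−9 inside the truncation guards against floats
  like 0.29 × 100 = 28.999… losing a point. Full precision is always kept
  internally.
* Scenario arm sizes round half up (100 × 0.205 → 21 should-treat).
* Simulated risks are clipped to [1e−9, 1 − 1e−9] before any log-odds
  transform so the miscalibration map is total.
* Cohort CSVs serialise risks at 10 significant digits — enough to
  round-trip any realistic risk through text without bloating files.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` stands in for a clinical risk model evaluated on a
patient series. *Calibrated* mode draws a true risk per patient from a
Beta(a, b) distribution and the outcome from Bernoulli(true risk),
reporting the true risk — a perfectly calibrated model whose analytic
curve properties (prevalence = Beta mean, closed-form NERD integrals) make
it the workhorse of the test suite. *Two-group* mode draws the outcome
first at a fixed prevalence and then a group-specific Beta risk,
controlling discrimination directly. Reported risks can additionally be
distorted on the log-odds scale (shift and slope) without touching the
outcome mechanism, which is how miscalibrated and overconfident models are
emulated.

Defaults are fixed at the package's running prostate-biopsy example: 20%
prevalence (calibrated Beta(2, 8); two-group π = 0.2), with two-group
shapes Beta(3, 3) vs Beta(1.5, 6) giving a well-separated, strongly
discriminating model (AUC ≈ 0.9) — the regime in which acting on the
model should clearly beat the blanket strategies over a wide threshold
band. For curve-shape
checks the tests use an *overconfident* variant (group shapes Beta(4, 2)
vs Beta(2, 4), log-odds slope 2), because a model with inflated extreme
predictions is what produces the classic three-band curve — treat-all
co-optimal near threshold 0, the model dominating an interior band, and
treat-none winning at high thresholds where the odds weight amplifies
false positives.

Two RNG streams (risks, outcomes) are derived deterministically from the
seed, so enlarging a cohort preserves the existing patients — stable
fixtures without stored data. The session RNG state is left untouched.

The generator does *not* emulate covariate structure (no logistic model is
fitted), informative missingness, verification bias, or clustering of
patients within clinicians. Passing tests on these cohorts therefore
demonstrates the correctness of the regret arithmetic and the selection
logic, not the real-world performance of any particular clinical model.

## Problem sizes

The test suite exercises exactness properties on 1,000 random cohorts of
up to 50 patients (net-benefit equivalence at 1e−12) and 300 of up to 25
(brute-force regret oracle), and Monte-Carlo recovery on calibrated
cohorts of 10,000 patients over the default 100-point threshold grid,
with agreement required within three standard errors of the plug-in
estimator. These sizes give standard errors around 0.004 on a prevalence
of 0.2 — tight enough that a sign or scale error in the curve arithmetic
cannot hide inside the Monte-Carlo band.

## Known limitations

* Single decision maker, single time point: shared decision-making and
  decisions that recur over time are out of scope.
* No confidence intervals or bootstrap bands around NERD curves.
* Harms of the diagnostic test itself are not modelled as a separate term.
* Whether VAS ratings should be re-elicited per patient or reused across
  similar patients is an empirical question the package does not answer;
  it simply recomputes everything per call.
* Elicitation by standard gamble or time trade-off is deliberately not
  offered; the dual-VAS design is the package's contract.
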
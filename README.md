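# regretdca

Regret-based decision curve analysis for clinical prediction models.

## The problem

A clinician holding a risk prediction for a patient — say, a statistical
model's 20% probability of prostate cancer — faces three options: act on the
model (biopsy if the risk clears a threshold), treat everyone, or treat no
one. Classic decision curve analysis (DCA) compares these strategies by
*net benefit* across a range of threshold probabilities. `regretdca`
reformulates that comparison in terms of **anticipated regret**: the utility
lost when a decision proves, in retrospect, wrong. The regret framing is
mathematically equivalent to net benefit but gives a more natural language
for eliciting preferences ("how much would you regret a missed cancer?") and
adds a notion classic DCA lacks — *acceptable regret*, the amount of loss a
decision maker can live with.

The package is for biostatisticians and clinical researchers evaluating
prediction models, and for building decision-support workflows on top of
such models.

## The method

**Threshold elicitation.** The decision maker rates, on two 0–100 visual
analog scales, the regret of *omission* (withholding needed treatment,
standing for the utility difference U₁−U₃) and of *commission* (treating
unnecessarily, U₄−U₂). The treatment threshold is

> Pₜ = 1 / (1 + omission/commission)

Ratings of 60 and 30 — omission twice as bad — give Pₜ = 1/3: treat when the
predicted risk reaches 33%.

**Regret curves.** For a cohort of n patients with predicted risks pᵢ and
observed outcomes, classifying each patient as "treat" when pᵢ ≥ Pₜ yields
confusion counts, and (in units where the omission regret is 1, with
w = Pₜ/(1−Pₜ)) the expected regrets

> ERg[model] = FN/n + (FP/n)·w  ERg[treat all] = (1−prev)·w  ERg[treat none] = prev

The **Net Expected Regret Difference** between two strategies,
NERD[s₁, s₂] = ERg[s₁] − ERg[s₂], is positive when the second strategy
inflicts less regret; NERD[treat none, model] = TP/n − (FP/n)·w is exactly
the classic net benefit. Sweeping Pₜ over a grid gives the regret decision
curve; the optimal strategy at each threshold follows from the NERD signs by
transitivity.

**Acceptable regret.** A scenario question ("out of the 20 patients who
should be biopsied, how many missed biopsies could you tolerate?") yields a
tolerated-error fraction r and a regret budget Rg₀. Strategies whose |NERD|
against the optimum fits inside Rg₀ are *equivalent in regret* — if treating
no one is equivalent to using the model, the model is superfluous effort.
The same fractions bound the *comfort zone*: withholding treatment is
tolerable below P_treat-none = r_b, treating is tolerable above
P_treat-all = 1 − r_h.

## Worked example

A physician rates the regret of a missed biopsy at 50/100 and of an
unnecessary biopsy at 10/100, would tolerate 1 missed biopsy among 20
needed ones, and sees a patient with a model-predicted cancer risk of 20%:

```r
library(regretdca)

cohort <- simulate_cohort(1000, mode = "two_group", seed = 7)
d <- decide(
  omission = 50, commission = 10,
  cohort = cohort, patient_risk = 0.20,
  tolerated = 1, denominator = 20, basis = "benefits"
)
glance(d)
#> # A tibble: 1 × 6
#>   threshold optimal   rg0 recommendation treat patient_risk
#>       <dbl> <chr>   <dbl> <chr>          <lgl>        <dbl>
#> 1     0.167 model   0.025 model          TRUE           0.2
```

The printed report narrates the five steps:

```
Step 1 - Threshold elicitation
  threshold: 16% (exact 0.166667, odds weight 0.2000)
Step 2 - Strategy comparison at the threshold
  NERD[treat_none vs model] = +0.140600 -> model
  NERD[treat_none vs treat_all] = +0.074800 -> treat_all
  NERD[treat_all vs model] = +0.065800 -> model
  optimal strategy: model
Step 3 - Patient decision
  patient risk 20% vs threshold 16% -> treat (risk at or above threshold)
Step 4 - Acceptable regret
  basis benefits: tolerated 1 of 20 -> r = 0.05, budget rg0 = 0.025
  equivalent in regret: model
Step 5 - Comfort bounds
  tolerate withholding treatment below p_treat_none = 5%

Recommendation: model -> treat this patient
```

Reading it: the 50/10 ratings put the biopsy threshold at 1/6 ≈ 16%. On this
cohort all three NERDs are positive, so acting on the model carries the
least expected regret. The patient's 20% risk clears the 16% threshold —
biopsy. The regret budget (5% of the benefit scale × 0.5 = 0.025) is smaller
than every NERD, so no simpler strategy is equivalent in regret, and the
physician would only be comfortable skipping the biopsy below a 5% risk.

Curves plot directly:

```r
curve <- regret_curve(cohort)          # thresholds 0 … 0.99
autoplot(curve, rg0 = 0.025)           # three NERD series ± budget lines
```

A thin CLI wraps the same functions
(`exec/regretdca elicit|simulate|curve|decide`), and a small synthetic
example cohort ships in `inst/extdata/synthetic_cohort_100.csv`.

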
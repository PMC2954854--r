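# shared fixtures, built in code

# four-patient toy cohort: one of each confusion cell at Pt = 0.5
toy_cohort <- function() {
  data.frame(
    risk = c(0.9, 0.6, 0.3, 0.1),
    outcome = c(1, 0, 1, 0)
  )
}

# a model that separates perfectly: risk 1 for diseased, 0 for the rest
perfect_cohort <- function(n_dis = 3, n_nondis = 7) {
  data.frame(
    risk = rep(c(1, 0), c(n_dis, n_nondis)),
    outcome = rep(c(1, 0), c(n_dis, n_nondis))
  )
}

# random small cohort for property tests (caller controls the RNG state)
random_cohort <- function(n) {
  data.frame(
    risk = stats::runif(n),
    outcome = stats::rbinom(n, 1, stats::runif(1, 0.1, 0.9))
  )
}

# independent oracle: average per-patient regret of acting on the model,
# 1 per false negative, w per false positive, under the treat-if-risk>=Pt rule
brute_force_erg_model <- function(cohort, pt) {
  w <- pt / (1 - pt)
  treat <- cohort$risk >= pt
  contrib <- ifelse(
    treat,
    ifelse(cohort$outcome == 1, 0, w),
    ifelse(cohort$outcome == 1, 1, 0)
  )
  mean(contrib)
}

# deterministic 20-patient cohort, prevalence 0.2, tuned so that at
# Pt = 6/13 the model makes 1 TP and 2 FP (treat_none mildly preferable)
physician2_cohort <- function() {
  data.frame(
    risk = c(
      0.60, 0.35, 0.30, 0.25,                  # diseased
      0.55, 0.50, 0.40, 0.38, 0.35, 0.32,      # non-diseased
      0.30, 0.28, 0.25, 0.22, 0.20, 0.18,
      0.15, 0.12, 0.10, 0.05
    ),
    outcome = rep(c(1, 0), c(4, 16))
  )
}
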
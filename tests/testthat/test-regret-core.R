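test_that("cohort validation catches malformed input", {
  expect_error(as_cohort(data.frame(risk = 0.5)), "outcome")
  expect_error(as_cohort(data.frame(risk = numeric(), outcome = numeric())),
    "no patients")
  expect_error(
    as_cohort(data.frame(risk = c(0.5, 1.2), outcome = c(1, 0))),
    "row\\(s\\): 2"
  )
  expect_error(
    as_cohort(data.frame(risk = c(0.5, 0.4), outcome = c(1, 2))),
    "0 or 1"
  )
  co <- as_cohort(toy_cohort())
  expect_s3_class(co, "cohort")
  expect_equal(co$id, 1:4)
  expect_equal(prevalence(co), 0.5)
})

test_that("classification treats at or above the threshold", {
  expect_equal(
    classify_cohort(toy_cohort(), 0.5)[, c("tp", "fp", "fn", "tn")],
    tibble::tibble(tp = 1L, fp = 1L, fn = 1L, tn = 1L)
  )
  # at Pt = 0 everyone is treated
  all_treated <- classify_cohort(toy_cohort(), 0)
  expect_equal(all_treated$tp, 2L)
  expect_equal(all_treated$fp, 2L)
  expect_equal(all_treated$fn + all_treated$tn, 0L)
  # boundary risk equal to the threshold counts as treated
  expect_equal(
    classify_cohort(data.frame(risk = 0.5, outcome = 1), 0.5)$tp, 1L
  )
  # vectorised over thresholds, counts always sum to n
  multi <- classify_cohort(toy_cohort(), c(0.05, 0.2, 0.5, 0.95))
  expect_equal(nrow(multi), 4L)
  expect_true(all(multi$tp + multi$fp + multi$fn + multi$tn == multi$n))
})

test_that("expected regrets follow the rescaled formulas", {
  cts <- classify_cohort(toy_cohort(), 0.5)
  erg <- expected_regrets(cts)
  expect_equal(erg$erg_model, 0.25 + 0.25 * 1) # fn/n + fp/n * w, w = 1
  expect_equal(erg$erg_treat_all, 0.5)
  expect_equal(erg$erg_treat_none, 0.5)

  # treat-none regret is the prevalence at every threshold
  prev2 <- data.frame(risk = runif(10), outcome = rep(c(1, 0), c(2, 8)))
  for (pt in c(0.1, 0.33, 0.7)) {
    e <- expected_regrets(classify_cohort(prev2, pt))
    expect_equal(e$erg_treat_none, 0.2)
  }
  expect_equal(
    expected_regrets(classify_cohort(prev2, 0.5))$erg_treat_all,
    0.8 * 1
  )

  # a perfect model accrues no regret below certainty
  for (pt in c(0.01, 0.5, 0.99)) {
    expect_equal(
      expected_regrets(classify_cohort(perfect_cohort(), pt))$erg_model, 0
    )
  }

  expect_error(expected_regrets(classify_cohort(toy_cohort(), 1)), "diverges")
})

test_that("model regret matches the brute-force per-patient oracle", {
  set.seed(101)
  for (i in 1:200) {
    cohort <- random_cohort(sample(1:25, 1))
    pt <- runif(1, 0, 0.95)
    erg <- expected_regrets(classify_cohort(cohort, pt))$erg_model
    expect_equal(erg, brute_force_erg_model(cohort, pt), tolerance = 1e-12)
  }
})

test_that("NERD pairs have the documented values, signs and symmetries", {
  cts <- classify_cohort(toy_cohort(), 0.5)
  expect_equal(nerd_pair(cts, pair = "none_vs_model"), 0)
  expect_equal(nerd_pair(cts, pair = "all_vs_model"), 0)

  # perfect model: none-vs-model equals the prevalence (fp = 0)
  pc <- perfect_cohort(3, 7)
  for (pt in c(0.1, 0.5, 0.9)) {
    expect_equal(
      nerd_pair(classify_cohort(pc, pt), pair = "none_vs_model"), 0.3
    )
  }

  # indifference between treat-all and treat-none when prevalence == Pt
  prev3 <- data.frame(risk = runif(10), outcome = rep(c(1, 0), c(3, 7)))
  expect_equal(
    nerd_pair(classify_cohort(prev3, 0.3), pair = "none_vs_all"), 0,
    tolerance = 1e-12
  )

  # self-comparison is identically zero; reversal negates
  set.seed(33)
  for (i in 1:50) {
    cohort <- random_cohort(sample(2:30, 1))
    cts <- classify_cohort(cohort, runif(1, 0, 0.9))
    expect_identical(nerd_pair(cts, pair = "none_vs_none"), 0)
    expect_identical(
      nerd_pair(cts, pair = "model_vs_none"),
      -nerd_pair(cts, pair = "none_vs_model")
    )
    expect_identical(
      nerd_pair(cts, pair = "model_vs_all"),
      -nerd_pair(cts, pair = "all_vs_model")
    )
  }
})

test_that("NERD additivity holds across random cohorts", {
  set.seed(77)
  for (i in 1:100) {
    cohort <- random_cohort(sample(2:40, 1))
    cts <- classify_cohort(cohort, runif(1, 0, 0.95))
    expect_equal(
      nerd_pair(cts, pair = "none_vs_model") -
        nerd_pair(cts, pair = "none_vs_all"),
      nerd_pair(cts, pair = "all_vs_model"),
      tolerance = 1e-12
    )
  }
})

test_that("net benefit coincides with NERD(treat none, model)", {
  set.seed(13)
  for (i in 1:50) {
    cohort <- random_cohort(sample(2:30, 1))
    cts <- classify_cohort(cohort, runif(1, 0, 0.95))
    expect_equal(
      net_benefit(cts),
      nerd_pair(cts, pair = "none_vs_model"),
      tolerance = 1e-12
    )
  }
  # with no false positives net benefit is the true-positive fraction
  cts0 <- classify_cohort(perfect_cohort(2, 8), 0.5)
  expect_equal(net_benefit(cts0), 0.2)
})

test_that("treat-all regret grows with the threshold; edge cases at Pt = 0", {
  prev2 <- data.frame(risk = runif(20), outcome = rep(c(1, 0), c(4, 16)))
  grid <- seq(0.05, 0.9, by = 0.05)
  erg_all <- expected_regrets(classify_cohort(prev2, grid))$erg_treat_all
  expect_true(all(diff(erg_all) > 0))

  at0 <- expected_regrets(classify_cohort(prev2, 0))
  expect_equal(at0$erg_model, 0)
  expect_equal(at0$erg_treat_all, 0)
  expect_equal(nerd_pair(classify_cohort(prev2, 0), pair = "all_vs_model"), 0)
})
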
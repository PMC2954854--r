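test_that("curve construction follows the threshold sweep", {
  # perfect model: none-vs-model equals the prevalence at every grid point
  curve <- regret_curve(perfect_cohort(3, 7), grid = seq(0.05, 0.95, 0.05))
  expect_equal(curve$nerd_none_model, rep(0.3, nrow(curve)))
  expect_equal(curve$erg_treat_none, rep(0.3, nrow(curve)))

  # single-threshold grid, hand-computed treat-none vs treat-all
  one <- regret_curve(toy_cohort(), grid = 0.25)
  expect_equal(nrow(one), 1L)
  expect_equal(one$nerd_none_all, 0.5 - 0.5 * (1 / 3), tolerance = 1e-12)

  expect_equal(attr(curve, "prevalence"), 0.3)
  expect_error(regret_curve(toy_cohort(), grid = numeric()), "at least one")
  expect_error(regret_curve(toy_cohort(), grid = c(0.1, 1)), "below 1")
  expect_error(regret_curve(toy_cohort(), grid = c(0.5, 0.2)), "increasing")
})

test_that("curve_at recomputes a grid point exactly", {
  cohort <- simulate_cohort(300, seed = 9)
  curve <- regret_curve(cohort, grid = seq(0, 0.9, 0.1))
  pt <- curve_at(cohort, curve$threshold[4])
  expect_equal(
    as.data.frame(pt), as.data.frame(curve[4, ]),
    ignore_attr = TRUE
  )
  expect_error(curve_at(cohort, 1), "certainty")
})

test_that("sign patterns drive strategy selection transitively", {
  # all three NERDs positive: model beats both defaults
  point <- list(
    nerd_none_model = 0.1, nerd_none_all = 0.04, nerd_all_model = 0.06
  )
  sel <- select_strategy(point)
  expect_identical(sel$optimal, "model")
  expect_identical(sel$recommendation, "model")

  # all zero: total indifference, three co-optimal strategies
  flat <- select_strategy(list(
    nerd_none_model = 0, nerd_none_all = 0, nerd_all_model = 0
  ))
  expect_setequal(flat$optimal, c("treat_none", "treat_all", "model"))

  # treat-none wins when both its NERDs are negative
  none <- select_strategy(list(
    nerd_none_model = -0.02, nerd_none_all = -0.4, nerd_all_model = 0.38
  ))
  expect_identical(none$optimal, "treat_none")
})

test_that("a small model advantage inside the budget makes the model superfluous", {
  # model nominally optimal, but its edge over treat-none fits inside rg0
  point <- list(
    nerd_none_model = 0.005, nerd_none_all = -0.3, nerd_all_model = 0.305
  )
  sel <- select_strategy(point, rg0 = 0.01)
  expect_identical(sel$optimal, "model")
  expect_setequal(sel$equivalent_in_regret, c("model", "treat_none"))
  expect_identical(sel$recommendation, "treat_none")
  expect_true(sel$model_superfluous)

  # a zero budget only admits exact ties
  strict <- select_strategy(point, rg0 = 0)
  expect_identical(strict$equivalent_in_regret, "model")
  expect_identical(strict$recommendation, "model")
})

test_that("selection depends only on regret differences", {
  set.seed(21)
  for (i in 1:30) {
    erg <- runif(3, 0, 2) # treat_none, treat_all, model
    shift <- runif(1, -5, 5)
    to_point <- function(e) {
      list(
        nerd_none_model = e[1] - e[3],
        nerd_none_all = e[1] - e[2],
        nerd_all_model = e[2] - e[3]
      )
    }
    a <- select_strategy(to_point(erg))
    b <- select_strategy(to_point(erg + shift))
    expect_identical(a$optimal, b$optimal)
    expect_identical(a$recommendation, b$recommendation)
  }
})

test_that("a perfect model is selected across the interior threshold range", {
  cohort <- perfect_cohort(4, 16)
  for (pt in c(0.05, 0.19, 0.21, 0.5, 0.9)) { # avoid the tie at prevalence
    sel <- select_strategy(curve_at(cohort, pt))
    expect_true("model" %in% sel$optimal)
    if (abs(pt - 0.2) > 1e-6 && pt > 0) {
      expect_identical(sel$optimal, "model")
    }
  }
})

test_that("the full workflow reproduces the biopsy-averse physician's path", {
  # omission 50 / commission 10 -> Pt = 1/6; a discriminating cohort makes
  # the model optimal; patient at 20% risk clears the threshold
  cohort <- simulate_cohort(1000, mode = "two_group", seed = 7)
  d1 <- decide(
    omission = 50, commission = 10, cohort = cohort, patient_risk = 0.20,
    tolerated = 1, denominator = 20, basis = "benefits"
  )
  expect_equal(d1$threshold$threshold, 1 / 6, tolerance = 1e-15)
  expect_identical(d1$strategy$optimal, "model")
  expect_equal(d1$acceptable$rg0, 0.025)
  # every NERD exceeds the budget, so the model stays the recommendation
  expect_identical(d1$strategy_rg$equivalent_in_regret, "model")
  expect_identical(d1$recommendation, "model")
  expect_true(d1$treat)
  expect_equal(d1$comfort$p_treat_none, 0.05)
})

test_that("the full workflow reproduces the biopsy-tolerant physician's path", {
  # omission 70 / commission 60 -> Pt = 6/13; at that threshold the model's
  # small deficit to treat-none sits inside the generous budget rg0 = 0.3
  d2 <- decide(
    omission = 70, commission = 60,
    cohort = physician2_cohort(), patient_risk = 0.20,
    tolerated = 40, denominator = 80, basis = "harms"
  )
  expect_equal(d2$threshold$threshold, 6 / 13, tolerance = 1e-15)
  expect_identical(d2$strategy$optimal, "treat_none")
  expect_equal(d2$acceptable$rg0, 0.3)
  expect_setequal(d2$strategy_rg$equivalent_in_regret, c("treat_none", "model"))
  expect_true(d2$strategy_rg$model_superfluous)
  expect_identical(d2$recommendation, "treat_none")
  expect_false(d2$treat)
  expect_equal(d2$comfort$p_treat_all, 0.5)
})

test_that("a patient risk exactly at the threshold is treated", {
  cohort <- simulate_cohort(1000, mode = "two_group", seed = 7)
  d <- decide(60, 30, cohort = cohort, patient_risk = 1 / 3)
  expect_identical(d$strategy$optimal, "model")
  expect_true(d$treat)
})

test_that("workflow input validation", {
  cohort <- toy_cohort()
  expect_error(decide(50, 10, cohort, patient_risk = 1.5), "\\[0, 1\\]")
  expect_error(
    decide(50, 10, cohort, 0.2, tolerated = 1, denominator = 20),
    "together"
  )
  expect_error(decide(80, 0, cohort, 0.2), "certainty")
})

test_that("the treat-none/treat-all crossover tracks the prevalence", {
  # the root of NERD(treat none, treat all) converges to the prevalence
  for (n in c(500, 5000)) {
    cohort <- simulate_cohort(n, seed = 3)
    curve <- regret_curve(cohort)
    crossing <- curve$threshold[which(diff(sign(curve$nerd_none_all)) < 0)[1]]
    expect_lt(abs(crossing - prevalence(cohort)), 0.011)
  }
})

test_that("tidy and glance summarise curves and decisions", {
  cohort <- simulate_cohort(300, mode = "two_group", seed = 7)
  curve <- regret_curve(cohort, grid = seq(0, 0.9, 0.1))
  long <- tidy(curve)
  expect_named(long, c("threshold", "comparison", "nerd"))
  expect_equal(nrow(long), 3 * nrow(curve))
  expect_setequal(
    unique(long$comparison),
    c("none_vs_model", "none_vs_all", "all_vs_model")
  )
  g <- glance(curve)
  expect_equal(g$n, 300)
  expect_equal(g$grid_size, 10)

  d <- decide(50, 10, cohort, 0.2, tolerated = 1, denominator = 20,
              basis = "benefits")
  td <- tidy(d)
  expect_true(all(c("threshold", "curve_point", "comfort_bounds") %in% td$step))
  gd <- glance(d)
  expect_equal(gd$threshold, 1 / 6)
  expect_identical(gd$recommendation, d$recommendation)
})

test_that("autoplot returns a layered NERD plot", {
  curve <- regret_curve(simulate_cohort(200, seed = 1), grid = seq(0, 0.9, 0.1))
  p <- ggplot2::autoplot(curve, rg0 = 0.02)
  expect_s3_class(p, "ggplot")
  expect_gte(length(p$layers), 3)
})
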
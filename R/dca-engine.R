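#' Regret decision curve over a threshold grid
#'
#' Sweeps a grid of threshold probabilities and, at each, classifies the
#' cohort, computes the expected regret of the three strategies (act on the
#' model, treat all, treat none) and the three pairwise net expected regret
#' differences (NERDs). The resulting curve is the regret analogue of a
#' decision curve: at each threshold the strategy with the lowest expected
#' regret — equivalently, the favourable NERD signs — is the one to act on.
#'
#' @param cohort A data frame accepted by [as_cohort()].
#' @param grid Strictly increasing threshold probabilities in `[0, 1)`.
#'   The default spans 0 to 0.99 in steps of 0.01; 1 is excluded because
#'   the odds weight diverges there.
#' @return A tibble of class `regret_curve` with one row per grid value and
#'   columns `threshold`, `tp`, `fp`, `fn`, `tn`, `n`, `erg_treat_none`,
#'   `erg_treat_all`, `erg_model`, `nerd_none_model`, `nerd_none_all`,
#'   `nerd_all_model`. Cohort size and prevalence are carried as attributes.
#' @examples
#' cohort <- simulate_cohort(200, seed = 42)
#' curve <- regret_curve(cohort)
#' head(curve)
#' @seealso [select_strategy()] to pick a strategy at one threshold,
#'   [ggplot2::autoplot()] for the standard plot.
#' @export
regret_curve <- function(cohort, grid = seq(0, 0.99, by = 0.01)) {
  cohort <- as_cohort(cohort)
  if (length(grid) == 0) {
    stop("`grid` must contain at least one threshold", call. = FALSE)
  }
  check_probability(grid, "grid")
  if (any(grid >= 1)) {
    stop("grid thresholds must be below 1 (odds weight diverges)",
      call. = FALSE
    )
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("`grid` must be strictly increasing", call. = FALSE)
  }
  curve <- curve_points(cohort, grid)
  attr(curve, "n") <- nrow(cohort)
  attr(curve, "prevalence") <- prevalence(cohort)
  class(curve) <- c("regret_curve", class(tibble::tibble()))
  curve
}

#' Evaluate the regret curve at one exact threshold
#'
#' Recomputes a single curve point at an arbitrary threshold (below 1) by
#' exact classification of the cohort — no grid interpolation, so elicited
#' thresholds such as 6/13 are honoured exactly.
#'
#' @inheritParams regret_curve
#' @param threshold A single threshold probability in `[0, 1)`.
#' @return A one-row tibble with the same columns as [regret_curve()].
#' @examples
#' cohort <- simulate_cohort(200, seed = 42)
#' curve_at(cohort, 1 / 6)
#' @export
curve_at <- function(cohort, threshold) {
  cohort <- as_cohort(cohort)
  if (length(threshold) != 1) {
    stop("`threshold` must be a single probability", call. = FALSE)
  }
  check_probability(threshold, "threshold")
  if (threshold >= 1 - 1e-9) {
    stop(
      "threshold is effectively 1: expected regrets are undefined ",
      "(treatment justified only at certainty of disease)",
      call. = FALSE
    )
  }
  curve_points(cohort, threshold)
}

# shared classify + regret arithmetic for a set of thresholds
curve_points <- function(cohort, thresholds) {
  counts <- classify_cohort(cohort, thresholds)
  counts <- expected_regrets(counts)
  dplyr::mutate(
    counts,
    nerd_none_model = nerd_pair(counts, pair = "none_vs_model"),
    nerd_none_all = nerd_pair(counts, pair = "none_vs_all"),
    nerd_all_model = nerd_pair(counts, pair = "all_vs_model")
  )
}

#' Select the optimal strategy at a curve point
#'
#' Orders the three strategies by the signs of their pairwise NERDs (a
#' positive NERD favours the second-named strategy of the pair) and returns
#' the transitive optimum. Ties within a numeric tolerance produce multiple
#' co-optimal strategies. When an acceptable-regret budget `rg0` is given,
#' any strategy whose absolute NERD against an optimal strategy is within
#' the budget is marked *equivalent in regret*, and the recommendation
#' becomes the least burdensome equivalent strategy (treat none over treat
#' all over model — a model whose advantage fits inside the budget is
#' superfluous effort).
#'
#' @param point A one-row data frame holding `nerd_none_model`,
#'   `nerd_none_all` and `nerd_all_model` — typically a row of a
#'   [regret_curve()] or the output of [curve_at()].
#' @param rg0 Optional acceptable-regret budget (non-negative), e.g. the
#'   `rg0` column of [acceptable_regret()].
#' @param tol Absolute tolerance separating algebraic ties from
#'   floating-point noise. Default `1e-12`.
#' @return An object of class `strategy_decision`: a list with elements
#'   `optimal` (character vector), `equivalent_in_regret`, `recommendation`,
#'   `model_superfluous` (logical), `comparisons` (tibble of the three
#'   pairwise NERDs with their preferred strategy) and `rg0`.
#' @examples
#' cohort <- simulate_cohort(500, seed = 42)
#' select_strategy(curve_at(cohort, 0.2))
#' select_strategy(curve_at(cohort, 0.2), rg0 = 0.01)
#' @export
select_strategy <- function(point, rg0 = NULL, tol = 1e-12) {
  point <- as.list(point)
  needed <- c("nerd_none_model", "nerd_none_all", "nerd_all_model")
  if (!all(needed %in% names(point))) {
    stop(
      "`point` must contain ", paste(needed, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(lengths(point[needed]) != 1)) {
    stop("`point` must be a single curve point (one row)", call. = FALSE)
  }
  if (!is.null(rg0)) {
    if (!is.numeric(rg0) || length(rg0) != 1 || is.na(rg0) || rg0 < 0) {
      stop("`rg0` must be a single non-negative number", call. = FALSE)
    }
  }
  nerd_nm <- point$nerd_none_model
  nerd_na <- point$nerd_none_all
  nerd_am <- point$nerd_all_model

  # expected regrets relative to treat-none (constant shifts cancel)
  erg <- c(
    treat_none = 0,
    treat_all = -nerd_na,
    model = -nerd_nm
  )
  optimal <- names(erg)[erg <= min(erg) + tol]

  comparisons <- tibble::tibble(
    pair = c(
      "treat_none vs model", "treat_none vs treat_all",
      "treat_all vs model"
    ),
    nerd = c(nerd_nm, nerd_na, nerd_am),
    preferred = c(
      tie_label(nerd_nm, "treat_none", "model", tol),
      tie_label(nerd_na, "treat_none", "treat_all", tol),
      tie_label(nerd_am, "treat_all", "model", tol)
    )
  )

  equivalent <- optimal
  if (!is.null(rg0)) {
    gap <- vapply(erg, function(e) min(abs(e - erg[optimal])), numeric(1))
    equivalent <- names(erg)[gap <= rg0 + tol]
  }
  preference <- c("treat_none", "treat_all", "model")
  recommendation <- preference[preference %in% equivalent][1]

  structure(
    list(
      optimal = optimal,
      equivalent_in_regret = equivalent,
      recommendation = recommendation,
      model_superfluous = "model" %in% equivalent &&
        recommendation != "model",
      comparisons = comparisons,
      rg0 = rg0,
      tol = tol
    ),
    class = "strategy_decision"
  )
}

tie_label <- function(nerd, first, second, tol) {
  if (abs(nerd) <= tol) "indifferent" else if (nerd > 0) second else first
}

#' @export
print.strategy_decision <- function(x, ...) {
  cat("Strategy comparison (positive NERD favours the second strategy)\n")
  for (i in seq_len(nrow(x$comparisons))) {
    cat(sprintf(
      "  NERD[%s] = %+.4g  -> %s\n",
      x$comparisons$pair[i], x$comparisons$nerd[i],
      x$comparisons$preferred[i]
    ))
  }
  cat("Optimal strategy:", paste(x$optimal, collapse = ", "), "\n")
  if (!is.null(x$rg0)) {
    cat(sprintf(
      "Equivalent in regret (|NERD| <= rg0 = %g): %s\n",
      x$rg0, paste(x$equivalent_in_regret, collapse = ", ")
    ))
    if (x$model_superfluous) {
      cat("The prediction model is superfluous at this budget.\n")
    }
  }
  cat("Recommendation:", x$recommendation, "\n")
  invisible(x)
}

#' Full regret-based decision workflow for one patient
#'
#' Runs the complete decision process: (1) elicit the threshold probability
#' from the dual regret ratings; (2) evaluate the regret curve at that exact
#' threshold and select the optimal strategy; (3) if acting on the model,
#' compare the patient's predicted risk against the threshold (treat when
#' `patient_risk >= threshold`); (4) if an acceptable-regret scenario answer
#' is supplied, convert it to a budget and re-assess which strategies are
#' equivalent in regret; (5) derive the comfort-bound probabilities. Every
#' intermediate quantity is kept in the returned report.
#'
#' @inheritParams threshold_from_regrets
#' @param cohort A data frame accepted by [as_cohort()]: the validation
#'   cohort of model-predicted risks and observed outcomes on which the
#'   strategies are compared.
#' @param patient_risk The current patient's model-predicted disease
#'   probability in `[0, 1]`.
#' @param tolerated,denominator,basis Optional acceptable-regret scenario
#'   answer, passed to [acceptable_regret()]; the matching VAS rating
#'   (omission for `basis = "benefits"`, commission for `"harms"`) is taken
#'   from the assessment. All three must be supplied together.
#' @param scale Acceptable-regret budget convention; see
#'   [acceptable_regret()].
#' @return An object of class `regret_decision`: a list with elements
#'   `assessment`, `threshold` (tibble from [threshold_from_regrets()]),
#'   `point` (the exact curve point), `strategy` (the
#'   [select_strategy()] result without a budget), `acceptable` (tibble or
#'   `NULL`), `strategy_rg` (the re-assessment under the budget, or `NULL`),
#'   `comfort` (tibble or `NULL`), `recommendation`, `treat` (logical:
#'   should this patient be treated under the recommended strategy) and
#'   `patient_risk`.
#' @examples
#' cohort <- simulate_cohort(1000, mode = "two_group", seed = 7)
#' decide(
#'   omission = 50, commission = 10,
#'   cohort = cohort, patient_risk = 0.20,
#'   tolerated = 1, denominator = 20, basis = "benefits"
#' )
#' @export
decide <- function(omission, commission, cohort, patient_risk,
                   tolerated = NULL, denominator = NULL, basis = NULL,
                   scale = c("literal", "normalized")) {
  scale <- match.arg(scale)
  threshold <- threshold_from_regrets(omission, commission)
  if (nrow(threshold) != 1) {
    stop("`decide()` handles one assessment at a time", call. = FALSE)
  }
  check_probability(patient_risk, "patient_risk")
  if (length(patient_risk) != 1) {
    stop("`patient_risk` must be a single probability", call. = FALSE)
  }
  pt <- threshold$threshold
  if (pt >= 1 - 1e-9) {
    stop(
      "the elicited threshold is 1 (no regret of commission): treatment ",
      "is justified only at certainty of disease, and the regret curve ",
      "is undefined there",
      call. = FALSE
    )
  }

  point <- curve_at(cohort, pt)
  strategy <- select_strategy(point)

  scenario <- list(tolerated = tolerated, denominator = denominator,
                   basis = basis)
  supplied <- !vapply(scenario, is.null, logical(1))
  if (any(supplied) && !all(supplied)) {
    stop(
      "supply `tolerated`, `denominator` and `basis` together ",
      "(or none of them)",
      call. = FALSE
    )
  }

  acceptable <- NULL
  strategy_rg <- NULL
  comfort <- NULL
  if (all(supplied)) {
    rating <- if (basis == "benefits") threshold$omission else
      threshold$commission
    acceptable <- acceptable_regret(
      tolerated, denominator,
      rating = rating, basis = basis, scale = scale
    )
    strategy_rg <- select_strategy(point, rg0 = acceptable$rg0)
    comfort <- if (basis == "benefits") {
      comfort_bounds(r_b = acceptable$r)
    } else {
      comfort_bounds(r_h = acceptable$r)
    }
  }

  final <- if (is.null(strategy_rg)) strategy else strategy_rg
  treat <- switch(final$recommendation,
    treat_all = TRUE,
    treat_none = FALSE,
    model = patient_risk >= pt
  )

  structure(
    list(
      assessment = threshold[, c("omission", "commission")],
      threshold = threshold,
      point = point,
      strategy = strategy,
      acceptable = acceptable,
      strategy_rg = strategy_rg,
      comfort = comfort,
      recommendation = final$recommendation,
      treat = treat,
      patient_risk = patient_risk
    ),
    class = "regret_decision"
  )
}

#' @export
print.regret_decision <- function(x, ...) {
  cat(format_report_text(x), sep = "\n")
  invisible(x)
}
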
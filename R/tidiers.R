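#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a regret curve into long format
#'
#' Pivots the three NERD series into one row per (threshold, comparison),
#' the shape wanted for faceting or plotting by hand.
#'
#' @param x A [regret_curve()] object.
#' @param ... Unused.
#' @return A tibble with columns `threshold`, `comparison` (one of
#'   `none_vs_model`, `none_vs_all`, `all_vs_model`) and `nerd`.
#' @method tidy regret_curve
#' @export
tidy.regret_curve <- function(x, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(x)[, c(
      "threshold", "nerd_none_model", "nerd_none_all", "nerd_all_model"
    )],
    cols = -"threshold",
    names_to = "comparison",
    names_prefix = "nerd_",
    values_to = "nerd"
  )
  long$comparison <- sub("none_model", "none_vs_model", long$comparison)
  long$comparison <- sub("none_all", "none_vs_all", long$comparison)
  long$comparison <- sub("all_model", "all_vs_model", long$comparison)
  long
}

#' One-row summary of a regret curve
#'
#' @param x A [regret_curve()] object.
#' @param ... Unused.
#' @return A one-row tibble with the cohort size, prevalence, grid extent
#'   and the threshold band (if any) where the model strategy is strictly
#'   optimal on the grid.
#' @method glance regret_curve
#' @export
glance.regret_curve <- function(x, ...) {
  model_opt <- x$nerd_none_model > 0 & x$nerd_all_model > 0
  tibble::tibble(
    n = attr(x, "n"),
    prevalence = attr(x, "prevalence"),
    grid_size = nrow(x),
    grid_min = min(x$threshold),
    grid_max = max(x$threshold),
    model_optimal_from = if (any(model_opt)) {
      min(x$threshold[model_opt])
    } else {
      NA_real_
    },
    model_optimal_to = if (any(model_opt)) {
      max(x$threshold[model_opt])
    } else {
      NA_real_
    }
  )
}

#' Tidy a decision report
#'
#' @param x A `regret_decision` object from [decide()].
#' @param ... Unused.
#' @return A tibble of the report's intermediate quantities, one per row,
#'   with columns `step`, `quantity` and `value`.
#' @method tidy regret_decision
#' @export
tidy.regret_decision <- function(x, ...) {
  rows <- list(
    tibble::tibble(
      step = "threshold",
      quantity = c("omission", "commission", "threshold", "weight"),
      value = c(
        x$assessment$omission, x$assessment$commission,
        x$threshold$threshold, x$threshold$weight
      )
    ),
    tibble::tibble(
      step = "curve_point",
      quantity = c(
        "erg_treat_none", "erg_treat_all", "erg_model",
        "nerd_none_model", "nerd_none_all", "nerd_all_model"
      ),
      value = c(
        x$point$erg_treat_none, x$point$erg_treat_all, x$point$erg_model,
        x$point$nerd_none_model, x$point$nerd_none_all, x$point$nerd_all_model
      )
    ),
    tibble::tibble(
      step = "patient",
      quantity = "patient_risk",
      value = x$patient_risk
    )
  )
  if (!is.null(x$acceptable)) {
    rows <- c(rows, list(tibble::tibble(
      step = "acceptable_regret",
      quantity = c("r", "rg0"),
      value = c(x$acceptable$r, x$acceptable$rg0)
    )))
  }
  if (!is.null(x$comfort)) {
    rows <- c(rows, list(tibble::tibble(
      step = "comfort_bounds",
      quantity = c("p_treat_none", "p_treat_all"),
      value = c(x$comfort$p_treat_none, x$comfort$p_treat_all)
    )))
  }
  dplyr::bind_rows(rows)
}

#' One-row summary of a decision report
#'
#' @param x A `regret_decision` object from [decide()].
#' @param ... Unused.
#' @return A one-row tibble: threshold, optimal strategy (collapsed with
#'   `+` when tied), acceptable-regret budget, final recommendation and
#'   the treat/no-treat call for the patient.
#' @method glance regret_decision
#' @export
glance.regret_decision <- function(x, ...) {
  tibble::tibble(
    threshold = x$threshold$threshold,
    optimal = paste(x$strategy$optimal, collapse = "+"),
    rg0 = if (is.null(x$acceptable)) NA_real_ else x$acceptable$rg0,
    recommendation = x$recommendation,
    treat = x$treat,
    patient_risk = x$patient_risk
  )
}
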
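#' Treatment threshold probability from dual regret ratings
#'
#' Converts a pair of visual-analog-scale (VAS) regret ratings into the
#' threshold probability at which the decision maker is indifferent between
#' treating and not treating. The omission rating measures anticipated regret
#' from failing to give needed treatment (the foregone benefit of treatment);
#' the commission rating measures regret from giving unnecessary treatment
#' (the harm incurred). The threshold is
#' \deqn{P_t = \frac{1}{1 + \mathrm{omission}/\mathrm{commission}},}
#' so a physician who rates omission twice as regrettable as commission is
#' indifferent at a disease probability of 1/3. When the commission rating is
#' zero there is no regret attached to unnecessary treatment and treatment is
#' justified only at certainty of disease: the threshold is exactly 1 and its
#' odds weight is infinite.
#'
#' @param omission Regret-of-omission rating(s) on the 0-100 VAS.
#' @param commission Regret-of-commission rating(s) on the 0-100 VAS.
#'   Recycled against `omission` if either has length 1.
#'
#' @return A tibble with one row per assessment and columns `omission`,
#'   `commission`, `threshold` (the probability \eqn{P_t}) and `weight`
#'   (the threshold odds \eqn{P_t/(1-P_t)}, `Inf` when `threshold == 1`).
#'
#' @examples
#' threshold_from_regrets(60, 30)      # indifferent at p = 1/3
#' threshold_from_regrets(
#'   omission   = c(50, 70),
#'   commission = c(10, 60)
#' )
#' @export
threshold_from_regrets <- function(omission, commission) {
  check_vas(omission, "omission")
  check_vas(commission, "commission")
  both <- vctrs_recycle(omission, commission)
  omission <- both[[1]]
  commission <- both[[2]]
  if (any(omission == 0 & commission == 0)) {
    stop(
      "both regret ratings are zero: total indifference cannot define ",
      "a treatment threshold",
      call. = FALSE
    )
  }
  threshold <- ifelse(commission == 0, 1, commission / (omission + commission))
  tibble::tibble(
    omission = as.numeric(omission),
    commission = as.numeric(commission),
    threshold = as.numeric(threshold),
    weight = threshold_weight(threshold)
  )
}

#' Threshold odds weight
#'
#' The odds form \eqn{P_t/(1 - P_t)} of a threshold probability, the factor
#' by which a false positive is down-weighted relative to a false negative in
#' every expected-regret and net-benefit formula. Returns `Inf` at
#' `threshold == 1`.
#'
#' @param threshold Threshold probability (or probabilities) in `[0, 1]`.
#' @return Numeric vector of odds; `Inf` where `threshold == 1`.
#' @examples
#' threshold_weight(c(0, 0.5, 1 / 3, 1))
#' @export
threshold_weight <- function(threshold) {
  check_probability(threshold, "threshold")
  ifelse(threshold == 1, Inf, threshold / (1 - threshold))
}

#' Acceptable-regret budget from a scenario answer
#'
#' Translates the answer to an acceptable-regret scenario question ("out of
#' these patients, how many wrong decisions would you tolerate?") into the
#' tolerated-error fraction `r` and the regret budget `rg0`. For
#' `basis = "benefits"` the fraction is \eqn{r_b}, the share of treatment
#' benefit the decision maker will forgo when wrongly withholding treatment;
#' for `basis = "harms"` it is \eqn{r_h}, the share of treatment harm
#' tolerated when wrongly treating. The matching VAS rating (omission for
#' benefits, commission for harms) supplies the utility scale.
#'
#' Two conventions for the budget are supported. The default `"literal"`
#' scale multiplies the fraction by the rating rescaled to `[0, 1]`,
#' `rg0 = r * rating / 100`. The `"normalized"` scale sets `rg0 = r`, which
#' keeps the budget in the same rescaled units as the NERD curves (where the
#' omission regret is the unit); see the package vignette for the trade-off.
#'
#' @param tolerated Integer count of tolerated wrong decisions.
#' @param denominator Integer count of patients in the scenario arm
#'   (must be positive).
#' @param rating The matching 0-100 VAS rating: the omission rating when
#'   `basis = "benefits"`, the commission rating when `basis = "harms"`.
#' @param basis `"benefits"` or `"harms"`.
#' @param scale Budget convention, `"literal"` (default) or `"normalized"`.
#'
#' @return A one-row tibble with columns `basis`, `tolerated`, `denominator`,
#'   `r`, `rating` and `rg0`.
#' @examples
#' # tolerate missing 1 of 20 needed biopsies, omission rating 50
#' acceptable_regret(1, 20, rating = 50, basis = "benefits")
#' # tolerate 40 of 80 unnecessary biopsies, commission rating 60
#' acceptable_regret(40, 80, rating = 60, basis = "harms")
#' @export
acceptable_regret <- function(tolerated, denominator, rating, basis,
                              scale = c("literal", "normalized")) {
  basis <- match.arg(basis, c("benefits", "harms"))
  scale <- match.arg(scale)
  if (!is.numeric(tolerated) || !is.numeric(denominator) ||
      length(tolerated) != 1 || length(denominator) != 1) {
    stop("`tolerated` and `denominator` must be single counts", call. = FALSE)
  }
  if (denominator <= 0) {
    stop("`denominator` must be a positive count", call. = FALSE)
  }
  if (tolerated < 0 || tolerated > denominator) {
    stop(
      "`tolerated` must lie between 0 and `denominator` (",
      denominator, ")",
      call. = FALSE
    )
  }
  check_vas(rating, "rating")
  r <- tolerated / denominator
  rg0 <- switch(scale,
    literal = r * rating / 100,
    normalized = r
  )
  tibble::tibble(
    basis = basis,
    tolerated = as.numeric(tolerated),
    denominator = as.numeric(denominator),
    r = r,
    rating = as.numeric(rating),
    rg0 = rg0
  )
}

#' Scenario arm sizes for acceptable-regret questions
#'
#' Splits a hypothetical cohort of patients who all share the current
#' patient's disease probability into the number who truly need treatment
#' and the number who do not, for phrasing the acceptable-regret scenario
#' ("Out of the N patients who should (not) be treated, how many ...?").
#' The diseased arm is rounded half up.
#'
#' @param cohort_size Number of patients in the hypothetical cohort.
#' @param disease_probability Shared disease probability in `[0, 1]`.
#' @return A one-row tibble with columns `should_treat` and
#'   `should_not_treat`.
#' @examples
#' scenario_arm_sizes(100, 0.2) # 20 need treatment, 80 do not
#' @export
scenario_arm_sizes <- function(cohort_size, disease_probability) {
  if (!is.numeric(cohort_size) || length(cohort_size) != 1 ||
      cohort_size <= 0 || cohort_size != trunc(cohort_size)) {
    stop("`cohort_size` must be a single positive integer", call. = FALSE)
  }
  check_probability(disease_probability, "disease_probability")
  should_treat <- floor(cohort_size * disease_probability + 0.5)
  tibble::tibble(
    should_treat = should_treat,
    should_not_treat = cohort_size - should_treat
  )
}

#' Comfort-bound probabilities from tolerated-error fractions
#'
#' The prognostic probabilities beyond which a possibly wrong commitment is
#' tolerable: below `p_treat_none = r_b` the decision maker comfortably
#' withholds treatment even though it might have helped, and above
#' `p_treat_all = 1 - r_h` they comfortably treat even though treatment might
#' prove unnecessary. Either fraction may be omitted, in which case the
#' corresponding bound is `NA`.
#'
#' @param r_b Tolerated fraction of foregone benefits in `[0, 1]`, or `NULL`.
#' @param r_h Tolerated fraction of incurred harms in `[0, 1]`, or `NULL`.
#' @return A one-row tibble with columns `p_treat_none` and `p_treat_all`.
#' @examples
#' comfort_bounds(r_b = 0.05)          # withhold comfortably below 5%
#' comfort_bounds(r_h = 0.5)           # treat comfortably above 50%
#' comfort_bounds(r_b = 0, r_h = 0)    # no tolerance for either error
#' @export
comfort_bounds <- function(r_b = NULL, r_h = NULL) {
  if (is.null(r_b) && is.null(r_h)) {
    stop("provide at least one of `r_b`, `r_h`", call. = FALSE)
  }
  if (!is.null(r_b)) check_probability(r_b, "r_b")
  if (!is.null(r_h)) check_probability(r_h, "r_h")
  tibble::tibble(
    p_treat_none = if (is.null(r_b)) NA_real_ else as.numeric(r_b),
    p_treat_all = if (is.null(r_h)) NA_real_ else 1 - as.numeric(r_h)
  )
}

#' Truncated whole-percent formatting
#'
#' Reports a probability as a whole percent with the fractional part
#' truncated (1/6 prints as 16%, 1/3 as 33%), the convention used when
#' reading thresholds back to a decision maker. A small epsilon guards
#' against floating-point representations such as `0.29 * 100 == 28.999...`
#' being truncated one point low.
#'
#' @param p Probability (or probabilities) in `[0, 1]`.
#' @param label If `TRUE` (default) return strings with a `%` suffix,
#'   otherwise the integer percents.
#' @return Character or integer vector of truncated whole percents.
#' @examples
#' percent_trunc(c(1 / 6, 1 / 3, 6 / 13))
#' percent_trunc(0.05, label = FALSE)
#' @export
percent_trunc <- function(p, label = TRUE) {
  check_probability(p, "p")
  pct <- as.integer(floor(p * 100 + 1e-9))
  if (label) paste0(pct, "%") else pct
}

# --- internal validation helpers -------------------------------------------

check_vas <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0 || anyNA(x)) {
    stop("`", name, "` must be numeric with no missing values", call. = FALSE)
  }
  if (any(x < 0 | x > 100)) {
    stop("`", name, "` must lie on the 0-100 rating scale", call. = FALSE)
  }
  invisible(x)
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0 || anyNA(x)) {
    stop("`", name, "` must be numeric with no missing values", call. = FALSE)
  }
  if (any(x < 0 | x > 1)) {
    stop("`", name, "` must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

# length-1 recycling for paired rating vectors
vctrs_recycle <- function(x, y) {
  if (length(x) == length(y)) return(list(x, y))
  if (length(x) == 1) return(list(rep(x, length(y)), y))
  if (length(y) == 1) return(list(x, rep(y, length(x))))
  stop("rating vectors must have equal length (or length 1)", call. = FALSE)
}
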
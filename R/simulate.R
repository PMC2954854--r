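#' Simulate a cohort of predicted risks and outcomes
#'
#' Generates synthetic cohorts that stand in for a clinical risk model
#' evaluated on a patient series, with controllable prevalence,
#' discrimination and calibration.
#'
#' Two generating modes are available:
#' \describe{
#'   \item{`calibrated`}{Each patient's true risk is drawn from
#'     `Beta(a, b)` and the outcome from `Bernoulli(true risk)`; the
#'     reported risk equals the true risk, so the model is perfectly
#'     calibrated by construction. Defaults `a = 2, b = 8` give a mean
#'     risk (hence prevalence) of 0.2, the disease frequency of the
#'     package's running prostate-biopsy example.}
#'   \item{`two_group`}{Outcomes are drawn first as
#'     `Bernoulli(prevalence)`; risks then come from group-specific Beta
#'     distributions — `Beta(a1, b1)` for diseased, `Beta(a0, b0)` for
#'     non-diseased patients. Defaults (`Beta(3, 3)` vs `Beta(1.5, 6)`)
#'     give the moderate discrimination typical of clinical prediction
#'     models.}
#' }
#'
#' Optional miscalibration distorts the *reported* risk only (never the
#' outcome mechanism) on the log-odds scale:
#' `logit(reported) = shift + slope * logit(true)`. Risks are clipped to
#' `[1e-9, 1 - 1e-9]` before the transform so it is always defined.
#'
#' Risks and outcomes are drawn from two RNG streams derived from `seed`,
#' so cohorts generated with the same seed share a common prefix when only
#' `n` changes.
#'
#' @param n Cohort size (positive integer).
#' @param mode `"calibrated"` or `"two_group"`.
#' @param a,b Beta shape parameters of the risk distribution
#'   (calibrated mode).
#' @param prevalence Disease probability (two-group mode).
#' @param a1,b1 Beta shape parameters for diseased patients (two-group).
#' @param a0,b0 Beta shape parameters for non-diseased patients (two-group).
#' @param miscalibration Optional numeric vector `c(shift, slope)` applied
#'   to reported risks on the log-odds scale; `NULL` (default) reports the
#'   true risks unchanged.
#' @param seed Integer seed; fully determines the cohort.
#' @return A [as_cohort()] tibble with columns `id`, `risk` (reported),
#'   `outcome`, and `true_risk` (the risk that generated the outcome in
#'   calibrated mode, or the undistorted group draw in two-group mode).
#' @examples
#' simulate_cohort(5, seed = 1)
#' simulate_cohort(5, mode = "two_group", prevalence = 0.3, seed = 1)
#' simulate_cohort(5, miscalibration = c(0.5, 1), seed = 1)
#' @export
simulate_cohort <- function(n,
                            mode = c("calibrated", "two_group"),
                            a = 2, b = 8,
                            prevalence = 0.2,
                            a1 = 3, b1 = 3,
                            a0 = 1.5, b0 = 6,
                            miscalibration = NULL,
                            seed = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != trunc(n)) {
    stop("`n` must be a single positive integer", call. = FALSE)
  }
  for (par in c("a", "b", "a1", "b1", "a0", "b0")) {
    val <- get(par)
    if (!is.numeric(val) || length(val) != 1 || val <= 0) {
      stop("`", par, "` must be a single positive number", call. = FALSE)
    }
  }
  check_probability(prevalence, "prevalence")
  if (!is.null(miscalibration) &&
      (!is.numeric(miscalibration) || length(miscalibration) != 2 ||
       anyNA(miscalibration))) {
    stop("`miscalibration` must be c(shift, slope)", call. = FALSE)
  }
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1)
  }

  if (mode == "calibrated") {
    true_risk <- with_stream(seed, "risks", stats::rbeta(n, a, b))
    u <- with_stream(seed, "outcomes", stats::runif(n))
    outcome <- as.numeric(u < true_risk)
  } else {
    u <- with_stream(seed, "outcomes", stats::runif(n))
    outcome <- as.numeric(u < prevalence)
    shape1 <- ifelse(outcome == 1, a1, a0)
    shape2 <- ifelse(outcome == 1, b1, b0)
    true_risk <- with_stream(seed, "risks", stats::rbeta(n, shape1, shape2))
  }

  risk <- clip_risk(true_risk)
  if (!is.null(miscalibration)) {
    risk <- stats::plogis(
      miscalibration[1] + miscalibration[2] * stats::qlogis(risk)
    )
  }

  as_cohort(tibble::tibble(
    id = seq_len(n),
    risk = risk,
    outcome = outcome,
    true_risk = true_risk
  ))
}

clip_risk <- function(x) pmin(pmax(x, 1e-9), 1 - 1e-9)

# named RNG stream: deterministic sub-seed per purpose, restores RNG state
with_stream <- function(seed, stream, expr) {
  offset <- c(risks = 1013L, outcomes = 7919L)[[stream]]
  sub_seed <- (as.integer(seed) %% 1000000000L) * 2L + offset
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(sub_seed)
  expr
}
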
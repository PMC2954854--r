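#' Validate a cohort of predicted risks and observed outcomes
#'
#' Coerces a data frame to the cohort format used throughout the package:
#' one row per patient with a predicted disease probability (`risk`) and a
#' binary observed disease status (`outcome`). An `id` column is added when
#' absent. Extra columns are preserved.
#'
#' @param data A data frame with numeric `risk` in `[0, 1]` and `outcome`
#'   in `{0, 1}`.
#' @return A tibble of class `cohort`.
#' @examples
#' as_cohort(data.frame(risk = c(0.9, 0.6, 0.3, 0.1), outcome = c(1, 0, 1, 0)))
#' @export
as_cohort <- function(data) {
  if (!is.data.frame(data)) {
    stop("`data` must be a data frame", call. = FALSE)
  }
  missing_cols <- setdiff(c("risk", "outcome"), names(data))
  if (length(missing_cols) > 0) {
    stop(
      "cohort is missing column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(data) == 0) {
    stop("cohort has no patients", call. = FALSE)
  }
  if (!is.numeric(data$risk) || anyNA(data$risk) ||
      any(data$risk < 0 | data$risk > 1)) {
    bad <- which(!is.finite(data$risk) | data$risk < 0 | data$risk > 1)
    stop(
      "`risk` must lie in [0, 1]; offending row(s): ",
      paste(utils::head(bad, 5), collapse = ", "),
      call. = FALSE
    )
  }
  if (anyNA(data$outcome) || !all(data$outcome %in% c(0, 1))) {
    bad <- which(!(data$outcome %in% c(0, 1)))
    stop(
      "`outcome` must be 0 or 1; offending row(s): ",
      paste(utils::head(bad, 5), collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::as_tibble(data)
  out$outcome <- as.numeric(out$outcome)
  if (!"id" %in% names(out)) {
    out <- tibble::add_column(out, id = seq_len(nrow(out)), .before = 1)
  }
  class(out) <- c("cohort", class(tibble::tibble()))
  out
}

#' Cohort prevalence
#'
#' The fraction of patients with `outcome == 1`, used as the plug-in
#' estimate of the marginal disease probability.
#'
#' @param cohort A data frame accepted by [as_cohort()].
#' @return A single number in `[0, 1]`.
#' @export
prevalence <- function(cohort) {
  cohort <- as_cohort(cohort)
  mean(cohort$outcome)
}

#' Classify a cohort at one or more treatment thresholds
#'
#' Applies the rule "treat if predicted risk >= threshold" and tallies the
#' resulting confusion counts. Boundary risks equal to the threshold are
#' treated. The counts are the plug-in estimators of the joint
#' classification probabilities: `tp/n` estimates
#' \eqn{P(p \ge P_t \cap D^+)}, `fp/n` estimates
#' \eqn{P(p \ge P_t \cap D^-)}, and so on.
#'
#' @param cohort A data frame accepted by [as_cohort()].
#' @param threshold Threshold probability (or vector of them) in `[0, 1]`.
#' @return A tibble with one row per threshold and columns `threshold`,
#'   `tp`, `fp`, `fn`, `tn`, `n`.
#' @examples
#' toy <- data.frame(risk = c(0.9, 0.6, 0.3, 0.1), outcome = c(1, 0, 1, 0))
#' classify_cohort(toy, 0.5)
#' @export
classify_cohort <- function(cohort, threshold) {
  cohort <- as_cohort(cohort)
  check_probability(threshold, "threshold")
  purrr::map_dfr(threshold, function(t) {
    treat <- cohort$risk >= t
    diseased <- cohort$outcome == 1
    tibble::tibble(
      threshold = t,
      tp = sum(treat & diseased),
      fp = sum(treat & !diseased),
      fn = sum(!treat & diseased),
      tn = sum(!treat & !diseased),
      n = nrow(cohort)
    )
  })
}

#' Expected regret of the three strategies
#'
#' Computes, in rescaled units where the regret of omission equals 1, the
#' expected regret of acting on the model, treating everyone, and treating
#' no one. With `w` the threshold odds `Pt/(1 - Pt)` and `p` the prevalence:
#' \deqn{ERg[\mathrm{model}] = \mathrm{fn}/n + (\mathrm{fp}/n)\,w}
#' \deqn{ERg[\mathrm{treat\ all}] = (1 - p)\,w}
#' \deqn{ERg[\mathrm{treat\ none}] = p}
#' The treat-none regret is the prevalence itself, independent of the
#' threshold. Regrets on the original VAS scale are recovered by
#' multiplying by (omission rating / 100).
#'
#' @param counts A confusion-count tibble from [classify_cohort()] (columns
#'   `threshold`, `tp`, `fp`, `fn`, `tn`, `n`).
#' @param threshold Optional threshold override; defaults to
#'   `counts$threshold`. Must be below 1 (at a threshold of 1 the odds
#'   weight diverges and expected regrets are undefined).
#' @return `counts` with columns `erg_model`, `erg_treat_all`,
#'   `erg_treat_none` appended.
#' @examples
#' toy <- data.frame(risk = c(0.9, 0.6, 0.3, 0.1), outcome = c(1, 0, 1, 0))
#' expected_regrets(classify_cohort(toy, 0.5))
#' @export
expected_regrets <- function(counts, threshold = NULL) {
  counts <- check_counts(counts, threshold)
  w <- threshold_weight(counts$threshold)
  p <- (counts$tp + counts$fn) / counts$n
  dplyr::mutate(
    counts,
    erg_model = .data$fn / .data$n + (.data$fp / .data$n) * w,
    erg_treat_all = (1 - p) * w,
    erg_treat_none = p
  )
}

#' Net expected regret difference between two strategies
#'
#' The signed gap in expected regret between a pair of strategies at the
#' threshold(s) in `counts`. A positive value means the second-named
#' strategy of the pair inflicts less regret and is preferred; a negative
#' value favours the first; zero is indifference. With `w = Pt/(1 - Pt)`
#' and `p` the prevalence, the three canonical pairs are
#' \deqn{NERD[\mathrm{none, model}] = \mathrm{tp}/n - (\mathrm{fp}/n)\,w}
#' \deqn{NERD[\mathrm{none, all}] = p - (1 - p)\,w}
#' \deqn{NERD[\mathrm{all, model}] = (\mathrm{tn}/n)\,w - \mathrm{fn}/n}
#' Reversed pair names (e.g. `"model_vs_none"`) negate the value, and a
#' strategy compared with itself gives identically 0.
#'
#' @inheritParams expected_regrets
#' @param pair Pair name: one of `"none_vs_model"`, `"none_vs_all"`,
#'   `"all_vs_model"`, their reversals, or a self-pair such as
#'   `"none_vs_none"`.
#' @return Numeric vector, one value per row of `counts`.
#' @examples
#' toy <- data.frame(risk = c(0.9, 0.6, 0.3, 0.1), outcome = c(1, 0, 1, 0))
#' cts <- classify_cohort(toy, 0.25)
#' nerd_pair(cts, pair = "none_vs_all")
#' @export
nerd_pair <- function(counts, threshold = NULL,
                      pair = c(
                        "none_vs_model", "none_vs_all", "all_vs_model",
                        "model_vs_none", "all_vs_none", "model_vs_all",
                        "none_vs_none", "all_vs_all", "model_vs_model"
                      )) {
  pair <- match.arg(pair)
  counts <- check_counts(counts, threshold)
  w <- threshold_weight(counts$threshold)
  p <- (counts$tp + counts$fn) / counts$n
  switch(pair,
    none_vs_model = counts$tp / counts$n - (counts$fp / counts$n) * w,
    none_vs_all = p - (1 - p) * w,
    all_vs_model = (counts$tn / counts$n) * w - counts$fn / counts$n,
    model_vs_none = -(counts$tp / counts$n - (counts$fp / counts$n) * w),
    all_vs_none = -(p - (1 - p) * w),
    model_vs_all = -((counts$tn / counts$n) * w - counts$fn / counts$n),
    none_vs_none = ,
    all_vs_all = ,
    model_vs_model = rep(0, nrow(counts))
  )
}

#' Classic decision-curve net benefit
#'
#' The net benefit of the model strategy as defined in classic decision
#' curve analysis, `tp/n - (fp/n) * Pt/(1 - Pt)`. Algebraically identical
#' to `nerd_pair(counts, pair = "none_vs_model")`; it exists as the
#' cross-check of that equivalence and for users who think in net-benefit
#' terms.
#'
#' @inheritParams expected_regrets
#' @return Numeric vector, one value per row of `counts`.
#' @examples
#' toy <- data.frame(risk = c(0.9, 0.6, 0.3, 0.1), outcome = c(1, 0, 1, 0))
#' net_benefit(classify_cohort(toy, 0.25))
#' @export
net_benefit <- function(counts, threshold = NULL) {
  counts <- check_counts(counts, threshold)
  w <- threshold_weight(counts$threshold)
  counts$tp / counts$n - (counts$fp / counts$n) * w
}

# shared validation: confusion counts + finite-weight threshold
check_counts <- function(counts, threshold = NULL) {
  if (!is.data.frame(counts) ||
      !all(c("tp", "fp", "fn", "tn", "n") %in% names(counts))) {
    stop(
      "`counts` must be a data frame with columns tp, fp, fn, tn, n ",
      "(see classify_cohort())",
      call. = FALSE
    )
  }
  if (!is.null(threshold)) {
    check_probability(threshold, "threshold")
    counts$threshold <- threshold
  }
  if (!"threshold" %in% names(counts)) {
    stop("supply `threshold` or include a threshold column", call. = FALSE)
  }
  with(counts, {
    if (any(tp + fp + fn + tn != n)) {
      stop("confusion counts must sum to n", call. = FALSE)
    }
  })
  if (any(counts$threshold >= 1 - 1e-9)) {
    stop(
      "threshold is 1 (or effectively 1): the odds weight Pt/(1 - Pt) ",
      "diverges, so expected regrets are undefined; treatment at such a ",
      "threshold is justified only at certainty of disease",
      call. = FALSE
    )
  }
  counts
}
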
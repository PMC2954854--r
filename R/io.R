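#' Read a cohort from CSV
#'
#' Reads the standard cohort file: a CSV with header `id,risk,outcome`,
#' one row per patient, `risk` a decimal in `[0, 1]` and `outcome` 0 or 1.
#' Row order is preserved; duplicate ids are rejected.
#'
#' @param path Path to the CSV file.
#' @return A validated [as_cohort()] tibble.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_cohort(simulate_cohort(5, seed = 1), path)
#' read_cohort(path)
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    stop("cohort file not found: ", path, call. = FALSE)
  }
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(c("id", "risk", "outcome"), names(data))
  if (length(missing_cols) > 0) {
    stop(
      "cohort file must have header id,risk,outcome; missing: ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(data) == 0) {
    stop("cohort file has a header but no patients: ", path, call. = FALSE)
  }
  if (anyDuplicated(data$id)) {
    dup <- data$id[duplicated(data$id)]
    stop(
      "duplicate patient id(s): ",
      paste(utils::head(unique(dup), 5), collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.numeric(data$risk)) {
    stop("`risk` column is not numeric", call. = FALSE)
  }
  as_cohort(data)
}

#' Write a cohort to CSV
#'
#' Serialises the `id`, `risk` and `outcome` columns with risks at 10
#' significant digits, enough for [read_cohort()] to reproduce the cohort
#' exactly at double precision for all practical risk values.
#'
#' @param cohort A data frame accepted by [as_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- as_cohort(cohort)
  out <- data.frame(
    id = cohort$id,
    risk = formatC(cohort$risk, digits = 10, format = "g"),
    outcome = as.integer(cohort$outcome)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a regret curve to TSV
#'
#' Emits the per-threshold expected regrets and NERDs as tab-separated
#' values with columns `threshold`, `erg_none`, `erg_all`, `erg_model`,
#' `nerd_none_model`, `nerd_none_all`, `nerd_all_model`.
#'
#' @param curve A [regret_curve()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  needed <- c(
    "threshold", "erg_treat_none", "erg_treat_all", "erg_model",
    "nerd_none_model", "nerd_none_all", "nerd_all_model"
  )
  if (!all(needed %in% names(curve))) {
    stop("`curve` must be a regret_curve tibble", call. = FALSE)
  }
  out <- curve[, needed]
  names(out) <- c(
    "threshold", "erg_none", "erg_all", "erg_model",
    "nerd_none_model", "nerd_none_all", "nerd_all_model"
  )
  readr::write_tsv(tibble::as_tibble(out), path, progress = FALSE)
  invisible(path)
}

#' Parse a grid specification string
#'
#' Turns `"start:stop:step"` (e.g. `"0:0.99:0.01"`) into the strictly
#' increasing threshold grid it denotes, validating that every value lies
#' in `[0, 1)`.
#'
#' @param spec A string of the form `"start:stop:step"`.
#' @return Numeric vector of thresholds.
#' @examples
#' parse_grid("0:0.5:0.1")
#' @export
parse_grid <- function(spec) {
  parts <- suppressWarnings(as.numeric(strsplit(spec, ":", fixed = TRUE)[[1]]))
  if (length(parts) != 3 || anyNA(parts)) {
    stop("grid spec must be \"start:stop:step\", e.g. \"0:0.99:0.01\"",
      call. = FALSE
    )
  }
  if (parts[3] <= 0 || parts[2] < parts[1]) {
    stop("grid spec must have step > 0 and stop >= start", call. = FALSE)
  }
  grid <- seq(parts[1], parts[2], by = parts[3])
  check_probability(grid, "grid")
  if (any(grid >= 1)) {
    stop("grid thresholds must be below 1", call. = FALSE)
  }
  grid
}

#' Serialise a decision report
#'
#' Writes a [decide()] report either as stable, machine-readable JSON or as
#' human-readable text that mirrors the five-step decision workflow
#' (threshold elicitation, strategy comparison, patient decision,
#' acceptable regret, comfort bounds). The JSON form round-trips: parsing
#' and re-serialising reproduces the bytes.
#'
#' @param report A `regret_decision` object from [decide()].
#' @param path Optional output path; when `NULL` the serialised report is
#'   only returned.
#' @param format `"json"` or `"text"`.
#' @return The serialised report as a character scalar (JSON) or character
#'   vector of lines (text), invisibly when `path` is given.
#' @export
write_report <- function(report, path = NULL, format = c("json", "text")) {
  format <- match.arg(format)
  if (!inherits(report, "regret_decision")) {
    stop("`report` must come from decide()", call. = FALSE)
  }
  out <- switch(format,
    json = report_json(report),
    text = format_report_text(report)
  )
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

report_json <- function(x) {
  strip_null <- function(l) l[!vapply(l, is.null, logical(1))]
  num <- function(v) if (is.null(v) || is.na(v)) NULL else as.numeric(v)
  payload <- strip_null(list(
    assessment = list(
      omission = x$assessment$omission,
      commission = x$assessment$commission
    ),
    threshold = list(
      value = x$threshold$threshold,
      weight = x$threshold$weight,
      percent = percent_trunc(x$threshold$threshold, label = FALSE)
    ),
    point = as.list(x$point),
    strategy = list(
      optimal = x$strategy$optimal,
      recommendation = x$strategy$recommendation
    ),
    acceptable = if (!is.null(x$acceptable)) as.list(x$acceptable),
    equivalence = if (!is.null(x$strategy_rg)) {
      list(
        rg0 = x$strategy_rg$rg0,
        equivalent_in_regret = x$strategy_rg$equivalent_in_regret,
        recommendation = x$strategy_rg$recommendation,
        model_superfluous = x$strategy_rg$model_superfluous
      )
    },
    comfort = if (!is.null(x$comfort)) {
      strip_null(list(
        p_treat_none = num(x$comfort$p_treat_none),
        p_treat_all = num(x$comfort$p_treat_all)
      ))
    },
    patient_risk = x$patient_risk,
    recommendation = x$recommendation,
    treat = x$treat
  ))
  as.character(jsonlite::toJSON(
    payload,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  ))
}

format_report_text <- function(x) {
  pct <- function(p) percent_trunc(p)
  lines <- c(
    "Regret-based decision report",
    "",
    "Step 1 - Threshold elicitation",
    sprintf("  regret of omission:   %g / 100", x$assessment$omission),
    sprintf("  regret of commission: %g / 100", x$assessment$commission),
    sprintf(
      "  threshold: %s (exact %.6f, odds weight %.4f)",
      pct(x$threshold$threshold), x$threshold$threshold, x$threshold$weight
    ),
    "",
    "Step 2 - Strategy comparison at the threshold"
  )
  cmp <- x$strategy$comparisons
  lines <- c(lines, sprintf(
    "  NERD[%s] = %+.6f -> %s",
    cmp$pair, cmp$nerd, cmp$preferred
  ))
  lines <- c(lines, sprintf(
    "  optimal strategy: %s",
    paste(x$strategy$optimal, collapse = ", ")
  ))

  lines <- c(lines, "", "Step 3 - Patient decision")
  if ("model" %in% x$strategy$optimal) {
    lines <- c(lines, sprintf(
      "  patient risk %s vs threshold %s -> %s",
      pct(x$patient_risk), pct(x$threshold$threshold),
      if (x$patient_risk >= x$threshold$threshold) {
        "treat (risk at or above threshold)"
      } else {
        "do not treat (risk below threshold)"
      }
    ))
  } else {
    lines <- c(lines, sprintf(
      "  model not the optimal strategy; acting as '%s' regardless of risk",
      x$strategy$recommendation
    ))
  }

  if (!is.null(x$acceptable)) {
    acc <- x$acceptable
    lines <- c(
      lines, "",
      "Step 4 - Acceptable regret",
      sprintf(
        "  basis %s: tolerated %g of %g -> r = %.4g, budget rg0 = %.4g",
        acc$basis, acc$tolerated, acc$denominator, acc$r, acc$rg0
      ),
      sprintf(
        "  equivalent in regret: %s",
        paste(x$strategy_rg$equivalent_in_regret, collapse = ", ")
      )
    )
    if (x$strategy_rg$model_superfluous) {
      lines <- c(
        lines,
        "  the prediction model is equivalent in regret to a simpler",
        "  strategy: its use is superfluous at this budget"
      )
    }
  }

  if (!is.null(x$comfort)) {
    lines <- c(lines, "", "Step 5 - Comfort bounds")
    if (!is.na(x$comfort$p_treat_none)) {
      lines <- c(lines, sprintf(
        "  tolerate withholding treatment below p_treat_none = %s",
        pct(x$comfort$p_treat_none)
      ))
    }
    if (!is.na(x$comfort$p_treat_all)) {
      lines <- c(lines, sprintf(
        "  tolerate unnecessary treatment above p_treat_all = %s",
        pct(x$comfort$p_treat_all)
      ))
    }
  }

  c(lines, "", sprintf(
    "Recommendation: %s%s",
    x$recommendation,
    if (x$recommendation == "model") {
      sprintf(
        " -> %s this patient",
        if (isTRUE(x$treat)) "treat" else "do not treat"
      )
    } else {
      ""
    }
  ))
}
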
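#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a regret decision curve
#'
#' Draws the three NERD series against threshold probability: treat-none
#' vs treat-all, treat-none vs model, and treat-all vs model. At a given
#' threshold the strategy favoured by the signs of these curves is the one
#' with least expected regret. When an acceptable-regret budget is given,
#' horizontal dashed lines at `+/- rg0` mark the band inside which two
#' strategies are equivalent in regret.
#'
#' @param object A [regret_curve()] object.
#' @param rg0 Optional acceptable-regret budget to mark as dashed lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' curve <- regret_curve(simulate_cohort(500, mode = "two_group", seed = 7))
#' autoplot(curve, rg0 = 0.02)
#' @method autoplot regret_curve
#' @export
autoplot.regret_curve <- function(object, rg0 = NULL, ...) {
  long <- tidy(object)
  long$comparison <- factor(
    long$comparison,
    levels = c("none_vs_all", "none_vs_model", "all_vs_model"),
    labels = c(
      "treat none vs treat all",
      "treat none vs model",
      "treat all vs model"
    )
  )
  p <- ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$threshold, y = .data$nerd,
      colour = .data$comparison, linetype = .data$comparison
    )
  ) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(
      x = "threshold probability",
      y = "net expected regret difference (NERD)",
      colour = NULL, linetype = NULL
    ) +
    ggplot2::theme_minimal()
  if (!is.null(rg0)) {
    p <- p + ggplot2::geom_hline(
      yintercept = c(-rg0, rg0),
      linetype = "dashed", colour = "grey40"
    )
  }
  p
}

#' @export
plot.regret_curve <- function(x, y, ...) {
  print(autoplot(x, ...))
  invisible(x)
}
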
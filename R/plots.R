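#' Histogram of probability-scale scores by race
#'
#' Mirrors the usual presentation of a risk-score distribution in a two-race
#' cohort: faceted histograms of the probability-scale score.
#'
#' @param scores Score tibble from [compute_grs()] or [score_cohort()].
#' @param panel Optional panel (or any tibble with `person_id` and `race`)
#'   used to facet by race.
#' @param variant Score column to plot (`"grs"` or `"grs_no_apoe"`).
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_grs_distribution <- function(scores, panel = NULL, variant = "grs",
                                  bins = 60) {
  assert_cols(scores, c("person_id", variant), "`scores`")
  df <- as_tibble(scores)
  if (!is.null(panel)) {
    race <- distinct(as_tibble(panel)[, c("person_id", "race")])
    df <- left_join(df, race, by = "person_id")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[variant]])) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white",
                            linewidth = 0.1) +
    ggplot2::labs(x = "probability-scale genetic risk score", y = "persons") +
    ggplot2::theme_minimal()
  if (!is.null(panel)) p <- p + ggplot2::facet_wrap(~race, scales = "free_y")
  p
}

#' Forest plot of a model battery
#'
#' @param battery Result tibble from [run_model_battery()].
#' @param outcome Which outcome to display.
#' @return A ggplot object (odds-ratio scale is logarithmic for the dementia
#'   outcome).
#' @export
plot_model_battery <- function(battery, outcome = "dementia") {
  df <- filter(as_tibble(battery), .data$outcome == !!outcome, .data$estimable)
  if (!nrow(df)) abort("No estimable rows for that outcome.")
  null_line <- if (outcome == "dementia") 1 else 0
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$analysis,
                                        colour = .data$exposure)) +
    ggplot2::geom_vline(xintercept = null_line, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = if (outcome == "dementia") "odds ratio per 0.1 score units"
                  else "SD difference per 0.1 score units",
                  y = NULL, colour = "score variant") +
    ggplot2::theme_minimal()
  if (outcome == "dementia") p <- p + ggplot2::scale_x_log10()
  p
}

#' @describeIn fit_pooled_logistic Coefficient plot of a `grs_fit` with
#'   cluster-robust Wald intervals.
#' @param object A `grs_fit`.
#' @method autoplot grs_fit
#' @export
autoplot.grs_fit <- function(object, ...) {
  df <- filter(object$coefficients, .data$term != "(Intercept)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "coefficient (link scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn run_exclusion_cascade Waterfall plot of the exclusion
#'   cascade's remaining counts.
#' @param object An `exclusion_report`.
#' @param ... Unused.
#' @method autoplot exclusion_report
#' @export
autoplot.exclusion_report <- function(object, ...) {
  df <- tibble(stage = c("candidates", object$stage),
               n = c(attr(object, "n_initial"), object$n_remaining))
  df$stage <- factor(df$stage, levels = df$stage)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "observations remaining") +
    ggplot2::theme_minimal()
}
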
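#' Shift a baseline probability by an odds-ratio effect
#'
#' Converts a baseline probability to odds, multiplies by
#' `or_per_unit^(delta / scale)`, and converts back. This is how a relative
#' (odds-ratio) effect per `scale` exposure units is translated into the
#' absolute probability implied at a shifted exposure -- e.g. the dementia
#' probability of a person one score-SD above the mean, starting from a
#' model-predicted baseline.
#'
#' @param baseline Baseline probability in (0, 1); vectorized.
#' @param or_per_unit Odds ratio per `scale` exposure units (> 0).
#' @param delta Exposure shift, in exposure units.
#' @param scale Exposure increment the odds ratio refers to (default 0.1).
#' @return The shifted probability.
#' @examples
#' # a 1.10% baseline risk shifted by +0.037 score units at OR 2.22 per 0.1
#' shift_probability(0.011, 2.22, 0.037)
#' @export
shift_probability <- function(baseline, or_per_unit, delta, scale = 0.1) {
  if (any(baseline <= 0 | baseline >= 1)) abort("`baseline` must lie in (0, 1).")
  if (any(or_per_unit <= 0)) abort("`or_per_unit` must be positive.")
  if (scale <= 0) abort("`scale` must be positive.")
  odds <- baseline / (1 - baseline) * or_per_unit^(delta / scale)
  odds / (1 + odds)
}

#' Absolute risk difference implied by an odds-ratio effect
#'
#' Percentage-point change in probability when the exposure shifts by
#' `delta`: `100 * (shifted - baseline)` with the shift computed by
#' [shift_probability()]. Puts a multiplicative odds-ratio effect on the
#' additive scale, where groups with different baseline risks can be
#' compared directly.
#'
#' @inheritParams shift_probability
#' @return Risk difference in percentage points.
#' @export
risk_difference <- function(baseline, or_per_unit, delta, scale = 0.1) {
  100 * (shift_probability(baseline, or_per_unit, delta, scale) - baseline)
}

#' Predict an absolute probability from a fitted pooled logistic model
#'
#' Evaluates the inverse-logit linear predictor of a `grs_fit` at a covariate
#' profile, giving the model-based analogue of the printed-number workflow in
#' [shift_probability()].
#'
#' @param fit A converged logistic `grs_fit`.
#' @param profile One-row data frame / list with the model's covariates in
#'   natural units: the exposure column (e.g. `grs`), `age`, `sex`, and
#'   optionally `wave_year` (defaults to the fit's year origin) and `race`
#'   for race-pooled fits.
#' @return The predicted probability.
#' @export
predict_from_fit <- function(fit, profile) {
  stopifnot(inherits(fit, "grs_fit"))
  if (fit$family == "gaussian") abort("Probability prediction needs a logistic fit.")
  if (!fit$converged) abort("The fit did not converge; refusing to predict.")
  profile <- as_tibble(profile)
  xcol <- exposure_column(fit$spec)
  needed <- setdiff(all.vars(stats::formula(fit$model)), ".outcome")
  nd <- tibble(.rows = nrow(profile))
  if (xcol %in% needed) {
    assert_cols(profile, xcol, "Profile")
    nd[[xcol]] <- profile[[xcol]]
  }
  if ("age_c" %in% needed) {
    assert_cols(profile, "age", "Profile")
    nd$age_c <- profile$age - 70
  }
  if ("sex" %in% needed) {
    assert_cols(profile, "sex", "Profile")
    nd$sex <- factor(profile$sex, levels = c("male", "female"))
  }
  if ("year_c" %in% needed) {
    yr <- if ("wave_year" %in% names(profile)) profile$wave_year else fit$year_origin
    nd$year_c <- yr - fit$year_origin
  }
  if ("race" %in% needed) {
    assert_cols(profile, "race", "Profile")
    nd$race <- factor(profile$race, levels = c("NHW", "NHB"))
  }
  if ("age65" %in% needed) {
    assert_cols(profile, "age", "Profile")
    nd$age65 <- factor(ifelse(profile$age >= 65, "65+", "50-64"),
                       levels = c("50-64", "65+"))
  }
  unname(predict(fit$model, newdata = nd, type = "response"))
}
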
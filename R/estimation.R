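#' Specify a panel model
#'
#' Describes one analysis cell: which outcome, which exposure, any stratum
#' restriction, and any exposure-by-factor interaction. Every model adjusts
#' for age (linear, centered at 70), sex and assessment year; these are part
#' of the model family, not options. Stratifying on a variable and
#' interacting the exposure with the same variable are mutually exclusive.
#'
#' @param outcome `"dementia"` (continuous probability outcome in \[0,1\],
#'   defined at ages 65+) or `"memory"` (standardized memory score).
#' @param exposure `"grs"`, `"grs_no_apoe"`, `"apoe_carrier"` or
#'   `"single_snp"` (with `snp` giving the dosage column).
#' @param snp Dosage column name for `exposure = "single_snp"`.
#' @param stratum Optional named list restricting the sample, e.g.
#'   `list(race = "NHW")`, `list(sex = "female")`,
#'   `list(age_band = "65+")` (bands `"50-64"` / `"65+"`).
#' @param interaction Optional factor to interact with the exposure:
#'   `"race"`, `"sex"` or `"age_65plus"`.
#' @param exposure_scale Exposure increment per reported effect (0.1 score
#'   units by convention).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(outcome = c("dementia", "memory"),
                       exposure = c("grs", "grs_no_apoe", "apoe_carrier", "single_snp"),
                       snp = NULL,
                       stratum = NULL,
                       interaction = NULL,
                       exposure_scale = 0.1) {
  outcome <- match.arg(outcome)
  exposure <- match.arg(exposure)
  if (exposure == "single_snp" && is.null(snp)) {
    abort("`single_snp` exposure needs `snp` (the dosage column name).")
  }
  if (!is.null(interaction)) {
    interaction <- match.arg(interaction, c("race", "sex", "age_65plus"))
  }
  if (!is.null(stratum)) {
    bad <- setdiff(names(stratum), c("race", "sex", "age_band"))
    if (length(bad)) abort(sprintf("Unknown stratum variable(s): %s.", paste(bad, collapse = ", ")))
    ivar <- switch(interaction %||% "", race = "race", sex = "sex",
                   age_65plus = "age_band", "")
    if (ivar %in% names(stratum)) {
      abort("Stratifying on a variable and interacting the exposure with it are mutually exclusive.")
    }
  }
  if (exposure_scale <= 0) abort("`exposure_scale` must be positive.")
  structure(list(outcome = outcome, exposure = exposure, snp = snp,
                 stratum = stratum, interaction = interaction,
                 exposure_scale = exposure_scale),
            class = "model_spec")
}

exposure_column <- function(spec) {
  if (spec$exposure == "single_snp") spec$snp else spec$exposure
}

outcome_column <- function(spec) {
  switch(spec$outcome, dementia = "dementia_prob", memory = "memory_score")
}

# build the analysis frame: stratum filter, derived covariates, complete cases
prep_model_frame <- function(panel, spec, year_origin = NULL) {
  xcol <- exposure_column(spec)
  ycol <- outcome_column(spec)
  assert_cols(panel, c(xcol, "age", "sex", "wave_year", ycol), "Panel")
  df <- as_tibble(panel)
  df$age_band <- ifelse(df$age >= 65, "65+", "50-64")
  if (!is.null(spec$stratum)) {
    for (v in names(spec$stratum)) {
      df <- df[df[[v]] %in% spec$stratum[[v]], , drop = FALSE]
    }
  }
  year_origin <- year_origin %||%
    if (nrow(df)) min(df$wave_year, na.rm = TRUE) else 0
  df$.outcome <- as.numeric(df[[ycol]])
  df$.exposure <- as.numeric(df[[xcol]])
  df$age_c <- df$age - 70
  df$year_c <- df$wave_year - year_origin
  df$sex <- factor(df$sex, levels = c("male", "female"))
  if ("race" %in% names(df)) df$race <- factor(df$race, levels = c("NHW", "NHB"))
  df$age65 <- factor(df$age_band, levels = c("50-64", "65+"))
  keep <- complete.cases(df[, c(".outcome", ".exposure", "age_c", "sex", "year_c")])
  structure(df[keep, , drop = FALSE], year_origin = year_origin)
}

model_formula <- function(spec, xcol, data) {
  # the age/sex/year adjustment set is fixed, but a covariate constant within
  # the analysis frame (one wave, a sex stratum) is absorbed by the intercept
  varies <- function(v) length(unique(data[[v]])) > 1
  rhs <- c(xcol, c("age_c", "sex", "year_c")[vapply(c("age_c", "sex", "year_c"),
                                                    varies, logical(1))])
  if (!is.null(spec$interaction)) {
    iv <- switch(spec$interaction, race = "race", sex = "sex", age_65plus = "age65")
    if (!iv %in% rhs) rhs <- c(rhs, iv)
    rhs <- c(rhs, paste0(xcol, ":", iv))
  }
  as.formula(paste(".outcome ~", paste(rhs, collapse = " + ")))
}

#' Cluster-robust (sandwich) covariance for a fitted glm or lm
#'
#' Computes the CR0 sandwich: bread is the unscaled inverse information
#' `(X'WX)^-1`; meat is the sum over clusters of outer products of
#' within-cluster summed score vectors `x_i (y_i - mu_i)`. With every
#' observation its own cluster this is the HC0 heteroskedasticity-robust
#' estimator. `"CR1"` applies the finite-sample scaling
#' `G/(G-1) * (n-1)/(n-k)`.
#'
#' @param model A fitted `glm` (canonical link) or `lm`.
#' @param cluster Cluster membership vector, length `nobs(model)`.
#' @param type `"CR0"` (default) or `"CR1"`.
#' @return The robust covariance matrix of the coefficients.
#' @export
cluster_vcov <- function(model, cluster, type = c("CR0", "CR1")) {
  type <- match.arg(type)
  X <- model.matrix(model)
  if (length(cluster) != nrow(X)) {
    abort("`cluster` must have one entry per model observation.")
  }
  if (inherits(model, "glm")) {
    mu <- stats::fitted(model)
    pw <- stats::weights(model, type = "prior")
    r <- pw * (model$y - mu)
    # information at the converged coefficients (not the lagged IRLS weights)
    w <- pw * model$family$variance(mu)
    bread <- chol2inv(chol(crossprod(X * sqrt(w))))
  } else {
    r <- residuals(model)
    bread <- chol2inv(chol(crossprod(X)))
  }
  S <- rowsum(X * r, group = as.character(cluster))
  meat <- crossprod(as.matrix(S))
  V <- bread %*% meat %*% bread
  if (type == "CR1") {
    G <- nrow(S); n <- nrow(X); k <- ncol(X)
    V <- V * G / (G - 1) * (n - 1) / (n - k)
  }
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

new_grs_fit <- function(model, data, spec, vcov_type, family_label) {
  co <- coef(model)
  if (anyNA(co)) {
    abort(sprintf("Design is rank deficient; collinear column(s): %s.",
                  paste(names(co)[is.na(co)], collapse = ", ")))
  }
  V <- cluster_vcov(model, data$person_id, type = vcov_type)
  se <- sqrt(diag(V))
  z <- co / se
  ctab <- tibble(
    term = names(co), estimate = unname(co), std.error = unname(se),
    statistic = unname(z), p.value = 2 * pnorm(-abs(z)),
    conf.low = unname(co - qnorm(0.975) * se),
    conf.high = unname(co + qnorm(0.975) * se)
  )
  xcol <- exposure_column(spec)
  s <- spec$exposure_scale
  main <- ctab[ctab$term == xcol, ]
  effect <- if (nrow(main) == 1) {
    if (family_label == "gaussian") {
      tibble(term = main$term, estimate = s * main$estimate,
             conf.low = s * main$conf.low, conf.high = s * main$conf.high,
             p.value = main$p.value)
    } else {
      tibble(term = main$term, estimate = exp(s * main$estimate),
             conf.low = exp(s * main$conf.low),
             conf.high = exp(s * main$conf.high), p.value = main$p.value)
    }
  } else tibble()
  structure(
    list(coefficients = ctab, vcov_cluster = V,
         n_obs = nrow(data), n_clusters = length(unique(data$person_id)),
         effect_per_scale = effect, converged = isTRUE(model$converged %||% TRUE),
         family = family_label, spec = spec, model = model,
         year_origin = attr(data, "year_origin")),
    class = "grs_fit"
  )
}

#' Pooled logistic regression with cluster-robust inference
#'
#' Fits a logistic model to stacked person-wave observations of the
#' continuous dementia-probability outcome (quasi-binomial likelihood, so the
#' outcome may be a fraction in \[0,1\] or binary), with covariance from the
#' cluster-robust sandwich over persons. The reported effect is the odds
#' ratio per `exposure_scale` (0.1 by default) exposure units, with a Wald
#' 95% CI on the log-odds scale.
#'
#' @param panel Person-wave tibble carrying the outcome, the exposure column
#'   and `person_id`, `age`, `sex`, `wave_year` (plus `race` when used).
#' @param spec A [model_spec()] with `outcome = "dementia"`.
#' @param vcov_type `"CR0"` or `"CR1"` (see [cluster_vcov()]).
#' @param min_obs Minimum observations with outcome present.
#' @return A `grs_fit` object; see [tidy.grs_fit()] and [glance.grs_fit()].
#' @export
fit_pooled_logistic <- function(panel, spec = model_spec("dementia"),
                                vcov_type = "CR0", min_obs = 50) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$outcome != "dementia") abort("Use fit_linear_clustered() for the memory outcome.")
  df <- prep_model_frame(panel, spec)
  if (nrow(df) < min_obs) {
    abort(sprintf("Only %d usable observations (< %d).", nrow(df), min_obs))
  }
  if (var(df$.outcome) == 0) {
    abort("Outcome has no variation in this stratum; the model is not estimable.")
  }
  xcol <- exposure_column(spec)
  df[[xcol]] <- df$.exposure
  model <- suppressWarnings(
    glm(model_formula(spec, xcol, df), family = quasibinomial(), data = df,
        control = list(maxit = 100, epsilon = 1e-10))
  )
  fit <- new_grs_fit(model, df, spec, vcov_type, "quasibinomial")
  if (!fit$converged) {
    warn("IRLS did not converge within 100 iterations; treat estimates as diagnostics.")
  }
  fit
}

#' Linear (least-squares) panel model with cluster-robust inference
#'
#' Ordinary least squares for the standardized memory score on stacked
#' person-wave observations, with the same cluster-robust sandwich
#' construction as [fit_pooled_logistic()] under an identity link. The
#' reported effect is in outcome SD units per `exposure_scale` exposure
#' units.
#'
#' @inheritParams fit_pooled_logistic
#' @param spec A [model_spec()] with `outcome = "memory"`.
#' @return A `grs_fit` object.
#' @export
fit_linear_clustered <- function(panel, spec = model_spec("memory"),
                                 vcov_type = "CR0", min_obs = 50) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$outcome != "memory") abort("Use fit_pooled_logistic() for the dementia outcome.")
  df <- prep_model_frame(panel, spec)
  if (nrow(df) < min_obs) {
    abort(sprintf("Only %d usable observations (< %d).", nrow(df), min_obs))
  }
  xcol <- exposure_column(spec)
  df[[xcol]] <- df$.exposure
  model <- lm(model_formula(spec, xcol, df), data = df)
  new_grs_fit(model, df, spec, vcov_type, "gaussian")
}

#' Wald test of a single model term under the cluster-robust covariance
#'
#' Typically used for exposure-by-factor interaction terms. Reports the term
#' on the effect scale of the fit: an odds ratio per `exposure_scale` units
#' for logistic fits, an SD-unit difference for linear fits.
#'
#' @param fit A `grs_fit`.
#' @param term Coefficient name (e.g. `"grs:raceNHB"`).
#' @return One-row tibble: `term`, `estimate`, `conf.low`, `conf.high`,
#'   `statistic`, `p.value`.
#' @export
interaction_test <- function(fit, term) {
  stopifnot(inherits(fit, "grs_fit"))
  ctab <- fit$coefficients
  row <- ctab[ctab$term == term, ]
  if (nrow(row) != 1) {
    abort(sprintf("Term '%s' is not in the model. Available: %s.",
                  term, paste(ctab$term, collapse = ", ")))
  }
  s <- fit$spec$exposure_scale
  scale_est <- grepl(":", term, fixed = TRUE) ||
    term == exposure_column(fit$spec)
  k <- if (scale_est) s else 1
  if (fit$family == "gaussian") {
    tibble(term = term, estimate = k * row$estimate,
           conf.low = k * row$conf.low, conf.high = k * row$conf.high,
           statistic = row$statistic, p.value = row$p.value)
  } else {
    tibble(term = term, estimate = exp(k * row$estimate),
           conf.low = exp(k * row$conf.low), conf.high = exp(k * row$conf.high),
           statistic = row$statistic, p.value = row$p.value)
  }
}

#' Run the standard battery of stratified and interaction models
#'
#' Reproduces the layout of a race-comparative risk-score analysis: for each
#' outcome and score variant, a race-pooled model, NHW and NHB stratified
#' models, and a race-pooled model with a race-by-exposure interaction.
#' Optional blocks add age-band-stratified models with an age-65+ interaction
#' (memory outcome, a survival-bias probe), gender-stratified models with a
#' gender interaction, and single-exposure models (APOE carriage, single
#' SNPs). Cells that cannot be estimated (empty stratum, no outcome
#' variation) come back flagged rather than failing the battery.
#'
#' @param panel Person-wave panel.
#' @param scores Per-person score table from [score_cohort()]; joined on
#'   `person_id`. Pass `NULL` if the exposure columns are already on `panel`.
#' @param outcomes Outcomes to run (`"dementia"`, `"memory"`).
#' @param exposures Score variants (`"grs"`, `"grs_no_apoe"`).
#' @param age_strata Add 50-64 / 65+ stratified + interaction rows for the
#'   memory outcome.
#' @param gender_strata Add male / female stratified + interaction rows.
#' @param carrier_models Add APOE-carrier exposure models.
#' @param snps Dosage column names to test as single-SNP exposures.
#' @param vcov_type Passed to the fitters.
#' @return Tibble with one row per analysis cell: `outcome`, `exposure`,
#'   `analysis`, `term`, `estimate`, `conf.low`, `conf.high`, `p.value`,
#'   `n_obs`, `n_clusters`, `estimable`, `note`.
#' @export
run_model_battery <- function(panel, scores = NULL,
                              outcomes = c("dementia", "memory"),
                              exposures = c("grs", "grs_no_apoe"),
                              age_strata = FALSE, gender_strata = FALSE,
                              carrier_models = FALSE, snps = character(),
                              vcov_type = "CR0") {
  df <- as_tibble(panel)
  if (!is.null(scores)) {
    df <- left_join(df, scores, by = "person_id",
                    suffix = c("", ".score"))
  }
  cells <- list()
  add <- function(outcome, exposure, analysis, spec, snp = NULL) {
    cells[[length(cells) + 1L]] <<- list(outcome = outcome, exposure = exposure,
                                         analysis = analysis, spec = spec)
  }
  for (y in outcomes) {
    for (x in exposures) {
      add(y, x, "pooled", model_spec(y, x))
      add(y, x, "NHW", model_spec(y, x, stratum = list(race = "NHW")))
      add(y, x, "NHB", model_spec(y, x, stratum = list(race = "NHB")))
      add(y, x, "race_interaction", model_spec(y, x, interaction = "race"))
      if (age_strata && y == "memory") {
        for (r in c("NHW", "NHB")) {
          add(y, x, paste0(r, "_age50-64"),
              model_spec(y, x, stratum = list(race = r, age_band = "50-64")))
          add(y, x, paste0(r, "_age65+"),
              model_spec(y, x, stratum = list(race = r, age_band = "65+")))
          add(y, x, paste0(r, "_age_interaction"),
              model_spec(y, x, stratum = list(race = r), interaction = "age_65plus"))
        }
      }
      if (gender_strata) {
        for (r in c("NHW", "NHB")) {
          add(y, x, paste0(r, "_gender_interaction"),
              model_spec(y, x, stratum = list(race = r), interaction = "sex"))
        }
      }
    }
    if (carrier_models) {
      for (r in c("NHW", "NHB")) {
        add(y, "apoe_carrier", r,
            model_spec(y, "apoe_carrier", stratum = list(race = r),
                       exposure_scale = 1))
      }
    }
    for (sn in snps) {
      add(y, sn, "NHB",
          model_spec(y, "single_snp", snp = sn, stratum = list(race = "NHB"),
                     exposure_scale = 1))
    }
  }

  purrr::map_dfr(cells, function(cell) {
    spec <- cell$spec
    base <- tibble(outcome = cell$outcome, exposure = cell$exposure,
                   analysis = cell$analysis)
    res <- tryCatch({
      fit <- if (spec$outcome == "dementia") {
        fit_pooled_logistic(df, spec, vcov_type = vcov_type)
      } else {
        fit_linear_clustered(df, spec, vcov_type = vcov_type)
      }
      xcol <- exposure_column(spec)
      row <- if (!is.null(spec$interaction)) {
        iv <- switch(spec$interaction, race = "raceNHB", sex = "sexfemale",
                     age_65plus = "age6565+")
        interaction_test(fit, paste0(xcol, ":", iv))
      } else {
        e <- fit$effect_per_scale
        tibble(term = e$term, estimate = e$estimate, conf.low = e$conf.low,
               conf.high = e$conf.high, statistic = NA_real_, p.value = e$p.value)
      }
      mutate(base, term = row$term, estimate = row$estimate,
             conf.low = row$conf.low, conf.high = row$conf.high,
             p.value = row$p.value, n_obs = fit$n_obs,
             n_clusters = fit$n_clusters, estimable = TRUE, note = "")
    }, error = function(e) {
      mutate(base, term = NA_character_, estimate = NA_real_,
             conf.low = NA_real_, conf.high = NA_real_, p.value = NA_real_,
             n_obs = NA_integer_, n_clusters = NA_integer_,
             estimable = FALSE, note = conditionMessage(e))
    })
    res
  })
}

#' @describeIn fit_pooled_logistic Tidy the coefficient table of a `grs_fit`
#'   (cluster-robust standard errors and Wald intervals on the link scale;
#'   `exponentiate = TRUE` for odds ratios).
#' @param x A `grs_fit` object.
#' @param exponentiate Report exponentiated coefficients (logistic fits).
#' @param ... Unused.
#' @method tidy grs_fit
#' @export
tidy.grs_fit <- function(x, exponentiate = FALSE, ...) {
  out <- x$coefficients
  if (exponentiate) {
    if (x$family == "gaussian") abort("Cannot exponentiate a linear fit.")
    out <- mutate(out, estimate = exp(.data$estimate),
                  conf.low = exp(.data$conf.low),
                  conf.high = exp(.data$conf.high))
  }
  out
}

#' @describeIn fit_pooled_logistic One-row model summary of a `grs_fit`.
#' @method glance grs_fit
#' @export
glance.grs_fit <- function(x, ...) {
  e <- x$effect_per_scale
  tibble(
    outcome = x$spec$outcome, exposure = x$spec$exposure,
    effect_per_scale = if (nrow(e)) e$estimate else NA_real_,
    conf.low = if (nrow(e)) e$conf.low else NA_real_,
    conf.high = if (nrow(e)) e$conf.high else NA_real_,
    p.value = if (nrow(e)) e$p.value else NA_real_,
    n_obs = x$n_obs, n_clusters = x$n_clusters, converged = x$converged
  )
}

#' @export
print.grs_fit <- function(x, ...) {
  cat(sprintf("<grs_fit> %s ~ %s | %s, %d obs in %d clusters\n",
              x$spec$outcome, x$spec$exposure,
              if (x$family == "gaussian") "linear (OLS)" else "pooled logistic",
              x$n_obs, x$n_clusters))
  e <- x$effect_per_scale
  if (nrow(e)) {
    lab <- if (x$family == "gaussian") "beta" else "OR"
    cat(sprintf("  %s per %.2g exposure units: %.3f (%.3f, %.3f), p = %.3g\n",
                lab, x$spec$exposure_scale, e$estimate, e$conf.low, e$conf.high,
                e$p.value))
  }
  invisible(x)
}
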
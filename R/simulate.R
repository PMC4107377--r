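#' Simulation parameters for a synthetic two-race biennial cohort
#'
#' Bundles and validates everything the synthetic-cohort generator needs. The
#' defaults emulate the published characteristics of the dementia-probability
#' analysis sample of the US Health and Retirement Study 2006-2010: 7,690
#' persons of whom 1,015 are non-Hispanic Black (NHB); first-wave age 74.0
#' (SD 7.08) among non-Hispanic White (NHW) and 71.6 (SD 6.62) among NHB;
#' 43.3% / 37.7% male; generative dementia odds ratios per 0.1 probability-scale
#' risk-score unit of 2.22 (NHW) and 1.33 (NHB); memory-score slopes of -0.07
#' and -0.01 SD per 0.1 unit with a -0.49 SD race main effect; and race-mean
#' probability-scale scores of 0.092 / 0.122, hit by calibrating allele
#' frequencies (see [calibrate_allele_freqs()]).
#'
#' @param n_persons Cohort size.
#' @param prop_nhb Proportion NHB.
#' @param weights Weight table; must carry `freq_nhw`/`freq_nhb` columns when
#'   `allele_freq` is to be calibrated.
#' @param allele_freq Named list with elements `NHW` and `NHB`, each a named
#'   per-locus effect-allele frequency vector. `NULL` (default) calibrates
#'   frequencies so the population mean score hits `target_mean_grs`.
#' @param target_mean_grs Named race vector of target mean probability-scale
#'   scores for calibration.
#' @param prevalence Anchor prevalence of the score transform.
#' @param age_mean,age_sd Named race vectors for the first-wave age draw
#'   (truncated normal on `age_bounds`).
#' @param age_bounds First-wave age range.
#' @param prop_male Named race vector.
#' @param or_per_0.1 Named race vector: generative dementia odds ratio per 0.1
#'   score unit.
#' @param baseline_dementia_prob Named race vector: dementia probability at
#'   the reference profile (male, age 70, first wave, score 0.1).
#' @param age_logodds_per_year,female_logodds,year_logodds Nuisance
#'   log-odds terms of the dementia model (per year of age, for female sex,
#'   per calendar year).
#' @param beta_memory_per_0.1 Named race vector: memory-score slope (SD units
#'   per 0.1 score unit).
#' @param race_main_effect_memory Memory SD-unit main effect of NHB race.
#' @param memory_intercept,memory_age_slope,memory_year_slope,memory_noise_sd
#'   Remaining memory-model terms (pre-standardization units).
#' @param wave_death_rate Per-wave death hazard after wave 1 (absorbing).
#' @param wave_nonresponse_rate Per-wave nonresponse probability after wave 1.
#' @param outcome_mode `"binary"` draws the dementia outcome as Bernoulli;
#'   `"fractional"` stores a logit-normal perturbation of the model
#'   probability (a continuous score in (0, 1)).
#' @param fractional_noise_sd Logit-scale noise SD for `"fractional"` mode.
#' @param waves Assessment calendar years.
#' @param seed Optional integer seed consumed by [simulate_study()].
#' @return A list of class `sim_params` (the simulation "truth").
#' @export
sim_params <- function(n_persons = 7690,
                       prop_nhb = 1015 / 7690,
                       weights = default_weight_table(),
                       allele_freq = NULL,
                       target_mean_grs = c(NHW = 0.092, NHB = 0.122),
                       prevalence = 0.1,
                       age_mean = c(NHW = 74.00, NHB = 71.63),
                       age_sd = c(NHW = 7.08, NHB = 6.62),
                       age_bounds = c(50, 95),
                       prop_male = c(NHW = 0.433, NHB = 0.377),
                       or_per_0.1 = c(NHW = 2.22, NHB = 1.33),
                       baseline_dementia_prob = c(NHW = 0.011, NHB = 0.033),
                       age_logodds_per_year = 0.08,
                       female_logodds = -0.1,
                       year_logodds = 0.02,
                       beta_memory_per_0.1 = c(NHW = -0.07, NHB = -0.01),
                       race_main_effect_memory = -0.49,
                       memory_intercept = 1.0,
                       memory_age_slope = -0.02,
                       memory_year_slope = -0.01,
                       memory_noise_sd = 0.95,
                       wave_death_rate = 0.04,
                       wave_nonresponse_rate = 0.03,
                       outcome_mode = c("binary", "fractional"),
                       fractional_noise_sd = 0.5,
                       waves = c(2006L, 2008L, 2010L),
                       seed = NULL) {
  outcome_mode <- match.arg(outcome_mode)
  if (n_persons < 10) abort("`n_persons` must be at least 10.")
  assert_scalar_prob(prop_nhb, "prop_nhb", open = FALSE)
  assert_scalar_prob(prevalence, "prevalence")
  weights <- validate_weight_table(weights)
  races <- c("NHW", "NHB")
  need_race <- function(x, what) {
    if (!all(races %in% names(x))) {
      abort(sprintf("`%s` must be named with NHW and NHB entries.", what))
    }
    x[races]
  }
  for (nm in c("age_mean", "age_sd", "prop_male", "or_per_0.1",
               "baseline_dementia_prob", "beta_memory_per_0.1",
               "target_mean_grs")) {
    assign(nm, need_race(get(nm), nm))
  }
  if (any(`or_per_0.1` <= 0)) abort("Generative odds ratios must be positive.")
  for (p in c(wave_death_rate, wave_nonresponse_rate)) {
    if (p < 0 || p > 1) abort("Dropout rates must lie in [0, 1].")
  }
  if (!is.null(allele_freq)) {
    if (!all(races %in% names(allele_freq))) {
      abort("`allele_freq` must be a list with NHW and NHB elements.")
    }
    for (r in races) {
      f <- allele_freq[[r]][weights$locus_id]
      if (anyNA(f) || any(f <= 0 | f >= 1)) {
        abort(sprintf("`allele_freq$%s` must give a frequency in (0, 1) for every weight-table locus.", r))
      }
      allele_freq[[r]] <- f
    }
  }
  structure(
    list(n_persons = as.integer(n_persons), prop_nhb = prop_nhb,
         weights = weights, allele_freq = allele_freq,
         target_mean_grs = target_mean_grs, prevalence = prevalence,
         age_mean = age_mean, age_sd = age_sd, age_bounds = age_bounds,
         prop_male = prop_male, or_per_0.1 = `or_per_0.1`,
         baseline_dementia_prob = baseline_dementia_prob,
         age_logodds_per_year = age_logodds_per_year,
         female_logodds = female_logodds, year_logodds = year_logodds,
         beta_memory_per_0.1 = beta_memory_per_0.1,
         race_main_effect_memory = race_main_effect_memory,
         memory_intercept = memory_intercept,
         memory_age_slope = memory_age_slope,
         memory_year_slope = memory_year_slope,
         memory_noise_sd = memory_noise_sd,
         wave_death_rate = wave_death_rate,
         wave_nonresponse_rate = wave_nonresponse_rate,
         outcome_mode = outcome_mode,
         fractional_noise_sd = fractional_noise_sd,
         waves = as.integer(waves), seed = seed),
    class = "sim_params"
  )
}

#' Exact population mean of the probability-scale score under Hardy-Weinberg
#'
#' Enumerates the full distribution of the weighted allele sum (dosages
#' independent binomial(2, freq) per locus) and returns the exact expectation
#' of the probability-scale score. Enumeration is over 3^L genotype classes,
#' so the weight table is capped at 13 loci.
#'
#' @param weights Weight table.
#' @param freq Named per-locus effect-allele frequency vector.
#' @param prevalence Anchor prevalence.
#' @return The expected probability-scale score (a single number).
#' @export
expected_mean_grs <- function(weights, freq, prevalence = 0.1) {
  weights <- validate_weight_table(weights)
  if (nrow(weights) > 13) abort("Exact enumeration supports at most 13 loci.")
  freq <- freq[weights$locus_id]
  if (anyNA(freq)) abort("`freq` must cover every weight-table locus.")
  s <- 0; p <- 1
  for (j in seq_len(nrow(weights))) {
    f <- freq[j]; b <- weights$beta[j]
    dp <- c((1 - f)^2, 2 * f * (1 - f), f^2)
    s <- as.vector(outer(s, c(0, b, 2 * b), "+"))
    p <- as.vector(outer(p, dp, "*"))
  }
  sum(p * plogis(log(prevalence) + s))
}

#' Calibrate allele frequencies to a target mean score
#'
#' Finds Hardy-Weinberg effect-allele frequencies whose population mean
#' probability-scale score equals `target_mean_grs`, by a monotone
#' one-dimensional root search over a shared logit-scale shift of the base
#' frequencies. The shift is signed by each locus's effect direction (+shift
#' for risk-increasing effect alleles, -shift for protective ones) so the
#' mean score is strictly increasing in the shift. Base frequencies (for the
#' bundled table, literature-typical values -- e.g. APOE epsilon-4 near
#' 0.285 / 0.415 in the two race groups) are starting points; the shift moves
#' every weighted locus unless it is listed in `fixed_loci`.
#'
#' @param weights Weight table with base-frequency column `base_freq_col`
#'   (or pass `base_freq` directly).
#' @param target_mean_grs Target population mean probability-scale score.
#' @param base_freq Named base-frequency vector; defaults to the column
#'   `base_freq_col` of `weights`.
#' @param base_freq_col Name of the frequency column in `weights`
#'   (e.g. `"freq_nhw"`).
#' @param prevalence Anchor prevalence.
#' @param fixed_loci Locus IDs whose frequencies are not shifted.
#' @param freq_bounds Allowed frequency range after shifting.
#' @return Named frequency vector with attribute `"shift"` (the logit shift).
#'   Errors, reporting the achievable range, if the target is out of reach.
#' @export
calibrate_allele_freqs <- function(weights, target_mean_grs,
                                   base_freq = NULL,
                                   base_freq_col = "freq_nhw",
                                   prevalence = 0.1,
                                   fixed_loci = character(),
                                   freq_bounds = c(0.01, 0.99)) {
  weights <- validate_weight_table(weights)
  assert_scalar_prob(target_mean_grs, "target_mean_grs")
  if (is.null(base_freq)) {
    if (!base_freq_col %in% names(weights)) {
      abort(sprintf("Weight table has no `%s` column and no `base_freq` was given.", base_freq_col))
    }
    base_freq <- setNames(weights[[base_freq_col]], weights$locus_id)
  }
  base_freq <- base_freq[weights$locus_id]
  if (anyNA(base_freq) || any(base_freq <= 0 | base_freq >= 1)) {
    abort("Base frequencies must lie in (0, 1) for every locus.")
  }
  shiftable <- !(weights$locus_id %in% fixed_loci) & weights$beta != 0
  freq_at <- function(shift) {
    f <- base_freq
    f[shiftable] <- plogis(qlogis(base_freq[shiftable]) +
                             sign(weights$beta[shiftable]) * shift)
    pmin(pmax(f, freq_bounds[1]), freq_bounds[2])
  }
  gap <- function(shift) {
    expected_mean_grs(weights, freq_at(shift), prevalence) - target_mean_grs
  }
  lo <- gap(-12); hi <- gap(12)
  if (abs(lo) < 1e-12 || abs(hi) < 1e-12 || (lo < 0) == (hi < 0)) {
    if (abs(gap(0)) < 1e-12) {
      out <- freq_at(0); attr(out, "shift") <- 0; return(out)
    }
    abort(sprintf(
      "Target mean score %.4f is unreachable; achievable range is [%.4f, %.4f] within frequency bounds [%.2f, %.2f].",
      target_mean_grs, lo + target_mean_grs, hi + target_mean_grs,
      freq_bounds[1], freq_bounds[2]))
  }
  root <- uniroot(gap, c(-12, 12), tol = 1e-10)
  out <- freq_at(root$root)
  attr(out, "shift") <- root$root
  out
}

#' Draw genotype dosages under Hardy-Weinberg equilibrium
#'
#' Dosages are independent binomial(2, freq) per locus and person, with
#' race-specific frequencies and linkage equilibrium between loci.
#'
#' @param race Character vector (NHW/NHB), one entry per person.
#' @param allele_freq Named list `NHW`/`NHB` of per-locus frequency vectors.
#' @param weights Weight table (defines locus set and order).
#' @param person_id Optional identifiers.
#' @return Genotype tibble (`person_id` + dosage columns).
#' @export
simulate_genotypes <- function(race, allele_freq, weights,
                               person_id = NULL) {
  weights <- validate_weight_table(weights)
  n <- length(race)
  person_id <- person_id %||% sprintf("P%06d", seq_len(n))
  geno <- tibble(person_id = person_id)
  for (loc in weights$locus_id) {
    f <- vapply(race, function(r) allele_freq[[r]][[loc]], numeric(1))
    if (any(f <= 0 | f >= 1)) abort("Allele frequencies must lie strictly in (0, 1).")
    geno[[loc]] <- rbinom(n, 2L, f)
  }
  validate_genotypes(geno, weights)
}

#' Simulate the person-wave phenotype panel
#'
#' Builds the long panel from per-person attributes and scores: ages advance
#' two years per biennial wave; after wave 1, persons die at the configured
#' absorbing hazard or miss a wave at the nonresponse rate; the dementia
#' outcome (only defined at ages 65+) has log-odds linear in the
#' probability-scale score with race-specific slope `log(or_per_0.1)/0.1`,
#' plus age, sex and year terms; the memory score is linear in the score with
#' race-specific slopes, a race main effect, age, year, and Gaussian noise,
#' then standardized by the first-wave observed standard deviation.
#'
#' @param params A [sim_params()] object.
#' @param persons Tibble `person_id`, `race`, `sex`, `age_w1`.
#' @param scores Tibble `person_id`, `grs` (probability scale).
#' @return A validated panel tibble.
#' @export
simulate_panel <- function(params, persons, scores) {
  stopifnot(inherits(params, "sim_params"))
  assert_cols(persons, c("person_id", "race", "sex", "age_w1"), "`persons`")
  df <- left_join(persons, scores[, c("person_id", "grs")], by = "person_id")
  if (anyNA(df$grs)) abort("Every person needs a score to simulate the panel.")
  n <- nrow(df)
  waves <- params$waves
  alive <- rep(TRUE, n)
  rows <- vector("list", length(waves))
  for (w in seq_along(waves)) {
    age <- df$age_w1 + 2 * (w - 1)
    if (w == 1) {
      status <- rep("observed", n)
    } else {
      newly_dead <- alive & (runif(n) < params$wave_death_rate)
      alive <- alive & !newly_dead
      status <- ifelse(!alive, "dead",
                       ifelse(runif(n) < params$wave_nonresponse_rate,
                              "nonresponse", "observed"))
    }
    observed <- status == "observed"

    eta <- qlogis(params$baseline_dementia_prob[df$race]) +
      (log(params$or_per_0.1[df$race]) / 0.1) * (df$grs - 0.1) +
      params$age_logodds_per_year * (age - 70) +
      params$female_logodds * (df$sex == "female") +
      params$year_logodds * (waves[w] - waves[1])
    dem <- rep(NA_real_, n)
    eligible <- observed & age >= 65
    if (params$outcome_mode == "binary") {
      dem[eligible] <- rbinom(sum(eligible), 1L, plogis(eta[eligible]))
    } else {
      noise <- rnorm(sum(eligible), 0, params$fractional_noise_sd)
      dem[eligible] <- plogis(eta[eligible] + noise)
    }

    mem <- rep(NA_real_, n)
    mem[observed] <- params$memory_intercept +
      params$race_main_effect_memory * (df$race[observed] == "NHB") +
      (params$beta_memory_per_0.1[df$race[observed]] / 0.1) * (df$grs[observed] - 0.1) +
      params$memory_age_slope * (age[observed] - 70) +
      params$memory_year_slope * (waves[w] - waves[1]) +
      rnorm(sum(observed), 0, params$memory_noise_sd)

    rows[[w]] <- tibble(
      person_id = df$person_id, wave_year = waves[w], race = df$race,
      sex = df$sex, age = age, dementia_prob = dem, memory_score = mem,
      status = status
    )
  }
  panel <- bind_rows(rows)
  # standardize memory by the first-wave observed SD
  sd1 <- sd(panel$memory_score[panel$wave_year == waves[1]], na.rm = TRUE)
  panel$memory_score <- panel$memory_score / sd1
  validate_panel(panel)
}

#' Simulate a complete synthetic study
#'
#' Orchestrates the generator: assigns race, sex and first-wave age; draws
#' Hardy-Weinberg genotypes at (calibrated) race-specific allele frequencies;
#' scores every person; and simulates the person-wave panel. The result
#' carries the parameters actually used (including calibrated frequencies) as
#' `truth`, so a run is fully reproducible from its own output.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed; overrides `params$seed`. Identical parameters
#'   and seed give a bit-identical study.
#' @return A list of class `synthetic_study` with elements `genotypes`,
#'   `panel`, `scores` and `truth`.
#' @export
simulate_study <- function(params = sim_params(), seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_persons
  n_nhb <- round(n * params$prop_nhb)
  race <- c(rep("NHB", n_nhb), rep("NHW", n - n_nhb))

  allele_freq <- params$allele_freq
  if (is.null(allele_freq)) {
    allele_freq <- list(
      NHW = calibrate_allele_freqs(params$weights, params$target_mean_grs[["NHW"]],
                                   base_freq_col = "freq_nhw",
                                   prevalence = params$prevalence),
      NHB = calibrate_allele_freqs(params$weights, params$target_mean_grs[["NHB"]],
                                   base_freq_col = "freq_nhb",
                                   prevalence = params$prevalence)
    )
  }
  params$allele_freq <- allele_freq

  genotypes <- simulate_genotypes(race, allele_freq, params$weights)
  scores <- score_cohort(genotypes, params$weights,
                         prevalence = params$prevalence)
  persons <- tibble(
    person_id = genotypes$person_id,
    race = race,
    sex = ifelse(runif(n) < params$prop_male[race], "male", "female"),
    age_w1 = rtruncnorm(n, params$age_mean[race], params$age_sd[race],
                        params$age_bounds[1], params$age_bounds[2])
  )
  panel <- simulate_panel(params, persons, scores)
  structure(list(genotypes = genotypes, panel = panel, scores = scores,
                 truth = params),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d persons, %d person-wave records (%s outcome mode)\n",
    nrow(x$genotypes), nrow(x$panel), x$truth$outcome_mode))
  invisible(x)
}
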
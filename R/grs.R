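#' Configuration for the probability-scale genetic risk score
#'
#' @param prevalence Assumed disease prevalence used to anchor the
#'   odds-to-probability transform; the conventional dementia value is 0.1.
#' @param exclude_loci Locus IDs dropped from the weighted sum (e.g. the APOE
#'   pair for the APOE-excluded score variant).
#' @param missing How to treat missing dosages: `"mean"` imputes the locus
#'   mean dosage over non-missing persons (the usual polygenic-score
#'   convention, keeps panels balanced); `"drop"` scores a person only if all
#'   included loci are observed.
#' @return A list of class `grs_config`.
#' @export
grs_config <- function(prevalence = 0.1, exclude_loci = character(),
                       missing = c("mean", "drop")) {
  assert_scalar_prob(prevalence, "prevalence")
  structure(
    list(prevalence = prevalence,
         exclude_loci = as.character(exclude_loci),
         missing = match.arg(missing)),
    class = "grs_config"
  )
}

#' Per-person weighted risk-allele sum
#'
#' Computes, for each person, the sum over score loci of effect-allele dosage
#' times the per-allele log odds ratio. Loci in `config$exclude_loci` are
#' removed before summing. Missing dosages are mean-imputed or cause the
#' person to be dropped to `NA`, per `config$missing`; a person with no
#' observed locus is always indeterminate (`NA`).
#'
#' @param genotypes Genotype tibble (`person_id` + dosage columns).
#' @param weights Weight table.
#' @param config A [grs_config()].
#' @return Tibble `person_id`, `weighted_sum`, `n_loci_used`.
#' @export
weighted_allele_sum <- function(genotypes, weights, config = grs_config()) {
  weights <- validate_weight_table(weights)
  stopifnot(inherits(config, "grs_config"))
  unknown <- setdiff(config$exclude_loci, weights$locus_id)
  if (length(unknown)) {
    abort(sprintf("exclude_loci not in the weight table: %s.",
                  paste(unknown, collapse = ", ")))
  }
  keep <- !weights$locus_id %in% config$exclude_loci
  w <- weights[keep, ]
  genotypes <- validate_genotypes(genotypes, weights)
  D <- as.matrix(genotypes[, w$locus_id, drop = FALSE])

  n_used <- rowSums(!is.na(D))
  if (config$missing == "mean") {
    for (j in seq_len(ncol(D))) {
      mu <- mean(D[, j], na.rm = TRUE)
      D[is.na(D[, j]), j] <- mu    # NaN when the whole locus is missing
    }
    D[is.nan(D)] <- 0  # fully-missing locus contributes nothing
    s <- drop(D %*% w$beta)
    s[n_used == 0 & nrow(w) > 0] <- NA_real_
  } else {
    s <- drop(ifelse(is.na(D), 0, D) %*% w$beta)
    s[n_used < nrow(w)] <- NA_real_
  }
  if (nrow(w) == 0) s <- rep(0, nrow(genotypes))
  if (anyNA(s)) {
    inform(sprintf("%d person(s) had an indeterminate weighted sum under the '%s' missing-dosage policy.",
                   sum(is.na(s)), config$missing))
  }
  tibble(person_id = genotypes$person_id, weighted_sum = s, n_loci_used = n_used)
}

#' Odds-anchored probability transform of a weighted allele sum
#'
#' Maps a weighted log-odds-ratio sum `s` to a probability via
#' `odds = prevalence * exp(s)` and `p = odds / (1 + odds)`. The result is the
#' probability-scale genetic risk score: the disease probability implied by
#' the person's alleles when a carrier of zero risk alleles sits at the
#' assumed population prevalence. Computed on the logit scale
#' (`plogis(log(prevalence) + s)`), so it is stable for |s| well beyond 50.
#'
#' @param weighted_sum Numeric vector of weighted allele sums.
#' @param prevalence Anchor prevalence in (0, 1).
#' @return Probabilities in (0, 1).
#' @export
grs_probability <- function(weighted_sum, prevalence = 0.1) {
  assert_scalar_prob(prevalence, "prevalence")
  if (any(!is.finite(weighted_sum) & !is.na(weighted_sum))) {
    abort("`weighted_sum` must be finite (or NA).")
  }
  plogis(log(prevalence) + weighted_sum)
}

#' Invert the probability transform back to the weighted sum
#'
#' @param probability Probabilities in (0, 1).
#' @param prevalence Anchor prevalence.
#' @return The weighted allele sums.
#' @export
grs_inverse <- function(probability, prevalence = 0.1) {
  assert_scalar_prob(prevalence, "prevalence")
  qlogis(probability) - log(prevalence)
}

#' Compute probability-scale genetic risk scores
#'
#' Composition of [weighted_allele_sum()] and [grs_probability()]: one row per
#' person with the weighted sum, the prevalence-anchored odds, and the
#' probability-scale score. With `config$exclude_loci` set to the APOE pair
#' this yields the APOE-excluded score variant.
#'
#' @inheritParams weighted_allele_sum
#' @return Tibble `person_id`, `weighted_sum`, `odds`, `grs`, `n_loci_used`.
#' @export
compute_grs <- function(genotypes, weights, config = grs_config()) {
  ws <- weighted_allele_sum(genotypes, weights, config)
  ws %>%
    mutate(odds = config$prevalence * exp(.data$weighted_sum),
           grs = grs_probability(.data$weighted_sum, config$prevalence)) %>%
    select("person_id", "weighted_sum", "odds", "grs", "n_loci_used")
}

#' Score a cohort with both the full and the APOE-excluded risk score
#'
#' Convenience wrapper returning, per person, the full score (`grs`) and the
#' variant excluding the APOE pair (`grs_no_apoe`), plus APOE epsilon-4
#' carrier status when the rs429358 dosage is available.
#'
#' @inheritParams weighted_allele_sum
#' @param prevalence Anchor prevalence passed to both score variants.
#' @param missing Missing-dosage policy (see [grs_config()]).
#' @return Tibble `person_id`, `weighted_sum`, `odds`, `grs`, `grs_no_apoe`,
#'   `apoe_carrier`, `n_loci_used`.
#' @export
score_cohort <- function(genotypes, weights, prevalence = 0.1,
                         missing = "mean") {
  weights <- validate_weight_table(weights)
  full <- compute_grs(genotypes, weights,
                      grs_config(prevalence, missing = missing))
  noap <- compute_grs(genotypes, weights,
                      grs_config(prevalence, exclude_loci = apoe_loci(weights),
                                 missing = missing))
  out <- full %>%
    left_join(noap %>% select("person_id", grs_no_apoe = "grs"),
              by = "person_id")
  out$apoe_carrier <- if ("rs429358" %in% names(genotypes)) {
    apoe_e4_status(genotypes$rs429358)$e4_carrier
  } else NA
  out %>% select("person_id", "weighted_sum", "odds", "grs", "grs_no_apoe",
                 "apoe_carrier", "n_loci_used")
}

#' APOE epsilon-4 status from rs429358 (and optionally rs7412) dosages
#'
#' The epsilon-4 haplotype is defined by the rs429358-C allele, so with
#' unphased data the epsilon-4 allele count is taken directly as the rs429358
#' effect-allele dosage. Under `strict = TRUE` the one genuinely phase-ambiguous
#' configuration -- the rs429358/rs7412 double heterozygote, whose two
#' phase-consistent haplotype pairs are epsilon-1/epsilon-3 and
#' epsilon-2/epsilon-4 -- is flagged indeterminate (`NA`) instead.
#'
#' @param rs429358_dosage Dosage of the epsilon-4-defining rs429358 allele.
#' @param rs7412_dosage Dosage of the epsilon-2-defining rs7412 allele
#'   (only needed for strict mode).
#' @param strict Flag the ambiguous double heterozygote as indeterminate.
#' @param person_id Optional identifiers carried through.
#' @return Tibble `person_id`, `e4_allele_count`, `e4_carrier` (logical,
#'   `NA` = indeterminate).
#' @export
apoe_e4_status <- function(rs429358_dosage, rs7412_dosage = NULL,
                           strict = FALSE, person_id = NULL) {
  n <- length(rs429358_dosage)
  cnt <- as.numeric(rs429358_dosage)
  if (any(!is.na(cnt) & !cnt %in% c(0, 1, 2))) {
    abort("rs429358 dosage must be 0, 1, 2 or missing.")
  }
  if (strict) {
    if (is.null(rs7412_dosage)) abort("Strict mode needs the rs7412 dosage.")
    amb <- !is.na(cnt) & cnt == 1 & !is.na(rs7412_dosage) & rs7412_dosage == 1
    cnt[amb] <- NA_real_
  }
  tibble(
    person_id = person_id %||% as.character(seq_len(n)),
    e4_allele_count = cnt,
    e4_carrier = cnt >= 1
  )
}

#' Quintile bins of a score
#'
#' Assigns each value to a sample quintile (1 = lowest). Binning is by rank
#' with ties sharing the lower bin, so bin sizes differ by at most one apart
#' from ties; an all-equal input has no quintiles and errors.
#'
#' @param x Numeric vector with at least 5 values, not all equal.
#' @return Integer bins in 1..5 (NA values propagate).
#' @export
quintile_bins <- function(x) {
  obs <- x[!is.na(x)]
  if (length(obs) < 5) abort("Quintile binning needs at least 5 non-missing values.")
  if (length(unique(obs)) == 1) abort("All values are equal; quintiles are undefined.")
  r <- rank(x, ties.method = "min", na.last = "keep")
  n <- length(obs)
  bins <- as.integer(floor((r - 1) * 5 / n) + 1L)
  pmin(bins, 5L)
}
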
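test_that("the cluster-robust sandwich matches an independent brute-force formula", {
  df <- small_cluster_fixture()
  fit <- fit_pooled_logistic(df, model_spec("dementia", "grs"), min_obs = 5)
  V_bf <- brute_force_cr0(fit$model, df$person_id)
  expect_equal(unname(fit$vcov_cluster), unname(V_bf), tolerance = 1e-10)

  lfit <- fit_linear_clustered(df, model_spec("memory", "grs"), min_obs = 5)
  V_bf_lm <- brute_force_cr0(lfit$model, df$person_id)
  expect_equal(unname(lfit$vcov_cluster), unname(V_bf_lm), tolerance = 1e-10)

  skip_if_not_installed("sandwich")
  V_pkg <- sandwich::vcovCL(fit$model, cluster = df$person_id,
                            type = "HC0", cadjust = FALSE)
  expect_equal(unname(fit$vcov_cluster), unname(V_pkg), tolerance = 1e-5)
})

test_that("singleton clusters collapse the sandwich to the HC0 form", {
  df <- small_cluster_fixture()
  df$person_id <- sprintf("solo%02d", seq_len(nrow(df)))  # one obs per person
  df <- df[!duplicated(df[c("person_id", "wave_year")]), ]
  fit <- fit_pooled_logistic(df, model_spec("dementia", "grs"), min_obs = 5)
  # HC0 by brute force: per-observation scores
  V_hc0 <- brute_force_cr0(fit$model, seq_len(nrow(df)))
  expect_equal(unname(fit$vcov_cluster), unname(V_hc0), tolerance = 1e-10)
  skip_if_not_installed("sandwich")
  expect_equal(unname(fit$vcov_cluster),
               unname(sandwich::vcovHC(fit$model, type = "HC0")),
               tolerance = 1e-5)
})

test_that("a binary-exposure logistic fit reproduces the 2x2 cross-product odds ratio", {
  # the same 2x2 table replicated over balanced covariate patterns, so the
  # covariate coefficients vanish by symmetry and the adjusted OR is the
  # marginal cross-product ratio (3/2)/(1/4) = 6
  cell <- function(apoe_carrier, y, k) {
    tibble::tibble(apoe_carrier = apoe_carrier, dementia_prob = y)[rep(1, k), ]
  }
  block <- dplyr::bind_rows(cell(1, 1, 3), cell(1, 0, 2), cell(0, 1, 1), cell(0, 0, 4))
  df <- purrr::map_dfr(1:4, function(pat) {
    dplyr::mutate(block,
                  sex = c("male", "male", "female", "female")[pat],
                  age = c(68, 72, 68, 72)[pat])
  })
  df$person_id <- sprintf("p%03d", seq_len(nrow(df)))
  df$wave_year <- 2006L
  fit <- fit_pooled_logistic(
    df, model_spec("dementia", "apoe_carrier", exposure_scale = 1), min_obs = 5)
  or <- fit$effect_per_scale$estimate
  expect_equal(or, 6, tolerance = 1e-8)
})

test_that("a noiseless linear outcome is interpolated exactly", {
  df <- small_cluster_fixture()
  df$memory_score <- 2 - 3 * df$grs + 0.05 * (df$age - 70) -
    0.2 * (df$sex == "female") + 0.01 * (df$wave_year - 2006)
  fit <- fit_linear_clustered(df, model_spec("memory", "grs"), min_obs = 5)
  co <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(unname(co["grs"]), -3, tolerance = 1e-10)
  expect_equal(unname(co["age_c"]), 0.05, tolerance = 1e-10)
  expect_equal(unname(co["sexfemale"]), -0.2, tolerance = 1e-10)
  expect_equal(fit$effect_per_scale$estimate, -0.3, tolerance = 1e-10)
})

test_that("point estimates and cluster-robust SEs are invariant to within-cluster duplication", {
  df <- toy_panel_data(n_persons = 120, seed = 2)
  dup <- dplyr::bind_rows(df, df)
  for (builder in list(
    function(d) fit_pooled_logistic(d, model_spec("dementia", "grs")),
    function(d) fit_linear_clustered(d, model_spec("memory", "grs"))
  )) {
    f1 <- builder(df); f2 <- builder(dup)
    expect_equal(f1$coefficients$estimate, f2$coefficients$estimate, tolerance = 1e-8)
    expect_equal(f1$coefficients$std.error, f2$coefficients$std.error, tolerance = 1e-6)
  }
})

test_that("stratified effects decompose as main plus interaction in a fully interacted model", {
  df <- toy_panel_data(n_persons = 400, seed = 3)
  nhb <- fit_pooled_logistic(df, model_spec("dementia", "grs",
                                            stratum = list(race = "NHB")))
  # oracle: one glm with race crossed against every term
  d2 <- dplyr::mutate(df, age_c = age - 70, year_c = wave_year - min(wave_year),
                      sex = factor(sex, levels = c("male", "female")),
                      race = factor(race, levels = c("NHW", "NHB")))
  full <- stats::glm(dementia_prob ~ race * (grs + age_c + sex + year_c),
                     family = stats::quasibinomial(), data = d2,
                     control = list(epsilon = 1e-12, maxit = 100))
  b <- stats::coef(full)
  expect_equal(
    unname(nhb$coefficients$estimate[nhb$coefficients$term == "grs"]),
    unname(b["grs"] + b["raceNHB:grs"]),
    tolerance = 1e-8
  )
})

test_that("the interaction Wald test reports the term on the effect scale", {
  df <- toy_panel_data(n_persons = 300, seed = 4)
  fit <- fit_pooled_logistic(df, model_spec("dementia", "grs", interaction = "race"))
  it <- interaction_test(fit, "grs:raceNHB")
  co <- fit$coefficients[fit$coefficients$term == "grs:raceNHB", ]
  expect_equal(it$estimate, exp(0.1 * co$estimate), tolerance = 1e-12)
  expect_identical(it$p.value, co$p.value)
  expect_error(interaction_test(fit, "grs:raceXX"), "not in the model")
})

test_that("exposure effects are invariant to affine relabeling of the year covariate", {
  df <- toy_panel_data(n_persons = 200, seed = 5)
  df2 <- dplyr::mutate(df, wave_year = 3L * wave_year - 5000L)
  f1 <- fit_pooled_logistic(df, model_spec("dementia", "grs"))
  f2 <- fit_pooled_logistic(df2, model_spec("dementia", "grs"))
  expect_equal(f1$effect_per_scale$estimate, f2$effect_per_scale$estimate,
               tolerance = 1e-8)
  expect_equal(f1$effect_per_scale$conf.low, f2$effect_per_scale$conf.low,
               tolerance = 1e-8)
})

test_that("centering age is a pure reparameterization", {
  df <- toy_panel_data(n_persons = 200, seed = 6)
  mine <- fit_pooled_logistic(df, model_spec("dementia", "grs"))
  d2 <- dplyr::mutate(df, year_c = wave_year - min(wave_year),
                      sex = factor(sex, levels = c("male", "female")))
  raw <- stats::glm(dementia_prob ~ grs + age + sex + year_c,
                    family = stats::quasibinomial(), data = d2,
                    control = list(epsilon = 1e-12, maxit = 100))
  expect_equal(
    unname(mine$coefficients$estimate[mine$coefficients$term == "grs"]),
    unname(stats::coef(raw)["grs"]), tolerance = 1e-8)
})

test_that("degenerate designs raise informative errors", {
  df <- toy_panel_data(n_persons = 100, seed = 7)
  no_var <- dplyr::mutate(df, dementia_prob = 1)
  expect_error(fit_pooled_logistic(no_var, model_spec("dementia", "grs")),
               "no variation")
  expect_error(fit_pooled_logistic(df[1:20, ], model_spec("dementia", "grs")),
               "usable observations")
  # age made an exact affine function of the exposure: rank deficient,
  # and the error names the aliased column
  collinear <- dplyr::mutate(df, age = 70 + 10 * grs)
  expect_error(
    fit_linear_clustered(collinear, model_spec("memory", "grs")),
    "rank deficient.*age_c"
  )
  # stratum and interaction on the same variable are rejected up front
  expect_error(model_spec("dementia", "grs", stratum = list(race = "NHW"),
                          interaction = "race"),
               "mutually exclusive")
})

test_that("the model battery emits the pooled/stratified/interaction layout", {
  df <- toy_panel_data(n_persons = 350, seed = 8)
  bat <- run_model_battery(df)
  expect_equal(nrow(bat), 16L)  # 2 outcomes x 2 exposures x 4 analyses
  expect_setequal(unique(bat$analysis), c("pooled", "NHW", "NHB", "race_interaction"))
  expect_true(all(bat$estimable))
  expect_true(all(bat$estimate[bat$outcome == "dementia"] > 0))

  # empty stratum rows are flagged, not fatal
  nhw_only <- dplyr::filter(df, race == "NHW")
  bat2 <- run_model_battery(nhw_only, outcomes = "dementia", exposures = "grs")
  nhb_row <- dplyr::filter(bat2, analysis == "NHB")
  expect_false(nhb_row$estimable)
  expect_match(nhb_row$note, ".")

  # a truly null single-SNP exposure estimates near its generative OR of 1
  set.seed(9)
  df$rs115550680 <- rbinom(nrow(df), 2, 0.1)
  bat3 <- run_model_battery(df, outcomes = "dementia", exposures = "grs",
                            snps = "rs115550680")
  snp_row <- dplyr::filter(bat3, exposure == "rs115550680")
  z <- log(snp_row$estimate) / ((log(snp_row$conf.high) - log(snp_row$conf.low)) / (2 * qnorm(0.975)))
  expect_lt(abs(z), 4)
})

test_that("tidy and glance expose coefficients and fit summaries", {
  df <- toy_panel_data(n_persons = 150, seed = 10)
  fit <- fit_pooled_logistic(df, model_spec("dementia", "grs"))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "p.value",
                    "conf.low", "conf.high") %in% names(td)))
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
  td_or <- tidy(fit, exponentiate = TRUE)
  expect_equal(td_or$estimate, exp(td$estimate), tolerance = 1e-12)
  gl <- glance(fit)
  expect_identical(gl$n_obs, fit$n_obs)
  expect_lte(gl$n_clusters, gl$n_obs)
  expect_true(gl$converged)
  expect_gt(gl$effect_per_scale, 0)
  lfit <- fit_linear_clustered(df, model_spec("memory", "grs"))
  expect_error(tidy(lfit, exponentiate = TRUE), "linear")
})
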
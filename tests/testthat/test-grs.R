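test_that("weighted allele sums match direct arithmetic and a brute-force oracle", {
  wt <- toy_weights(c(rsA = 0.5, rsB = -0.2))
  g <- toy_genotypes(wt, rbind(c(0, 0), c(2, 1)))
  ws <- weighted_allele_sum(g, wt)
  expect_identical(ws$weighted_sum, c(0, 2 * 0.5 + 1 * (-0.2)))
  expect_identical(ws$n_loci_used, c(2, 2))

  set.seed(7)
  betas <- stats::setNames(round(runif(10, -0.5, 0.8), 3), sprintf("rs%02d", 1:10))
  wt10 <- toy_weights(betas)
  D <- matrix(sample(0:2, 20 * 10, replace = TRUE), nrow = 20)
  g10 <- toy_genotypes(wt10, D)
  got <- weighted_allele_sum(g10, wt10)$weighted_sum
  # independent oracle: explicit loop over (person, locus) pairs
  want <- numeric(20)
  for (i in 1:20) for (j in 1:10) want[i] <- want[i] + D[i, j] * betas[j]
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("the odds-anchored probability transform is exact, stable and invertible", {
  expect_equal(grs_probability(0, 0.1), 0.1 / 1.1, tolerance = 1e-15)
  expect_equal(grs_probability(log(10), 0.1), 0.5, tolerance = 1e-12)
  expect_equal(grs_probability(-log(10), 0.1), 0.0099009900990099, tolerance = 1e-12)
  expect_error(grs_probability(Inf), "finite")
  expect_error(grs_probability(0, prevalence = 1.2), "\\(0, 1\\)")

  s <- seq(-50, 50, length.out = 401)
  p <- grs_probability(s, 0.1)
  expect_true(all(is.finite(p) & p >= 0 & p <= 1))
  expect_true(all(diff(p) >= 0))
  mid <- abs(s) <= 15  # realistic allele-sum range; logit representable to 1e-9
  expect_true(all(diff(p[mid]) > 0))  # strictly increasing
  expect_equal(grs_inverse(p[mid], 0.1), s[mid], tolerance = 1e-9)
})

test_that("score computation composes, excludes loci, and respects the zero-weight invariance", {
  wt <- toy_weights(c(rsA = 0.3, rsB = 0, rsC = -0.1))
  g <- toy_genotypes(wt, rbind(c(2, 1, 0), c(0, 2, 2), c(1, 0, 1)))
  full <- compute_grs(g, wt)
  noB <- compute_grs(g, wt, grs_config(exclude_loci = "rsB"))
  expect_equal(full$grs, noB$grs, tolerance = 1e-15)

  one <- compute_grs(toy_genotypes(toy_weights(c(rsA = 0.3)), cbind(2)),
                     toy_weights(c(rsA = 0.3)))
  expect_equal(one$grs, (0.1 * exp(0.6)) / (1 + 0.1 * exp(0.6)), tolerance = 1e-12)
  expect_equal(one$odds, 0.1 * exp(0.6), tolerance = 1e-12)

  expect_error(compute_grs(g, wt, grs_config(exclude_loci = "nope")), "not in the weight table")
})

test_that("full score decomposes additively into APOE and non-APOE parts", {
  wt <- default_weight_table()
  set.seed(11)
  D <- matrix(sample(0:2, 40 * nrow(wt), replace = TRUE), nrow = 40)
  g <- toy_genotypes(wt, D)
  apoe <- apoe_loci(wt)
  full <- weighted_allele_sum(g, wt)$weighted_sum
  no_apoe <- weighted_allele_sum(g, wt, grs_config(exclude_loci = apoe))$weighted_sum
  only_apoe <- weighted_allele_sum(
    g, wt, grs_config(exclude_loci = setdiff(wt$locus_id, apoe)))$weighted_sum
  expect_equal(full, no_apoe + only_apoe, tolerance = 1e-12)
})

test_that("zero-dosage genomes score exactly at the prevalence anchor", {
  wt <- default_weight_table()
  g <- toy_genotypes(wt, matrix(0, nrow = 2, ncol = nrow(wt)))
  out <- compute_grs(g, wt)
  expect_equal(out$grs, rep(0.1 / 1.1, 2), tolerance = 1e-15)
  out2 <- compute_grs(g, wt, grs_config(prevalence = 0.25))
  expect_equal(out2$grs, rep(0.25 / 1.25, 2), tolerance = 1e-15)
})

test_that("raising a positive-weight dosage strictly raises the score", {
  wt <- toy_weights(c(rsA = 0.4, rsB = -0.3))
  for (d in 0:1) {
    lo <- compute_grs(toy_genotypes(wt, cbind(d, 1)), wt)$grs
    hi <- compute_grs(toy_genotypes(wt, cbind(d + 1, 1)), wt)$grs
    expect_true(hi > lo)
  }
})

test_that("missing dosages follow the configured policy", {
  wt <- toy_weights(c(rsA = 0.5, rsB = 0.2))
  g <- toy_genotypes(wt, rbind(c(2, 1), c(0, NA), c(NA, NA)))
  mean_fill <- suppressMessages(weighted_allele_sum(g, wt))  # locus mean of rsB is 1
  expect_equal(mean_fill$weighted_sum[2], 0 * 0.5 + 1 * 0.2, tolerance = 1e-12)
  expect_true(is.na(mean_fill$weighted_sum[3]))  # nothing observed at all

  strict <- suppressMessages(
    weighted_allele_sum(g, wt, grs_config(missing = "drop")))
  expect_equal(strict$weighted_sum[1], 1.2, tolerance = 1e-12)
  expect_true(all(is.na(strict$weighted_sum[2:3])))
})

test_that("APOE e4 carrier status counts rs429358 and flags the ambiguous double heterozygote", {
  st <- apoe_e4_status(c(0, 1, 2, NA))
  expect_identical(st$e4_carrier, c(FALSE, TRUE, TRUE, NA))
  expect_identical(st$e4_allele_count, c(0, 1, 2, NA))

  strict <- apoe_e4_status(c(1, 1, 2), rs7412_dosage = c(1, 0, 1), strict = TRUE)
  expect_true(is.na(strict$e4_carrier[1]))   # e2/e4 vs e1/e3 cannot be phased
  expect_identical(strict$e4_carrier[2:3], c(TRUE, TRUE))
  expect_error(apoe_e4_status(1, strict = TRUE), "rs7412")
})

test_that("quintile bins split evenly, give ties the lower bin, and reject degenerate input", {
  expect_identical(quintile_bins(1:10), rep(1:5, each = 2))
  expect_error(quintile_bins(rep(3, 10)), "equal")
  expect_error(quintile_bins(c(1, 2, 3, 4)), "at least 5")

  set.seed(5)
  u <- runif(1000)
  tab <- table(quintile_bins(u))
  expect_identical(as.vector(tab), rep(200L, 5))
  # rank-count oracle on a tied vector: all copies of a value share one bin
  x <- c(1, 2, 2, 2, 3, 4, 5, 6, 7, 8)
  b <- quintile_bins(x)
  expect_length(unique(b[x == 2]), 1L)
  expect_true(all(diff(b[order(x)]) >= 0))
})
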
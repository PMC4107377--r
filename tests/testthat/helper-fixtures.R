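# fixtures built in code; everything deterministic given the seed set in tests

toy_weights <- function(betas = c(rsA = 0.5, rsB = -0.2, rsC = 0.3)) {
  tibble::tibble(
    locus_id = names(betas),
    effect_allele = rep(c("A", "C", "G", "T"), length.out = length(betas)),
    beta = unname(betas),
    source_or = NA_real_,
    apoe = FALSE
  )
}

toy_genotypes <- function(weights, dosages) {
  # dosages: matrix persons x loci
  g <- tibble::tibble(person_id = sprintf("p%d", seq_len(nrow(dosages))))
  for (j in seq_len(ncol(dosages))) g[[weights$locus_id[j]]] <- dosages[, j]
  g
}

# logistic person-wave data with known structure, cheap enough for unit tests
toy_panel_data <- function(n_persons = 300, waves = 2, slope = 1.5,
                           base = 0.2, seed = 1) {
  set.seed(seed)
  grs <- runif(n_persons, 0.05, 0.3)
  race <- sample(c("NHW", "NHB"), n_persons, replace = TRUE)
  sex <- sample(c("male", "female"), n_persons, replace = TRUE)
  age1 <- runif(n_persons, 66, 88)
  purrr::map_dfr(seq_len(waves), function(w) {
    age <- age1 + 2 * (w - 1)
    eta <- qlogis(base) + slope * (grs - 0.1) * 10 + 0.03 * (age - 70) +
      0.1 * (sex == "female")
    tibble::tibble(
      person_id = sprintf("p%04d", seq_len(n_persons)),
      wave_year = 2006L + 2L * (w - 1L),
      race = race, sex = sex, age = age,
      dementia_prob = rbinom(n_persons, 1, plogis(eta)),
      memory_score = 1 - 0.5 * (race == "NHB") - 0.7 * (grs - 0.1) -
        0.02 * (age - 70) + rnorm(n_persons, 0, 0.3),
      status = "observed", grs = grs,
      grs_no_apoe = grs * 0.9
    )
  })
}

# small simulation parameter set reused across simulator tests
small_sim_params <- function(..., n_persons = 400) {
  freqs <- list(
    NHW = stats::setNames(rep(0.3, 11), adgrs::default_weight_table()$locus_id),
    NHB = stats::setNames(rep(0.35, 11), adgrs::default_weight_table()$locus_id)
  )
  adgrs::sim_params(n_persons = n_persons, allele_freq = freqs, ...)
}

write_test_vcf <- function(path, records,
                           samples = c("s1", "s2", "s3")) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, records), path)
  path
}

# textbook CR0 sandwich, written out by brute force as an independent oracle
brute_force_cr0 <- function(model, cluster) {
  X <- stats::model.matrix(model)
  if (inherits(model, "glm")) {
    mu <- stats::fitted(model)
    r <- model$y - mu
    W <- diag(mu * (1 - mu))
  } else {
    r <- stats::residuals(model)
    W <- diag(nrow(X))
  }
  bread <- solve(t(X) %*% W %*% X)
  meat <- matrix(0, ncol(X), ncol(X))
  for (g in unique(cluster)) {
    idx <- which(cluster == g)
    s_g <- colSums(X[idx, , drop = FALSE] * r[idx])
    meat <- meat + s_g %o% s_g
  }
  bread %*% meat %*% bread
}

small_cluster_fixture <- function(seed = 17) {
  set.seed(seed)
  n <- 24
  tibble::tibble(
    person_id = rep(sprintf("c%02d", 1:10), times = c(3, 3, 3, 3, 2, 2, 2, 2, 2, 2)),
    wave_year = unlist(lapply(c(3, 3, 3, 3, 2, 2, 2, 2, 2, 2), function(k) 2006L + 2L * (seq_len(k) - 1L))),
    race = rep(rep(c("NHW", "NHB"), 5), times = c(3, 3, 3, 3, 2, 2, 2, 2, 2, 2)),
    sex = rep(rep(c("male", "female"), 5), times = c(3, 3, 3, 3, 2, 2, 2, 2, 2, 2)),
    age = runif(n, 66, 85),
    grs = rep(runif(10, 0.05, 0.3), times = c(3, 3, 3, 3, 2, 2, 2, 2, 2, 2)),
    dementia_prob = rbinom(n, 1, 0.4),
    memory_score = rnorm(n, 1, 0.4),
    status = "observed"
  )
}
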
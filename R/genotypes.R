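#' Read genotype dosages for the score loci
#'
#' Reads per-person effect-allele dosages at the loci of a weight table, from
#' either a VCF (GT field) or a simple dosage TSV. For VCF input, each locus
#' is harmonized to the weight table's effect allele: the allele is matched
#' against REF, ALT, and their reverse complements (to recover strand flips),
#' and the dosage is counted accordingly. Palindromic (A/T or C/G) sites
#' cannot be strand-resolved and are excluded by default. Loci absent from
#' the file come back all-missing. The per-locus harmonization outcome is
#' attached as attribute `"harmonization"`.
#'
#' @param path File path.
#' @param weights Weight table (see [read_weight_table()]) naming the loci.
#' @param dialect `"dosage_tsv"` (persons as rows, rsID header columns,
#'   dosages 0/1/2 already counted on the effect allele, `NA` = missing) or
#'   `"vcf"`.
#' @param force_palindromic If `TRUE`, palindromic sites are taken on the
#'   written strand instead of being excluded.
#' @return A tibble with `person_id` and one 0/1/2 dosage column per locus of
#'   `weights`, with attribute `"harmonization"`: a tibble of
#'   `locus_id`, `status` (`ok_alt`, `ok_ref`, `flip_alt`, `flip_ref`,
#'   `palindromic_excluded`, `unresolvable`, `absent`, `assumed`).
#' @export
read_genotypes <- function(path, weights, dialect = c("dosage_tsv", "vcf"),
                           force_palindromic = FALSE) {
  dialect <- match.arg(dialect)
  weights <- validate_weight_table(weights)
  if (dialect == "dosage_tsv") read_dosage_tsv(path, weights)
  else read_vcf_genotypes(path, weights, force_palindromic = force_palindromic)
}

read_dosage_tsv <- function(path, weights) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("NA", ""))
  assert_cols(raw, "person_id", "Dosage table")
  found <- intersect(weights$locus_id, names(raw))
  if (!length(found)) abort("Dosage table covers none of the weight-table loci.")
  geno <- tibble(person_id = as.character(raw$person_id))
  for (loc in weights$locus_id) {
    geno[[loc]] <- if (loc %in% found) as.numeric(raw[[loc]]) else NA_real_
  }
  report <- tibble(
    locus_id = weights$locus_id,
    status = ifelse(weights$locus_id %in% found, "assumed", "absent")
  )
  structure(validate_genotypes(geno, weights), harmonization = report)
}

read_vcf_genotypes <- function(path, weights, force_palindromic = FALSE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  persons <- colnames(gt)
  geno <- tibble(person_id = as.character(persons))
  report <- vector("list", nrow(weights))

  for (k in seq_len(nrow(weights))) {
    loc <- weights$locus_id[k]
    ea <- weights$effect_allele[k]
    i <- which(fix$ID == loc)
    if (!length(i)) {
      geno[[loc]] <- NA_real_
      report[[k]] <- tibble(locus_id = loc, status = "absent")
      next
    }
    i <- i[1]
    ref <- toupper(fix$REF[i]); alt <- toupper(fix$ALT[i])
    if (!ref %in% NUC || !alt %in% NUC) {
      geno[[loc]] <- NA_real_
      report[[k]] <- tibble(locus_id = loc, status = "unresolvable")
      next
    }
    alt_count <- count_alt_alleles(gt[i, ])
    palindromic <- is_palindromic(ref, alt)
    status <-
      if (palindromic && !force_palindromic) "palindromic_excluded"
      else if (ea == alt) "ok_alt"
      else if (ea == ref) "ok_ref"
      else if (!palindromic && ea == complement_allele(alt)) "flip_alt"
      else if (!palindromic && ea == complement_allele(ref)) "flip_ref"
      else "unresolvable"
    geno[[loc]] <- switch(status,
      ok_alt = , flip_alt = alt_count,
      ok_ref = , flip_ref = 2 - alt_count,
      NA_real_
    )
    report[[k]] <- tibble(locus_id = loc, status = status)
  }
  report <- bind_rows(report)
  if (any(report$status == "palindromic_excluded")) {
    warn(sprintf(
      "Excluded palindromic (strand-ambiguous) locus/loci: %s. Use force_palindromic = TRUE to keep them on the written strand.",
      paste(report$locus_id[report$status == "palindromic_excluded"], collapse = ", ")
    ))
  }
  if (any(report$status == "unresolvable")) {
    warn(sprintf("Effect allele matches neither REF/ALT nor complements at: %s.",
                 paste(report$locus_id[report$status == "unresolvable"], collapse = ", ")))
  }
  structure(validate_genotypes(geno, weights), harmonization = report)
}

# allele counts from unphased or phased GT strings; any missing allele -> NA
count_alt_alleles <- function(gt) {
  alleles <- strsplit(gsub("\\|", "/", gt), "/", fixed = FALSE)
  unname(vapply(alleles, function(a) {
    if (length(a) == 0 || anyNA(a) || any(a == ".")) return(NA_real_)
    sum(a == "1")
  }, numeric(1)))
}

#' Validate (and order) a genotype dosage table against a weight table
#'
#' Checks that all dosages are 0, 1, 2 or missing and orders the locus columns
#' to the weight table. Applying it twice is a no-op, so harmonized input
#' passes through unchanged.
#'
#' @param genotypes Tibble with `person_id` and one dosage column per locus.
#' @param weights Weight table whose loci define the column set and order.
#' @return The validated tibble.
#' @export
validate_genotypes <- function(genotypes, weights) {
  weights <- validate_weight_table(weights)
  genotypes <- as_tibble(genotypes)
  assert_cols(genotypes, "person_id", "Genotype table")
  extra <- setdiff(names(genotypes), c("person_id", weights$locus_id))
  if (length(extra)) {
    abort(sprintf("Genotype table has loci not in the weight table: %s.",
                  paste(extra, collapse = ", ")))
  }
  for (loc in weights$locus_id) {
    if (!loc %in% names(genotypes)) genotypes[[loc]] <- NA_real_
    d <- genotypes[[loc]]
    if (any(!is.na(d) & !d %in% c(0, 1, 2))) {
      abort(sprintf("Dosages at %s must be 0, 1, 2 or missing.", loc))
    }
  }
  if (anyDuplicated(genotypes$person_id)) abort("Duplicate person_id in genotype table.")
  harm <- attr(genotypes, "harmonization")
  out <- genotypes[, c("person_id", weights$locus_id)]
  attr(out, "harmonization") <- harm
  out
}

#' Write a dosage TSV
#'
#' @param genotypes Genotype tibble (person_id plus locus columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  readr::write_tsv(as_tibble(genotypes), path, na = "NA")
  invisible(path)
}
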
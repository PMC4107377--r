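#' Read a risk-locus weight table
#'
#' Reads a delimited table of risk loci with, per locus, the effect allele and
#' either a per-allele log odds ratio (`beta`) or a published odds ratio
#' (`or`), from which `beta = log(or)` is derived. Extra columns (gene symbol,
#' a second allele, race-specific allele frequencies, an `apoe` flag) are kept
#' when present; the `apoe` flag marks the loci that jointly define APOE
#' epsilon-4 carriage (conventionally rs429358 and rs7412) so that the
#' APOE-excluded score variant can drop them as a unit.
#'
#' @param path Path to a tab- or comma-delimited file with a header. Column
#'   names are matched case-insensitively: `locus_id` (or `rsid`/`snp`),
#'   `effect_allele` (or `ea`), and at least one of `beta` / `or`.
#' @return A tibble with columns `locus_id`, `effect_allele`, `beta`,
#'   `source_or` (`NA` when only `beta` was supplied), `apoe` (logical), plus
#'   any extra columns from the file.
#' @examples
#' wt <- read_weight_table(adgrs_example("alzgene_weights_synthetic.tsv"))
#' wt
#' @export
read_weight_table <- function(path) {
  raw <- readr::read_delim(path, delim = guess_delim(path), show_col_types = FALSE,
                           progress = FALSE)
  names(raw) <- tolower(names(raw))
  nm <- names(raw)
  pick <- function(cands) cands[cands %in% nm][1]
  locus_col <- pick(c("locus_id", "rsid", "snp", "locus"))
  ea_col <- pick(c("effect_allele", "ea", "risk_allele"))
  if (is.na(locus_col) || is.na(ea_col)) {
    abort("Weight table must name a locus column (locus_id/rsid/snp) and an effect-allele column (effect_allele/ea).")
  }
  beta_col <- pick("beta")
  or_col <- pick(c("or", "odds_ratio", "source_or"))
  if (is.na(beta_col) && is.na(or_col)) {
    abort("Weight table must contain a `beta` or an `or` column.")
  }
  out <- tibble(
    locus_id = as.character(raw[[locus_col]]),
    effect_allele = toupper(as.character(raw[[ea_col]])),
    beta = if (!is.na(beta_col)) as.numeric(raw[[beta_col]]) else NA_real_,
    source_or = if (!is.na(or_col)) as.numeric(raw[[or_col]]) else NA_real_
  )
  out$apoe <- if ("apoe" %in% nm) as.logical(raw[["apoe"]]) else
    out$locus_id %in% c("rs429358", "rs7412")
  extra <- setdiff(nm, c(locus_col, ea_col, beta_col, or_col, "apoe"))
  for (cl in extra) out[[cl]] <- raw[[cl]]
  out$beta <- ifelse(is.na(out$beta), log(out$source_or), out$beta)
  validate_weight_table(out)
}

#' Validate a weight table
#'
#' Enforces the weight-table contract: unique locus IDs, ACGT effect alleles,
#' a finite `beta` for every locus, and `beta == log(source_or)` (within 1e-9)
#' whenever both are present.
#'
#' @param weights A data frame shaped like the output of [read_weight_table()].
#' @return The validated tibble, invisibly identical to the input.
#' @export
validate_weight_table <- function(weights) {
  weights <- as_tibble(weights)
  assert_cols(weights, c("locus_id", "effect_allele", "beta"), "Weight table")
  if (!"source_or" %in% names(weights)) weights$source_or <- NA_real_
  if (!"apoe" %in% names(weights)) {
    weights$apoe <- weights$locus_id %in% c("rs429358", "rs7412")
  }
  dup <- weights$locus_id[duplicated(weights$locus_id)]
  if (length(dup)) {
    abort(sprintf("Duplicate locus_id in weight table: %s.",
                  paste(unique(dup), collapse = ", ")))
  }
  bad <- !weights$effect_allele %in% NUC
  if (any(bad)) {
    abort(sprintf("Non-ACGT effect allele for locus %s.",
                  paste(weights$locus_id[bad], collapse = ", ")))
  }
  if (any(!is.finite(weights$beta))) {
    abort("Every locus needs a finite beta (or a positive odds ratio to derive it).")
  }
  both <- is.finite(weights$source_or) & is.finite(weights$beta)
  if (any(abs(weights$beta[both] - log(weights$source_or[both])) > 1e-9)) {
    abort("`beta` disagrees with log(`source_or`) beyond 1e-9.")
  }
  weights
}

#' Write a weight table
#'
#' @param weights Validated weight table.
#' @param path Output path; written tab-delimited with a stable column order.
#' @return `path`, invisibly.
#' @export
write_weight_table <- function(weights, path) {
  weights <- validate_weight_table(weights)
  lead <- c("locus_id", "effect_allele", "beta", "source_or", "apoe")
  readr::write_tsv(weights[, c(lead, setdiff(names(weights), lead))], path)
  invisible(path)
}

#' Locus IDs flagged as the APOE pair
#'
#' @param weights A weight table.
#' @return Character vector of locus IDs with `apoe == TRUE`.
#' @export
apoe_loci <- function(weights) {
  weights <- validate_weight_table(weights)
  weights$locus_id[isTRUE_vec(weights$apoe)]
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Bundled default weight table (synthetic stand-in)
#'
#' Returns the weight table shipped with the package:
#' the ten Alzheimer's loci conventionally combined into an AD genetic risk
#' score (APOE via rs429358/rs7412, plus BIN1, CLU, ABCA7, CR1, PICALM,
#' MS4A6A, CD33, MS4A4E and CD2AP), with odds ratios *representative of* the
#' AlzGene meta-analysis database circa January 2013. The file is a synthetic
#' stand-in -- the exact meta-analysed values are not redistributed here --
#' and is meant to be replaced by the user's own weight file for substantive
#' work. It also carries synthetic European-ancestry (`freq_nhw`) and
#' African-American (`freq_nhb`) effect-allele frequencies used as the
#' starting point for simulator calibration.
#'
#' @return A validated weight-table tibble.
#' @export
default_weight_table <- function() {
  read_weight_table(adgrs_example("alzgene_weights_synthetic.tsv"))
}

#' Path to a bundled example file
#'
#' @param file File name under the package's `extdata/` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a vector of file names).
#' @export
adgrs_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "adgrs"))
  } else {
    path <- system.file("extdata", file, package = "adgrs")
    if (path == "") abort(sprintf("No bundled file named '%s'.", file))
    path
  }
}

guess_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}
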
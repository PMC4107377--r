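#' Read a long-format cohort panel
#'
#' Reads one-row-per-person-wave phenotype records: demographics, the
#' continuous dementia-probability outcome (only defined at ages 65+, where
#' the underlying cognitive instrument is administered), a standardized memory
#' score, and an observation status. Rows carrying a dementia probability
#' before age 65 violate the instrument's definition and are dropped with a
#' message (their count is attached as attribute `"n_rejected"`); structural
#' violations (duplicate person-waves, out-of-range probabilities) are errors.
#'
#' @param path CSV or TSV file with columns `person_id`, `wave_year`, `race`
#'   (NHW/NHB), `sex` (male/female), `age`, `dementia_prob`, `memory_score`,
#'   `status` (observed/nonresponse/dead).
#' @return A validated panel tibble.
#' @export
read_panel <- function(path) {
  raw <- readr::read_delim(path, delim = guess_delim(path),
                           show_col_types = FALSE, progress = FALSE,
                           na = c("NA", ""))
  validate_panel(raw)
}

#' Validate a cohort panel
#'
#' @param panel Data frame of person-wave records (see [read_panel()]).
#' @return Validated tibble with attribute `"n_rejected"` counting dropped
#'   under-65 dementia-probability rows.
#' @export
validate_panel <- function(panel) {
  panel <- as_tibble(panel)
  assert_cols(panel, c("person_id", "wave_year", "race", "sex", "age"), "Panel")
  for (cl in c("dementia_prob", "memory_score")) {
    if (!cl %in% names(panel)) panel[[cl]] <- NA_real_
  }
  if (!"status" %in% names(panel)) panel$status <- "observed"
  panel$person_id <- as.character(panel$person_id)
  panel$wave_year <- as.integer(panel$wave_year)

  if (anyDuplicated(panel[, c("person_id", "wave_year")])) {
    abort("Panel has more than one record for the same person and wave.")
  }
  if (any(!panel$race %in% c("NHW", "NHB"))) abort("`race` must be NHW or NHB.")
  if (any(!panel$sex %in% c("male", "female"))) abort("`sex` must be male or female.")
  if (any(!panel$status %in% c("observed", "nonresponse", "dead"))) {
    abort("`status` must be observed, nonresponse or dead.")
  }
  if (any(panel$age < 50, na.rm = TRUE)) abort("Panel ages must be 50 or older.")
  dp <- panel$dementia_prob
  if (any(!is.na(dp) & (dp < 0 | dp > 1))) {
    abort("`dementia_prob` must lie in [0, 1].")
  }

  # dementia probability is undefined before age 65: reject those rows
  bad <- !is.na(panel$dementia_prob) & panel$age < 65
  n_rejected <- sum(bad)
  if (n_rejected > 0) {
    inform(sprintf("Dropped %d row(s) with a dementia probability recorded before age 65.",
                   n_rejected))
    panel <- panel[!bad, ]
  }

  # death is absorbing
  dead_rows <- filter(panel, .data$status == "dead")
  if (nrow(dead_rows)) {
    died <- dead_rows %>%
      group_by(.data$person_id) %>%
      summarise(first_dead = min(.data$wave_year), .groups = "drop")
    revived <- panel %>%
      left_join(died, by = "person_id") %>%
      filter(!is.na(.data$first_dead),
             .data$wave_year > .data$first_dead,
             .data$status != "dead")
    if (nrow(revived)) {
      abort("Death must be absorbing: records after a 'dead' wave must remain 'dead'.")
    }
  }
  out <- arrange(panel, .data$person_id, .data$wave_year)
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write a cohort panel
#'
#' @param panel Validated panel tibble.
#' @param path Output CSV path (stable column order).
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  lead <- c("person_id", "wave_year", "race", "sex", "age",
            "dementia_prob", "memory_score", "status")
  panel <- as_tibble(panel)
  readr::write_csv(panel[, c(lead, setdiff(names(panel), lead))], path, na = "NA")
  invisible(path)
}
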
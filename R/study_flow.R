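#' Apply an ordered exclusion cascade to a table of observations
#'
#' Reproduces CONSORT-style sample accounting: rules are applied
#' sequentially, each removing the rows (observations) that match its
#' predicate among the rows still remaining, so every observation is counted
#' at the first rule it fails. Percentages are recomputed from the integer
#' counts against the pre-cascade denominator and rounded to one decimal.
#'
#' @param data Tibble of candidate observations (e.g. a person-wave panel).
#' @param rules Named list of predicates -- one-sided formulas such as
#'   `~ age < 65`, or functions of the data returning a logical vector.
#'   `NA` predicate values count as not matching.
#' @return Tibble of class `exclusion_report` with one row per rule:
#'   `stage`, `n_removed`, `pct_removed`, `n_remaining`. The surviving rows
#'   (the analysis set) are attached as attribute `"kept"`.
#' @examples
#' panel <- tibble::tibble(age = c(60, 70, 80), status = c("observed", "dead", "observed"))
#' run_exclusion_cascade(panel, list(
#'   under_65 = ~ age < 65,
#'   dead = ~ status == "dead"
#' ))
#' @export
run_exclusion_cascade <- function(data, rules) {
  data <- as_tibble(data)
  if (length(rules) && is.null(names(rules))) abort("`rules` must be named.")
  n0 <- nrow(data)
  remaining <- data
  out <- vector("list", length(rules))
  for (i in seq_along(rules)) {
    rule <- rules[[i]]
    pred <- if (is_formula(rule)) {
      f <- rule
      vars <- all.vars(f)
      missing <- setdiff(vars, names(remaining))
      if (length(missing)) {
        abort(sprintf("Rule '%s' references missing column(s): %s.",
                      names(rules)[i], paste(missing, collapse = ", ")))
      }
      rlang::eval_tidy(rlang::f_rhs(f), data = remaining)
    } else {
      as_function(rule)(remaining)
    }
    pred <- !is.na(pred) & pred
    n_removed <- sum(pred)
    remaining <- remaining[!pred, , drop = FALSE]
    out[[i]] <- tibble(
      stage = names(rules)[i],
      n_removed = as.integer(n_removed),
      pct_removed = pct_of(n_removed, n0),
      n_remaining = nrow(remaining)
    )
  }
  report <- bind_rows(out)
  if (!length(rules)) {
    report <- tibble(stage = character(), n_removed = integer(),
                     pct_removed = numeric(), n_remaining = integer())
  }
  structure(report, kept = remaining, n_initial = n0,
            class = c("exclusion_report", class(report)))
}

#' Percentage of a denominator, recomputed from integer counts
#'
#' The cascade's percentage arithmetic: `round(100 * n / total, 1)`. Exposed
#' so retention fractions (e.g. persons kept out of a source sample) use the
#' identical rounding rule as the per-stage percentages.
#'
#' @param n Integer count.
#' @param total Integer denominator.
#' @return Percentage rounded to one decimal.
#' @export
pct_of <- function(n, total) {
  if (total <= 0) abort("`total` must be positive.")
  round(100 * n / total, 1)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("<exclusion_report> %d candidate observations, %d remaining\n",
              attr(x, "n_initial"),
              if (nrow(x)) x$n_remaining[nrow(x)] else attr(x, "n_initial")))
  print(as_tibble(x), ...)
  invisible(x)
}
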
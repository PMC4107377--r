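# internal helpers shared across modules

NUC <- c("A", "C", "G", "T")

complement_allele <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[x])
}

is_palindromic <- function(a1, a2) {
  !is.na(a1) & !is.na(a2) & complement_allele(a1) == a2
}

assert_scalar_prob <- function(x, what, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", what))
  }
  ok <- if (open) x > 0 && x < 1 else x >= 0 && x <= 1
  if (!ok) abort(sprintf("`%s` must lie in %s.", what, if (open) "(0, 1)" else "[0, 1]"))
  invisible(x)
}

assert_cols <- function(df, cols, where) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s.",
                  where, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# inverse-CDF truncated normal draw, vectorised
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  stats::qnorm(runif(n, plo, phi), mean, sd)
}
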
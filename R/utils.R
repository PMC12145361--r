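#' @importFrom rlang abort warn .data %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows bind_cols left_join pull n across
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map_chr map_lgl imap walk
#' @importFrom stats var sd rnorm setNames pt qtukey ptukey
NULL

# row-wise variance of a matrix with (n - 1) denominator; 0 rows of variance
# guarded upstream
row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2) {
    return(rep(NA_real_, nrow(m)))
  }
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

assert_positive_int <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x < 1 || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single positive integer (got %s).", name, deparse(x)),
          class = "stretchsig_validation_error")
  }
  invisible(as.integer(x))
}

assert_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be finite and nonnegative.", name),
          class = "stretchsig_validation_error")
  }
  invisible(x)
}

# deterministic child seed derived from a base seed, kept within 32-bit range
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% .Machine$integer.max)
}
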
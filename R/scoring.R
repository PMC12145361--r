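#' A transcriptomic signature: disjoint up- and down-regulated feature sets
#'
#' @param up,down Character vectors of feature ids; disjoint, union
#'   non-empty. One-sided signatures (empty `up` or empty `down`) are valid.
#' @param label Signature label.
#' @return A `signature_set` object.
#' @export
signature_set <- function(up = character(), down = character(),
                          label = "signature") {
  up <- sort(unique(as.character(up)))
  down <- sort(unique(as.character(down)))
  both <- intersect(up, down)
  if (length(both)) {
    abort(sprintf("feature(s) in both up and down sets: %s",
                  paste(both, collapse = ", ")),
          class = "stretchsig_validation_error")
  }
  if (!length(up) && !length(down)) {
    abort("a signature needs at least one feature.",
          class = "stretchsig_validation_error")
  }
  structure(list(up = up, down = down, label = label), class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set '%s'> %d up, %d down\n",
              x$label, length(x$up), length(x$down)))
  invisible(x)
}

#' Geometric mean of positive values
#'
#' `exp(mean(log(x)))`. Non-positive values are rejected: shift the
#' expression matrix into positive territory first (see [score_samples()],
#' which applies and records a single global shift when needed).
#'
#' @param values Positive numeric vector, non-empty.
#' @return The geometric mean.
#' @export
geometric_mean <- function(values) {
  if (!length(values)) {
    abort("`values` is empty.", class = "stretchsig_validation_error")
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    abort("geometric mean requires positive finite values; apply a positivity shift to the matrix first.",
          class = "stretchsig_validation_error")
  }
  exp(mean(log(values)))
}

#' Transcriptomic score of a signature for each sample
#'
#' For each sample, the score is the geometric mean of the up-regulated
#' features' expression minus the geometric mean of the down-regulated
#' features' expression. An empty up or down set contributes 0, so one-sided
#' signatures score as plain geometric means. If any expression value needed
#' by the signature is non-positive, a single global shift of
#' `1 - min(matrix)` is added to the whole matrix first and recorded in the
#' result (per-sample shifts would distort between-sample comparisons).
#'
#' @param pooled A `pooled_matrix`, an [expr_study()], or a features x
#'   samples matrix (then `samples` may supply annotations).
#' @param sig A [signature_set()]; all its features must be present.
#' @param samples Optional annotation tibble for bare matrices.
#' @return A `score_report` tibble: `sample_id`, `study_id`, `score`,
#'   `stretch`, `second_hit`, `magnitude`; attribute `shift` records the
#'   positivity shift applied (0 if none).
#' @export
score_samples <- function(pooled, sig, samples = NULL) {
  if (inherits(pooled, "pooled_matrix") || inherits(pooled, "expr_study")) {
    samples <- pooled$samples
    Y <- pooled$expr
  } else {
    Y <- pooled
  }
  if (!inherits(sig, "signature_set")) {
    abort("`sig` must be a signature_set.", class = "stretchsig_validation_error")
  }
  feats <- c(sig$up, sig$down)
  missing_f <- setdiff(feats, rownames(Y))
  if (length(missing_f)) {
    abort(sprintf("signature feature(s) absent from the matrix: %s",
                  paste(missing_f, collapse = ", ")),
          class = "stretchsig_missing_features")
  }
  shift <- 0
  if (any(Y[feats, , drop = FALSE] <= 0)) {
    shift <- 1 - min(Y)
    Y <- Y + shift
  }
  score <- score_from_logs(log(Y[feats, , drop = FALSE]), sig)
  out <- tibble(
    sample_id = colnames(Y) %||% as.character(seq_len(ncol(Y))),
    study_id = if (!is.null(samples)) samples$study_id else NA_character_,
    score = score,
    stretch = if (!is.null(samples)) samples$stretch else NA_integer_,
    second_hit = if (!is.null(samples)) samples$second_hit else NA_integer_,
    magnitude = if (!is.null(samples)) samples$magnitude else NA_real_
  )
  class(out) <- c("score_report", class(out))
  attr(out, "shift") <- shift
  attr(out, "signature") <- sig$label
  out
}

# score from a log-expression matrix: exp(col means of up rows) minus
# exp(col means of down rows); empty side contributes 0
score_from_logs <- function(logY, sig) {
  gm_side <- function(feats) {
    if (!length(feats)) return(0)
    exp(colMeans(logY[feats, , drop = FALSE]))
  }
  unname(gm_side(sig$up) - gm_side(sig$down))
}
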
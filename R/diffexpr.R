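#' Two-factor linear model for one feature
#'
#' Ordinary least squares of one feature's expression on an intercept, a
#' stretch indicator and a second-hit indicator (main effects only), with
#' two-sided t-tests on the residual degrees of freedom. If the second-hit
#' indicator is constant the model reduces to intercept + stretch. Degenerate
#' designs (zero residual degrees of freedom, perfect collinearity of the two
#' factors, zero residual variance) yield `tested = FALSE` with `NA`
#' p-values rather than an error.
#'
#' @param y Numeric expression values, one per sample.
#' @param stretch,second_hit 0/1 indicators, same length as `y`.
#' @return A one-row tibble: `beta_stretch`, `beta_hit`, `p_stretch`,
#'   `p_hit`, `direction` (sign of the stretch coefficient), `tested`.
#' @export
fit_feature_model <- function(y, stretch, second_hit) {
  if (length(stretch) != length(y) || length(second_hit) != length(y)) {
    abort("`y`, `stretch` and `second_hit` must have equal length.",
          class = "stretchsig_validation_error")
  }
  de_fit_matrix(matrix(y, nrow = 1, dimnames = list("feature", NULL)),
                stretch, second_hit)[, -1]
}

# vectorized OLS across features: Y is features x samples
de_fit_matrix <- function(Y, stretch, second_hit) {
  stretch <- as.numeric(stretch)
  second_hit <- as.numeric(second_hit)
  if (length(unique(stretch)) < 2) {
    abort("`stretch` must take both values 0 and 1.",
          class = "stretchsig_validation_error")
  }
  hit_varies <- length(unique(second_hit)) > 1
  collinear <- hit_varies && qr(cbind(1, stretch, second_hit))$rank < 3

  n <- ncol(Y)
  p <- nrow(Y)
  untested_all <- collinear
  X <- if (hit_varies && !collinear) cbind(1, stretch, second_hit) else cbind(1, stretch)
  q <- ncol(X)
  df <- n - q

  beta_s <- rep(NA_real_, p); beta_h <- rep(NA_real_, p)
  p_s <- rep(NA_real_, p); p_h <- rep(NA_real_, p)
  tested <- rep(FALSE, p)

  if (!untested_all && df > 0) {
    XtX_inv <- solve(crossprod(X))
    B <- XtX_inv %*% t(X) %*% t(Y)            # q x p
    resid <- t(Y) - X %*% B
    s2 <- colSums(resid^2) / df
    tested <- s2 > 0
    se_s <- sqrt(s2 * XtX_inv[2, 2])
    beta_s <- B[2, ]
    t_s <- beta_s / se_s
    p_s <- ifelse(tested, 2 * pt(abs(t_s), df, lower.tail = FALSE), NA_real_)
    if (q == 3) {
      se_h <- sqrt(s2 * XtX_inv[3, 3])
      beta_h <- B[3, ]
      p_h <- ifelse(tested, 2 * pt(abs(beta_h / se_h), df, lower.tail = FALSE), NA_real_)
    }
    beta_s[!tested] <- B[2, !tested]  # coefficients still defined (often 0)
  }

  tibble(
    feature_id = rownames(Y) %||% as.character(seq_len(p)),
    beta_stretch = as.numeric(beta_s),
    beta_hit = as.numeric(beta_h),
    p_stretch = as.numeric(p_s),
    p_hit = as.numeric(p_h),
    direction = ifelse(tested, ifelse(beta_s >= 0, "up", "down"), NA_character_),
    tested = tested
  )
}

#' Benjamini-Hochberg adjustment with validation and NA bookkeeping
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1, original
#' order preserved). `NA` entries are excluded from the family size and
#' returned as `NA`.
#'
#' @param pvals Numeric p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(pvals) {
  if (!is.numeric(pvals)) {
    abort("`pvals` must be numeric.", class = "stretchsig_validation_error")
  }
  bad <- !is.na(pvals) & (pvals < 0 | pvals > 1 | !is.finite(pvals))
  if (any(bad)) {
    abort(sprintf("p-value(s) outside [0, 1] at position(s): %s",
                  paste(utils::head(which(bad), 5), collapse = ", ")),
          class = "stretchsig_validation_error")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Per-feature differential expression on a pooled matrix
#'
#' Fits the two-factor stretch + second-hit linear model to every feature of
#' a co-normalized pooled matrix and adjusts p-values with
#' Benjamini-Hochberg, separately within each coefficient's family (stretch
#' p-values together; second-hit p-values together). Untested features
#' (degenerate fits) are excluded from the adjustment families.
#'
#' @param pooled A `pooled_matrix` from [coconut()], or a features x samples
#'   matrix if `samples` is supplied.
#' @param samples Optional annotation tibble when `pooled` is a bare matrix.
#' @return A `DETable` tibble: `feature_id`, `beta_stretch`, `beta_hit`,
#'   `p_stretch`, `p_hit`, `padj_stretch`, `padj_hit`, `direction`, `tested`.
#' @export
run_de <- function(pooled, samples = NULL) {
  if (inherits(pooled, "pooled_matrix")) {
    samples <- pooled$samples
    Y <- pooled$expr
  } else {
    Y <- pooled
    if (is.null(samples)) {
      abort("`samples` annotations are required when `pooled` is a bare matrix.",
            class = "stretchsig_validation_error")
    }
  }
  de <- de_fit_matrix(Y, samples$stretch, samples$second_hit)
  de$padj_stretch <- adjust_bh(de$p_stretch)
  de$padj_hit <- adjust_bh(de$p_hit)
  de[, c("feature_id", "beta_stretch", "beta_hit", "p_stretch", "p_hit",
         "padj_stretch", "padj_hit", "direction", "tested")]
}

#' Threshold-based signature selection from a differential-expression table
#'
#' Selects features whose adjusted stretch p-value falls below `alpha`:
#' positive coefficients go to the up-regulated set, negative to the
#' down-regulated set. With `stretch_only = TRUE`, features that are also
#' significant for the second-hit factor (adjusted hit p-value below `alpha`)
#' are excluded, isolating the stretch-specific partition.
#'
#' @param de A `DETable` from [run_de()].
#' @param alpha Adjusted-p threshold (miRNA analyses conventionally use 0.1,
#'   gene analyses 0.01).
#' @param stretch_only Exclude features also significant for the second hit.
#' @param label Signature label.
#' @return A [signature_set()] with attribute `counts`: number of
#'   stretch-only, hit-only and both-significant features.
#' @export
select_signature <- function(de, alpha, stretch_only = FALSE,
                             label = "de_signature") {
  if (!nrow(de)) {
    abort("`de` is empty.", class = "stretchsig_validation_error")
  }
  if (length(alpha) != 1 || !is.finite(alpha) || alpha <= 0 || alpha > 1) {
    abort("`alpha` must be a single value in (0, 1].",
          class = "stretchsig_validation_error")
  }
  sig_stretch <- !is.na(de$padj_stretch) & de$padj_stretch < alpha
  sig_hit <- !is.na(de$padj_hit) & de$padj_hit < alpha
  counts <- c(
    stretch_only = sum(sig_stretch & !sig_hit),
    hit_only = sum(sig_hit & !sig_stretch),
    both = sum(sig_stretch & sig_hit)
  )
  keep <- if (stretch_only) sig_stretch & !sig_hit else sig_stretch
  up <- de$feature_id[keep & de$beta_stretch > 0]
  down <- de$feature_id[keep & de$beta_stretch < 0]
  if (!length(up) && !length(down)) {
    abort(
      sprintf(
        "no feature passes alpha = %g (stretch-only: %d, hit-only: %d, both: %d).",
        alpha, counts[["stretch_only"]], counts[["hit_only"]], counts[["both"]]
      ),
      class = "stretchsig_empty_signature"
    )
  }
  out <- signature_set(up = up, down = down, label = label)
  attr(out, "counts") <- counts
  out
}

#' Restrict a feature set to miRNA targets
#'
#' Intersects `features` with the union of target sets of the given miRNAs.
#' Unknown miRNA ids raise a warning and are skipped.
#'
#' @param features Character vector of gene ids.
#' @param target_map Tibble with columns `mirna_id`, `gene_id` (see
#'   [read_target_map_tsv()]).
#' @param mirnas miRNA ids whose targets define the restriction.
#' @return Sorted character vector: `features` that are targets of `mirnas`.
#' @export
filter_by_targets <- function(features, target_map, mirnas) {
  if (!all(c("mirna_id", "gene_id") %in% names(target_map))) {
    abort("`target_map` needs columns `mirna_id` and `gene_id`.",
          class = "stretchsig_validation_error")
  }
  unknown <- setdiff(mirnas, unique(target_map$mirna_id))
  if (length(unknown)) {
    warn(sprintf("miRNA id(s) not in target map, skipped: %s",
                 paste(unknown, collapse = ", ")))
  }
  targets <- unique(target_map$gene_id[target_map$mirna_id %in% mirnas])
  sort(intersect(features, targets))
}
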
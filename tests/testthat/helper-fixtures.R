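# Shared fixtures, all built in code.

# a small hand-made study: deterministic values, optional case offset on
# selected features
make_tiny_study <- function(study_id = "s1", n_features = 6, n_ctrl = 3,
                            n_case = 3, offset = 0, case_features = NULL,
                            shift = 0, seed = 42) {
  set.seed(seed)
  n <- n_ctrl + n_case
  feat <- sprintf("f%02d", seq_len(n_features))
  m <- matrix(rnorm(n_features * n, mean = 8, sd = 1), n_features, n,
              dimnames = list(feat, sprintf("%s_%02d", study_id, seq_len(n))))
  stretch <- c(rep(0L, n_ctrl), rep(1L, n_case))
  if (is.null(case_features)) case_features <- feat
  m[case_features, stretch == 1] <- m[case_features, stretch == 1] + offset
  m <- m + shift
  expr_study(
    study_id = study_id, expr = m,
    samples = tibble::tibble(
      sample_id = colnames(m), study_id = study_id,
      stretch = stretch, second_hit = 0L, magnitude = NA_real_
    )
  )
}

# no-noise pair: study B is study A shifted by +3 everywhere
shifted_pair_studies <- function(delta = 3) {
  base <- matrix(
    rep(c(5, 8, 10, 7), each = 6) + rep(c(0, 0, 0, 1, 1, 1), times = 4) * 2,
    nrow = 4, byrow = TRUE,
    dimnames = list(sprintf("f%02d", 1:4), sprintf("a_%02d", 1:6))
  )
  # add deterministic within-group spread so control variances are nonzero
  spread <- matrix(rep(c(-0.5, 0, 0.5), times = 2 * 4), nrow = 4, byrow = TRUE)
  base <- base + spread
  samples_a <- tibble::tibble(
    sample_id = colnames(base), study_id = "A",
    stretch = c(0L, 0L, 0L, 1L, 1L, 1L), second_hit = 0L,
    magnitude = NA_real_
  )
  b <- base + delta
  colnames(b) <- sprintf("b_%02d", 1:6)
  samples_b <- samples_a
  samples_b$sample_id <- colnames(b)
  samples_b$study_id <- "B"
  list(
    a = expr_study("A", base, samples_a),
    b = expr_study("B", b, samples_b)
  )
}

# independent brute-force Benjamini-Hochberg step-up (double loop over the
# definition: adj_i = min(1, min over j with rank >= rank_i of m/rank_j * p_j))
bh_brute_force <- function(p) {
  keep <- !is.na(p)
  pv <- p[keep]
  m <- length(pv)
  r <- rank(pv, ties.method = "first")
  adj <- vapply(seq_len(m), function(i) {
    min(1, min((m / r[r >= r[i]]) * pv[r >= r[i]]))
  }, numeric(1))
  out <- rep(NA_real_, length(p))
  out[keep] <- adj
  out
}

# exhaustive pair-counting AUROC (ties = 1/2)
auroc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}
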
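#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The fraction of (positive, negative) sample pairs in which the positive
#' sample's score exceeds the negative's, with ties counted as 1/2 —
#' computed via mid-ranks in O(n log n).
#'
#' @param scores Numeric scores.
#' @param labels 0/1 class labels (1 = stretched / positive).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal length.",
          class = "stretchsig_validation_error")
  }
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("both classes must be present to compute an AUROC.",
          class = "stretchsig_single_class")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' AUROC with a stratified-bootstrap confidence interval
#'
#' Resamples positives and negatives with replacement within class `B`
#' times and reports the percentile interval of the bootstrap AUROCs.
#'
#' @inheritParams auroc
#' @param B Bootstrap replicates (at least 100; default 2000).
#' @param seed Integer seed (the result is deterministic given it).
#' @param conf Confidence level (default 0.95).
#' @return An `auroc_result`: `auroc`, `ci_low`, `ci_high`, `n_pos`,
#'   `n_neg`, `B`, `conf`, `seed`.
#' @export
auroc_ci <- function(scores, labels, B = 2000, seed = 1L, conf = 0.95) {
  if (B < 100) {
    abort("`B` must be at least 100.", class = "stretchsig_validation_error")
  }
  labels <- as.integer(labels)
  point <- auroc(scores, labels)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  set.seed(seed)
  boots <- vapply(seq_len(B), function(b) {
    s <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    l <- c(rep(1L, length(pos)), rep(0L, length(neg)))
    auroc(s, l)
  }, numeric(1))
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE, type = 7)
  structure(
    list(auroc = point, ci_low = qs[1], ci_high = qs[2],
         n_pos = length(pos), n_neg = length(neg),
         B = as.integer(B), conf = conf, seed = as.integer(seed)),
    class = "auroc_result"
  )
}

#' @export
print.auroc_result <- function(x, ...) {
  cat(sprintf("AUROC %.3f (%g%% CI %.3f-%.3f), %d positives vs %d negatives, B = %d\n",
              x$auroc, 100 * x$conf, x$ci_low, x$ci_high, x$n_pos, x$n_neg, x$B))
  invisible(x)
}

#' Random-signature null distribution of the AUROC
#'
#' Draws `B` random signatures with the same up/down split sizes as the
#' evaluated signature (disjoint sets, uniform without replacement), scores
#' each and computes its AUROC against the given labels. The exceedance
#' probability at `threshold` estimates how often a random signature of this
#' size performs at least as well.
#'
#' @param pooled A `pooled_matrix` or features x samples matrix.
#' @param labels 0/1 stretch labels (defaults to the pooled annotations).
#' @param k_up,k_down Sizes of the random up/down sets.
#' @param B Number of random signatures (default 1000).
#' @param seed Integer seed.
#' @param threshold AUROC threshold for the exceedance probability
#'   (default 0.9).
#' @return A `null_dist`: vector of null AUROCs, sizes, threshold,
#'   `exceedance = mean(null >= threshold)`, seed.
#' @export
random_signature_null <- function(pooled, labels = NULL, k_up, k_down = 0,
                                  B = 1000, seed = 1L, threshold = 0.9) {
  if (inherits(pooled, "pooled_matrix")) {
    if (is.null(labels)) labels <- pooled$samples$stretch
    Y <- pooled$expr
  } else {
    Y <- pooled
    if (is.null(labels)) {
      abort("`labels` are required with a bare matrix.",
            class = "stretchsig_validation_error")
    }
  }
  labels <- as.integer(labels)
  feats <- rownames(Y)
  if (k_up + k_down > length(feats)) {
    abort(sprintf("k_up + k_down = %d exceeds the %d available features.",
                  k_up + k_down, length(feats)),
          class = "stretchsig_validation_error")
  }
  if (k_up + k_down < 1) {
    abort("`k_up + k_down` must be at least 1.",
          class = "stretchsig_validation_error")
  }
  shift <- if (any(Y <= 0)) 1 - min(Y) else 0
  logY <- log(Y + shift)
  set.seed(seed)
  nulls <- vapply(seq_len(B), function(b) {
    draw <- sample(feats, k_up + k_down)
    up <- draw[seq_len(k_up)]
    down <- if (k_down > 0) draw[k_up + seq_len(k_down)] else character()
    up_term <- if (k_up > 0) exp(colMeans(logY[up, , drop = FALSE])) else 0
    down_term <- if (k_down > 0) exp(colMeans(logY[down, , drop = FALSE])) else 0
    auroc(up_term - down_term, labels)
  }, numeric(1))
  structure(
    list(null_aurocs = nulls, k_up = as.integer(k_up),
         k_down = as.integer(k_down), B = as.integer(B),
         threshold = threshold, exceedance = mean(nulls >= threshold),
         seed = as.integer(seed)),
    class = "null_dist"
  )
}

#' @export
print.null_dist <- function(x, ...) {
  cat(sprintf(
    "<null_dist> B = %d random signatures (%d up / %d down): median AUROC %.3f, P(AUROC >= %g) = %.4g\n",
    x$B, x$k_up, x$k_down, stats::median(x$null_aurocs), x$threshold, x$exceedance
  ))
  invisible(x)
}

#' Leave-one-study-out robustness of a signature's AUROC
#'
#' For each study in turn, re-pools the remaining studies with a full
#' control-anchored co-normalization re-fit, scores the signature and
#' computes the AUROC with a bootstrap CI. Rounds in which only one class
#' remains are flagged (`NA` AUROC), not fatal.
#'
#' @param studies List of [expr_study()] objects (at least 2).
#' @param sig A [signature_set()].
#' @param eb,tol,max_iter Co-normalization settings (see [coconut()]).
#' @param B,seed,conf Bootstrap CI settings (see [auroc_ci()]).
#' @return A tibble with one row per excluded study: `excluded_study`,
#'   `auroc`, `ci_low`, `ci_high`, `n_pos`, `n_neg`, `flagged`.
#' @export
leave_one_study_out <- function(studies, sig, eb = TRUE, tol = 1e-6,
                                max_iter = 200, B = 500, seed = 1L,
                                conf = 0.95) {
  ids <- check_studies(studies)
  if (length(studies) < 2) {
    abort("leave-one-study-out needs at least 2 studies.",
          class = "stretchsig_validation_error")
  }
  rows <- map(seq_along(studies), function(i) {
    rest <- studies[-i]
    pooled <- coconut(rest, eb = eb, tol = tol, max_iter = max_iter)
    labels <- pooled$samples$stretch
    if (length(unique(labels)) < 2) {
      return(tibble(excluded_study = ids[i], auroc = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_,
                    n_pos = sum(labels == 1), n_neg = sum(labels == 0),
                    flagged = TRUE))
    }
    sc <- score_samples(pooled, sig)
    res <- auroc_ci(sc$score, labels, B = B, seed = child_seed(seed, i),
                    conf = conf)
    tibble(excluded_study = ids[i], auroc = res$auroc,
           ci_low = res$ci_low, ci_high = res$ci_high,
           n_pos = res$n_pos, n_neg = res$n_neg, flagged = FALSE)
  })
  bind_rows(rows)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks (average ranks for ties); the two-sided
#' p-value uses the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`
#' on `n - 2` degrees of freedom.
#'
#' @param x,y Paired numeric vectors (at least 3 finite pairs).
#' @return A tibble: `rho`, `p.value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) {
    abort("at least 3 paired finite values are required.",
          class = "stretchsig_validation_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("rho is undefined when either vector has zero variance.",
          class = "stretchsig_validation_error")
  }
  rho <- stats::cor(rank(x, ties.method = "average"),
                    rank(y, ties.method = "average"))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
  }
  tibble(rho = rho, p.value = p, n = n)
}

#' Compare transcriptomic scores among groups
#'
#' Two groups: two-sided pooled-variance t-test. More than two groups:
#' one-way ANOVA; if the ANOVA p-value is below 0.05, all pairwise
#' comparisons with Tukey's honest significant difference via the
#' studentized-range distribution.
#'
#' @param scores Numeric scores.
#' @param groups Group labels (factor or character), each group with at
#'   least 2 samples.
#' @return A `group_comparison` list: `method` (`"t_test"` or `"anova"`),
#'   `statistic`, `p.value`, and for ANOVA a `tukey` tibble (`comparison`,
#'   `diff`, `ci_low`, `ci_high`, `p.adj`), `NULL` when the ANOVA gate is
#'   not passed.
#' @export
compare_groups <- function(scores, groups) {
  groups <- factor(groups)
  if (length(scores) != length(groups)) {
    abort("`scores` and `groups` must have equal length.",
          class = "stretchsig_validation_error")
  }
  tab <- table(groups)
  if (length(tab) < 2) {
    abort("at least 2 groups are required.", class = "stretchsig_validation_error")
  }
  if (any(tab < 2)) {
    abort(sprintf("group(s) with fewer than 2 samples: %s",
                  paste(names(tab)[tab < 2], collapse = ", ")),
          class = "stretchsig_validation_error")
  }
  if (length(tab) == 2) {
    ht <- stats::t.test(scores ~ groups, var.equal = TRUE)
    out <- list(method = "t_test", statistic = unname(ht$statistic),
                p.value = ht$p.value, df = unname(ht$parameter), tukey = NULL)
  } else {
    fit <- stats::aov(scores ~ groups)
    s <- summary(fit)[[1]]
    pval <- s[["Pr(>F)"]][1]
    tukey <- NULL
    if (is.finite(pval) && pval < 0.05) {
      tk <- stats::TukeyHSD(fit)$groups
      tukey <- tibble(
        comparison = rownames(tk), diff = tk[, "diff"],
        ci_low = tk[, "lwr"], ci_high = tk[, "upr"], p.adj = tk[, "p adj"]
      )
    }
    out <- list(method = "anova", statistic = s[["F value"]][1],
                p.value = pval, df = s[["Df"]], tukey = tukey)
  }
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic %.4g, p = %.4g\n",
              x$method, x$statistic, x$p.value))
  if (!is.null(x$tukey)) {
    cat(sprintf("  Tukey HSD: %d pairwise comparisons\n", nrow(x$tukey)))
  }
  invisible(x)
}

#' Full evaluation report for a signature on pooled data
#'
#' Bundles the accuracy and robustness analyses: AUROC with bootstrap CI,
#' random-signature null with exceedance probability, optional
#' leave-one-study-out (when the original studies are supplied), Spearman
#' correlation of the score with stretch magnitude (when available), and a
#' group comparison across the control / stretch / second-hit /
#' stretch+second-hit partition.
#'
#' @param pooled A `pooled_matrix`.
#' @param sig A [signature_set()].
#' @param studies Optional list of the original [expr_study()] objects,
#'   enabling leave-one-study-out.
#' @param B Bootstrap and null replicates (default 1000).
#' @param seed Integer seed.
#' @param null_threshold AUROC threshold for the null exceedance
#'   (default 0.9).
#' @param eb,tol,max_iter Co-normalization settings for the leave-one-out
#'   re-fits.
#' @return An `evaluation_report` list; see [tidy.evaluation_report()] and
#'   [glance.evaluation_report()].
#' @export
evaluate_signature <- function(pooled, sig, studies = NULL, B = 1000,
                               seed = 1L, null_threshold = 0.9, eb = TRUE,
                               tol = 1e-6, max_iter = 200) {
  sc <- score_samples(pooled, sig)
  labels <- pooled$samples$stretch
  acc <- auroc_ci(sc$score, labels, B = B, seed = child_seed(seed, 101L))
  nul <- random_signature_null(
    pooled, labels, k_up = length(sig$up), k_down = length(sig$down),
    B = B, seed = child_seed(seed, 102L), threshold = null_threshold
  )
  loso <- NULL
  if (!is.null(studies) && length(studies) >= 2) {
    loso <- leave_one_study_out(studies, sig, eb = eb, tol = tol,
                                max_iter = max_iter, B = max(100L, B %/% 2L),
                                seed = child_seed(seed, 103L))
  }
  spear <- NULL
  stretched <- labels == 1
  if (any(stretched) && !all(is.na(sc$magnitude))) {
    mag <- ifelse(is.na(sc$magnitude), 0, sc$magnitude)
    if (sd(mag) > 0) spear <- spearman_cor(sc$score, mag)
  }
  grp <- interaction(pooled$samples$stretch, pooled$samples$second_hit,
                     drop = TRUE)
  levels(grp) <- sub("^0\\.0$", "control",
                 sub("^1\\.0$", "stretch",
                 sub("^0\\.1$", "second_hit",
                 sub("^1\\.1$", "stretch_second_hit", levels(grp)))))
  groups_test <- if (nlevels(grp) >= 2 && all(table(grp) >= 2)) {
    compare_groups(sc$score, grp)
  }
  structure(
    list(signature = sig, scores = sc, auroc = acc, null = nul,
         leave_one_out = loso, magnitude_correlation = spear,
         group_comparison = groups_test, B = as.integer(B),
         seed = as.integer(seed)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> signature '%s' (%d up / %d down)\n",
              x$signature$label, length(x$signature$up), length(x$signature$down)))
  print(x$auroc)
  print(x$null)
  if (!is.null(x$leave_one_out)) {
    cat(sprintf("  leave-one-study-out AUROC range: %.3f-%.3f over %d studies\n",
                min(x$leave_one_out$auroc, na.rm = TRUE),
                max(x$leave_one_out$auroc, na.rm = TRUE),
                nrow(x$leave_one_out)))
  }
  if (!is.null(x$magnitude_correlation)) {
    cat(sprintf("  score vs magnitude: Spearman rho %.3f (p = %.3g)\n",
                x$magnitude_correlation$rho, x$magnitude_correlation$p.value))
  }
  invisible(x)
}
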
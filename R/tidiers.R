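#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_boxplot geom_jitter
#'   geom_histogram geom_vline geom_line geom_point geom_step labs
#'   theme_minimal geom_abline coord_equal
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a signature into a two-column tibble
#'
#' @param x A [signature_set()].
#' @param ... Unused.
#' @return Tibble with `feature_id`, `direction`.
#' @method tidy signature_set
#' @export
tidy.signature_set <- function(x, ...) {
  tibble(
    feature_id = c(x$up, x$down),
    direction = c(rep("up", length(x$up)), rep("down", length(x$down)))
  )
}

#' @rdname tidy.signature_set
#' @method glance signature_set
#' @export
glance.signature_set <- function(x, ...) {
  tibble(label = x$label, n_up = length(x$up), n_down = length(x$down),
         n_features = length(x$up) + length(x$down))
}

#' Tidy an AUROC result
#'
#' @param x An `auroc_result` from [auroc_ci()].
#' @param ... Unused.
#' @return One-row tibble: `auroc`, `ci_low`, `ci_high`, `n_pos`, `n_neg`,
#'   `B`, `conf`.
#' @method tidy auroc_result
#' @export
tidy.auroc_result <- function(x, ...) {
  tibble(auroc = x$auroc, ci_low = x$ci_low, ci_high = x$ci_high,
         n_pos = x$n_pos, n_neg = x$n_neg, B = x$B, conf = x$conf)
}

#' Tidy a random-signature null distribution
#'
#' @param x A `null_dist` from [random_signature_null()].
#' @param ... Unused.
#' @return Tibble with one row per draw (`draw`, `auroc`).
#' @method tidy null_dist
#' @export
tidy.null_dist <- function(x, ...) {
  tibble(draw = seq_along(x$null_aurocs), auroc = x$null_aurocs)
}

#' @rdname tidy.null_dist
#' @method glance null_dist
#' @export
glance.null_dist <- function(x, ...) {
  tibble(B = x$B, k_up = x$k_up, k_down = x$k_down,
         median_auroc = stats::median(x$null_aurocs),
         threshold = x$threshold, exceedance = x$exceedance)
}

#' Tidy an evaluation report
#'
#' `tidy()` returns the leave-one-study-out table (or the single full-data
#' AUROC row when leave-one-out was not run); `glance()` returns the one-row
#' headline summary.
#'
#' @param x An `evaluation_report` from [evaluate_signature()].
#' @param ... Unused.
#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) {
  if (!is.null(x$leave_one_out)) {
    return(x$leave_one_out)
  }
  tidy(x$auroc)
}

#' @rdname tidy.evaluation_report
#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble(
    signature = x$signature$label,
    n_up = length(x$signature$up), n_down = length(x$signature$down),
    auroc = x$auroc$auroc, ci_low = x$auroc$ci_low, ci_high = x$auroc$ci_high,
    null_exceedance = x$null$exceedance,
    loso_min_auroc = if (!is.null(x$leave_one_out)) {
      min(x$leave_one_out$auroc, na.rm = TRUE)
    } else NA_real_,
    magnitude_rho = if (!is.null(x$magnitude_correlation)) {
      x$magnitude_correlation$rho
    } else NA_real_,
    group_p = if (!is.null(x$group_comparison)) {
      x$group_comparison$p.value
    } else NA_real_
  )
}

#' Plot transcriptomic scores by experimental group
#'
#' @param object A `score_report` from [score_samples()].
#' @param ... Unused.
#' @return A ggplot: score distribution per condition, points colored by
#'   study.
#' @method autoplot score_report
#' @export
autoplot.score_report <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(condition = dplyr::case_when(
      .data$stretch == 1 & .data$second_hit == 1 ~ "stretch + second hit",
      .data$stretch == 1 ~ "stretch",
      .data$second_hit == 1 ~ "second hit",
      TRUE ~ "control"
    ))
  ggplot(df, aes(x = .data$condition, y = .data$score)) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(aes(color = .data$study_id), width = 0.15, alpha = 0.8) +
    labs(x = NULL, y = "transcriptomic score", color = "study") +
    theme_minimal()
}

#' Plot a random-signature null distribution with an observed AUROC
#'
#' @param object A `null_dist`.
#' @param observed Optional observed AUROC drawn as a vertical line.
#' @param ... Unused.
#' @method autoplot null_dist
#' @export
autoplot.null_dist <- function(object, observed = NULL, ...) {
  p <- ggplot(tidy(object), aes(x = .data$auroc)) +
    geom_histogram(bins = 40, fill = "grey70", color = "white") +
    geom_vline(xintercept = object$threshold, linetype = "dashed") +
    labs(x = sprintf("AUROC of random %d-feature signatures",
                     object$k_up + object$k_down),
         y = "count") +
    theme_minimal()
  if (!is.null(observed)) {
    p <- p + geom_vline(xintercept = observed, color = "red")
  }
  p
}

#' Plot a greedy-selection trace
#'
#' @param object A `greedy_trace` from [greedy_optimize()].
#' @param ... Unused.
#' @return A ggplot of AUROC against signature size.
#' @method autoplot greedy_trace
#' @export
autoplot.greedy_trace <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$step, y = .data$auroc)) +
    geom_step() +
    geom_point() +
    labs(x = "signature size", y = "discovery AUROC") +
    theme_minimal()
}

#' ROC curve points for a score vector
#'
#' Convenience for plotting: sensitivity / 1-specificity at every score
#' cutoff.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @return Tibble `threshold`, `tpr`, `fpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tibble(
    threshold = cuts,
    tpr = vapply(cuts, function(c) mean(scores[labels == 1] >= c), numeric(1)),
    fpr = vapply(cuts, function(c) mean(scores[labels == 0] >= c), numeric(1))
  )
}

#' Plot a ROC curve
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @return A ggplot of the ROC curve with the chance diagonal.
#' @export
plot_roc <- function(scores, labels) {
  ggplot(roc_points(scores, labels), aes(x = .data$fpr, y = .data$tpr)) +
    geom_step() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                color = "grey60") +
    coord_equal() +
    labs(x = "1 - specificity", y = "sensitivity") +
    theme_minimal()
}
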
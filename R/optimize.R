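#' Greedy AUROC-maximizing signature refinement
#'
#' Forward selection from the empty signature: at each step every remaining
#' candidate is tentatively added on its differential-expression direction
#' side (up or down), the geometric-mean-difference score is recomputed, and
#' the candidate giving the highest AUROC against the stretch labels is kept.
#' Ties are broken by smaller adjusted stretch p-value, then lexicographic
#' feature id, so the result does not depend on candidate order. Selection
#' stops when no addition strictly increases the AUROC, when the AUROC
#' reaches 1, or at `max_size`. A backward-elimination variant (start from
#' all candidates, drop the feature whose removal most increases the AUROC)
#' is available for comparison.
#'
#' @param pooled A `pooled_matrix` (or features x samples matrix with
#'   `labels` supplied).
#' @param candidates Tibble with columns `feature_id`, `direction`
#'   (`"up"`/`"down"`), optionally `padj_stretch` for tie-breaking — e.g. a
#'   filtered [run_de()] table.
#' @param labels Optional 0/1 stretch labels; defaults to the pooled
#'   matrix's `stretch` annotation.
#' @param max_size Maximum signature size (default 10).
#' @param method `"forward"` (default) or `"backward"`.
#' @param label Label for the returned signature.
#' @return A list: `signature` (a [signature_set()]) and `trace` (tibble
#'   `step`, `feature_id`, `direction`, `auroc`, plus attribute
#'   `stopping_reason` in `no_improvement`, `perfect_auroc`, `max_size`).
#' @export
greedy_optimize <- function(pooled, candidates, labels = NULL, max_size = 10,
                            method = c("forward", "backward"),
                            label = "greedy_signature") {
  method <- match.arg(method)
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
  if (length(unique(labels)) < 2) {
    abort("both label classes (0 and 1) must be present.",
          class = "stretchsig_validation_error")
  }
  if (!nrow(candidates)) {
    abort("`candidates` is empty.", class = "stretchsig_validation_error")
  }
  if (!all(c("feature_id", "direction") %in% names(candidates))) {
    abort("`candidates` needs columns `feature_id` and `direction`.",
          class = "stretchsig_validation_error")
  }
  if (!all(candidates$direction %in% c("up", "down"))) {
    abort("candidate `direction` must be \"up\" or \"down\".",
          class = "stretchsig_validation_error")
  }
  missing_f <- setdiff(candidates$feature_id, rownames(Y))
  if (length(missing_f)) {
    abort(sprintf("candidate feature(s) absent from the matrix: %s",
                  paste(missing_f, collapse = ", ")),
          class = "stretchsig_missing_features")
  }
  cand <- as_tibble(candidates)
  if (anyDuplicated(cand$feature_id)) {
    abort("duplicated candidate feature id(s).",
          class = "stretchsig_validation_error")
  }
  if (!"padj_stretch" %in% names(cand)) cand$padj_stretch <- NA_real_
  # canonical order for deterministic tie-breaks
  cand <- cand[order(cand$padj_stretch, cand$feature_id, na.last = TRUE,
                     method = "radix"), ]

  shift <- if (any(Y[cand$feature_id, , drop = FALSE] <= 0)) 1 - min(Y) else 0
  logY <- log(Y[cand$feature_id, , drop = FALSE] + shift)
  n <- ncol(Y)

  score_of <- function(in_set) {
    up <- cand$feature_id[in_set & cand$direction == "up"]
    down <- cand$feature_id[in_set & cand$direction == "down"]
    up_term <- if (length(up)) exp(colMeans(logY[up, , drop = FALSE])) else 0
    down_term <- if (length(down)) exp(colMeans(logY[down, , drop = FALSE])) else 0
    up_term - down_term
  }

  k <- nrow(cand)
  if (method == "forward") {
    in_set <- rep(FALSE, k)
    best_auc <- 0.5
    trace <- list()
    reason <- "no_improvement"
    while (sum(in_set) < min(max_size, k)) {
      step_auc <- rep(-Inf, k)
      for (j in which(!in_set)) {
        trial <- in_set
        trial[j] <- TRUE
        step_auc[j] <- auroc(score_of(trial), labels)
      }
      j_best <- which.max(step_auc)   # cand is tie-break ordered
      if (step_auc[j_best] <= best_auc + 1e-12) {
        reason <- "no_improvement"
        break
      }
      in_set[j_best] <- TRUE
      best_auc <- step_auc[j_best]
      trace[[length(trace) + 1]] <- tibble(
        step = length(trace) + 1L,
        feature_id = cand$feature_id[j_best],
        direction = cand$direction[j_best],
        auroc = best_auc
      )
      if (best_auc >= 1 - 1e-12) {
        reason <- "perfect_auroc"
        break
      }
      if (sum(in_set) >= min(max_size, k)) {
        reason <- "max_size"
      }
    }
    if (!any(in_set)) {
      abort(sprintf(
        "no candidate improves on the chance AUROC of 0.5 (best single-feature AUROC: %.3f).",
        max(vapply(seq_len(k), function(j) {
          trial <- rep(FALSE, k); trial[j] <- TRUE
          auroc(score_of(trial), labels)
        }, numeric(1)))
      ), class = "stretchsig_empty_signature")
    }
    trace <- bind_rows(trace)
  } else {
    in_set <- rep(TRUE, k)
    best_auc <- auroc(score_of(in_set), labels)
    removed <- list()
    reason <- "no_improvement"
    while (sum(in_set) > 1) {
      step_auc <- rep(-Inf, k)
      for (j in which(in_set)) {
        trial <- in_set
        trial[j] <- FALSE
        step_auc[j] <- auroc(score_of(trial), labels)
      }
      j_best <- which.max(step_auc)
      if (step_auc[j_best] <= best_auc + 1e-12) break
      in_set[j_best] <- FALSE
      best_auc <- step_auc[j_best]
      if (best_auc >= 1 - 1e-12 && sum(in_set) <= max_size) {
        reason <- "perfect_auroc"
        break
      }
    }
    kept <- which(in_set)
    trace <- tibble(
      step = seq_along(kept),
      feature_id = cand$feature_id[kept],
      direction = cand$direction[kept],
      auroc = c(rep(NA_real_, length(kept) - 1), best_auc)
    )
  }

  sig <- signature_set(
    up = trace$feature_id[trace$direction == "up"],
    down = trace$feature_id[trace$direction == "down"],
    label = label
  )
  attr(trace, "stopping_reason") <- reason
  class(trace) <- c("greedy_trace", class(trace))
  list(signature = sig, trace = trace)
}
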
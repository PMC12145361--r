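#' One expression study (features x samples) with sample annotations
#'
#' Container for a single study: a numeric log-scale expression matrix with
#' feature ids as rownames and sample ids as colnames, plus a per-sample
#' annotation tibble (`sample_id`, `study_id`, `stretch`, `second_hit`,
#' `magnitude`).
#'
#' @param study_id Study identifier.
#' @param expr Numeric matrix, features x samples, with dimnames.
#' @param samples Tibble of per-sample annotations; one row per matrix column,
#'   matched by `sample_id`.
#'
#' @return An `expr_study` object.
#' @export
expr_study <- function(study_id, expr, samples) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    abort("`expr` must be a numeric matrix.", class = "stretchsig_validation_error")
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    abort("`expr` needs feature ids as rownames and sample ids as colnames.",
          class = "stretchsig_validation_error")
  }
  if (anyDuplicated(rownames(expr))) {
    abort(sprintf("duplicate feature id(s) in study '%s': %s", study_id,
                  paste(unique(rownames(expr)[duplicated(rownames(expr))]), collapse = ", ")),
          class = "stretchsig_validation_error")
  }
  if (anyDuplicated(colnames(expr))) {
    abort(sprintf("duplicate sample id(s) in study '%s': %s", study_id,
                  paste(unique(colnames(expr)[duplicated(colnames(expr))]), collapse = ", ")),
          class = "stretchsig_validation_error")
  }
  samples <- as_tibble(samples)
  required <- c("sample_id", "stretch", "second_hit")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    abort(sprintf("`samples` is missing column(s): %s", paste(missing_cols, collapse = ", ")),
          class = "stretchsig_validation_error")
  }
  if (!"study_id" %in% names(samples)) samples$study_id <- study_id
  if (!"magnitude" %in% names(samples)) samples$magnitude <- NA_real_
  extra <- setdiff(samples$sample_id, colnames(expr))
  if (length(extra)) {
    abort(sprintf("annotation row(s) without matrix column in study '%s': %s",
                  study_id, paste(extra, collapse = ", ")),
          class = "stretchsig_validation_error")
  }
  if (!setequal(samples$sample_id, colnames(expr)) ||
      nrow(samples) != ncol(expr)) {
    abort(sprintf("`samples` must have exactly one row per matrix column of study '%s'.",
                  study_id),
          class = "stretchsig_validation_error")
  }
  samples <- samples[match(colnames(expr), samples$sample_id), ]
  structure(
    list(study_id = study_id, expr = expr, samples = samples),
    class = "expr_study"
  )
}

#' @export
print.expr_study <- function(x, ...) {
  cat(sprintf("<expr_study '%s'> %d features x %d samples (%d controls)\n",
              x$study_id, nrow(x$expr), ncol(x$expr), sum(is_control(x$samples))))
  invisible(x)
}

is_control <- function(samples) samples$stretch == 0 & samples$second_hit == 0

check_studies <- function(studies) {
  if (!length(studies) || !all(map_lgl(studies, inherits, "expr_study"))) {
    abort("`studies` must be a non-empty list of expr_study objects.",
          class = "stretchsig_validation_error")
  }
  ids <- map_chr(studies, "study_id")
  if (anyDuplicated(ids)) {
    abort("duplicate study ids in `studies`.", class = "stretchsig_validation_error")
  }
  invisible(ids)
}

#' Common feature set across studies
#'
#' @param studies List of [expr_study()] objects.
#' @return Sorted character vector: the intersection of the studies' feature
#'   ids. Errors if the intersection is empty.
#' @export
intersect_features <- function(studies) {
  check_studies(studies)
  common <- Reduce(intersect, lapply(studies, function(s) rownames(s$expr)))
  if (!length(common)) {
    abort("the studies share no features; check that feature ids are harmonized across studies.",
          class = "stretchsig_empty_intersection")
  }
  sort(common)
}

#' Fit control-anchored batch parameters (location/scale model)
#'
#' Fits the ComBat location/scale batch model using only control samples
#' (`stretch == 0` and `second_hit == 0`): per-feature grand mean and pooled
#' scale are estimated from controls, then per-(study, feature) batch
#' locations and scales on the standardized scale. With `eb = TRUE` the batch
#' parameters are shrunk by parametric empirical Bayes (normal prior on
#' locations, inverse-gamma prior on squared scales, moment-matched
#' hyperparameters, fixed-point iteration of the conditional posteriors).
#'
#' @param studies List of [expr_study()] objects, each with at least two
#'   control samples.
#' @param eb Apply empirical-Bayes shrinkage (default `TRUE`).
#' @param tol Convergence tolerance of the EB fixed point (max relative
#'   change).
#' @param max_iter Maximum EB iterations.
#' @param scale_floor Lower floor for pooled and per-batch scale estimates;
#'   floored features are flagged in the result.
#'
#' @return A `batch_params` object: per-feature `alpha` (grand control mean)
#'   and `sigma` (pooled control scale), per-(study, feature) matrices
#'   `gamma_hat`/`delta2_hat` (direct estimates) and `gamma_star`/`delta2_star`
#'   (applied, shrunken if `eb`), per-study hyperparameters and convergence
#'   diagnostics.
#' @export
fit_control_batch_params <- function(studies, eb = TRUE, tol = 1e-6,
                                     max_iter = 200, scale_floor = 1e-8) {
  study_ids <- check_studies(studies)
  features <- intersect_features(studies)
  p <- length(features)
  k <- length(studies)

  ctrl <- lapply(studies, function(s) {
    keep <- is_control(s$samples)
    if (sum(keep) < 2) {
      abort(sprintf("study '%s' has %d control sample(s); at least 2 are required to anchor the normalization.",
                    s$study_id, sum(keep)),
            class = "stretchsig_validation_error")
    }
    m <- s$expr[features, keep, drop = FALSE]
    if (!all(is.finite(m))) {
      abort(sprintf("non-finite expression values in study '%s'.", s$study_id),
            class = "stretchsig_validation_error")
    }
    m
  })
  n_ctrl <- vapply(ctrl, ncol, integer(1))
  n_tot <- sum(n_ctrl)

  batch_means <- vapply(ctrl, rowMeans, numeric(p))        # p x k
  batch_vars <- vapply(ctrl, row_vars, numeric(p))         # p x k, (n-1) denom
  alpha <- as.vector(batch_means %*% n_ctrl) / n_tot
  # pooled within-batch variance of control residuals, (n_i - 1) weights so a
  # single batch standardizes exactly to unit scale
  sigma2 <- as.vector(batch_vars %*% (n_ctrl - 1)) / sum(n_ctrl - 1)
  floored <- sigma2 < scale_floor^2
  sigma <- sqrt(pmax(sigma2, scale_floor^2))

  z <- lapply(ctrl, function(m) (m - alpha) / sigma)
  gamma_hat <- vapply(z, rowMeans, numeric(p))
  delta2_hat <- vapply(z, row_vars, numeric(p))
  delta_floored <- delta2_hat < scale_floor^2
  delta2_hat <- pmax(delta2_hat, scale_floor^2)
  dimnames(gamma_hat) <- dimnames(delta2_hat) <- list(features, study_ids)

  hyper <- tibble(
    study_id = study_ids, n_controls = as.integer(n_ctrl),
    gamma_bar = NA_real_, tau2 = NA_real_,
    a_prior = NA_real_, b_prior = NA_real_,
    iterations = 0L, converge_delta = NA_real_, shrunk = FALSE
  )
  gamma_star <- gamma_hat
  delta2_star <- delta2_hat

  if (eb) {
    for (i in seq_len(k)) {
      g_hat <- gamma_hat[, i]
      d2_hat <- delta2_hat[, i]
      g_bar <- mean(g_hat)
      t2 <- var(g_hat)
      m_d <- mean(d2_hat)
      s2_d <- var(d2_hat)
      hyper$gamma_bar[i] <- g_bar
      hyper$tau2[i] <- t2
      if (!is.finite(t2) || t2 <= 0 || !is.finite(s2_d) || s2_d <= 0) {
        # degenerate hyperparameter moments (e.g. near-constant batch): keep
        # the direct estimates for this batch
        next
      }
      a <- (2 * s2_d + m_d^2) / s2_d
      b <- (m_d * s2_d + m_d^3) / s2_d
      hyper$a_prior[i] <- a
      hyper$b_prior[i] <- b
      n_i <- n_ctrl[i]
      zi <- z[[i]]
      g_new <- g_hat
      d2_new <- d2_hat
      change <- Inf
      it <- 0L
      while (change > tol && it < max_iter) {
        g_old <- g_new
        d2_old <- d2_new
        g_new <- (n_i * t2 * g_hat + d2_old * g_bar) / (n_i * t2 + d2_old)
        ss <- rowSums((zi - g_new)^2)
        d2_new <- (0.5 * ss + b) / (n_i / 2 + a - 1)
        change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                      abs(d2_new - d2_old) / pmax(abs(d2_old), 1e-12))
        it <- it + 1L
      }
      gamma_star[, i] <- g_new
      delta2_star[, i] <- pmax(d2_new, scale_floor^2)
      hyper$iterations[i] <- it
      hyper$converge_delta[i] <- change
      hyper$shrunk[i] <- TRUE
    }
  }

  structure(
    list(
      features = features, study_ids = study_ids,
      alpha = setNames(alpha, features), sigma = setNames(sigma, features),
      gamma_hat = gamma_hat, delta2_hat = delta2_hat,
      gamma_star = gamma_star, delta2_star = delta2_star,
      hyper = hyper, eb = eb, tol = tol, max_iter = max_iter,
      scale_floor = scale_floor,
      floored_features = features[floored | rowSums(delta_floored) > 0]
    ),
    class = "batch_params"
  )
}

#' @export
print.batch_params <- function(x, ...) {
  cat(sprintf("<batch_params> %d features x %d studies, eb = %s\n",
              length(x$features), length(x$study_ids), x$eb))
  if (length(x$floored_features)) {
    cat(sprintf("  %d feature(s) scale-floored\n", length(x$floored_features)))
  }
  invisible(x)
}

#' Apply fitted batch corrections to all samples of each study
#'
#' Standardizes every sample with the control-derived grand mean and pooled
#' scale, removes the (shrunken) batch location and scale of its study, and
#' back-transforms to the original scale. Controls and non-controls of a
#' study receive the same per-feature correction, so case effects are
#' preserved.
#'
#' @param studies List of [expr_study()] objects.
#' @param params A `batch_params` from [fit_control_batch_params()]; must
#'   cover every study and feature.
#'
#' @return A `pooled_matrix`: the corrected matrix over the common feature
#'   set, the combined sample annotations, and the `batch_params` used
#'   (provenance).
#' @export
apply_batch_params <- function(studies, params) {
  study_ids <- check_studies(studies)
  if (!inherits(params, "batch_params")) {
    abort("`params` must come from fit_control_batch_params().",
          class = "stretchsig_validation_error")
  }
  missing_st <- setdiff(study_ids, params$study_ids)
  if (length(missing_st)) {
    abort(sprintf("no batch parameters for study(ies): %s",
                  paste(missing_st, collapse = ", ")),
          class = "stretchsig_validation_error")
  }
  features <- params$features
  corrected <- lapply(studies, function(s) {
    missing_f <- setdiff(features, rownames(s$expr))
    if (length(missing_f)) {
      abort(sprintf("study '%s' lacks parameterized feature(s): %s",
                    s$study_id, paste(utils::head(missing_f, 5), collapse = ", ")),
            class = "stretchsig_validation_error")
    }
    y <- s$expr[features, , drop = FALSE]
    z <- (y - params$alpha) / params$sigma
    z_adj <- (z - params$gamma_star[, s$study_id]) /
      sqrt(params$delta2_star[, s$study_id])
    z_adj * params$sigma + params$alpha
  })
  expr <- do.call(cbind, corrected)
  samples <- bind_rows(lapply(studies, function(s) s$samples))
  structure(
    list(expr = expr, samples = samples, params = params),
    class = "pooled_matrix"
  )
}

# inverse of apply_batch_params for one pooled matrix (used to audit that the
# correction is lossless given its parameters)
invert_batch_params <- function(pooled) {
  params <- pooled$params
  out <- pooled$expr
  for (sid in unique(pooled$samples$study_id)) {
    cols <- pooled$samples$study_id == sid
    z_adj <- (out[, cols, drop = FALSE] - params$alpha) / params$sigma
    z <- z_adj * sqrt(params$delta2_star[, sid]) + params$gamma_star[, sid]
    out[, cols] <- z * params$sigma + params$alpha
  }
  out
}

#' @export
print.pooled_matrix <- function(x, ...) {
  cat(sprintf("<pooled_matrix> %d features x %d samples from %d studies (eb = %s)\n",
              nrow(x$expr), ncol(x$expr),
              length(unique(x$samples$study_id)), x$params$eb))
  invisible(x)
}

#' Control-anchored co-normalization (pool + batch-correct)
#'
#' Composes [intersect_features()], [fit_control_batch_params()] and
#' [apply_batch_params()]: restricts all studies to their common feature set,
#' fits the location/scale batch model on control samples only, and applies
#' the corrections to every sample. This pools heterogeneous studies onto one
#' comparable scale without removing case (stretch) effects.
#'
#' @inheritParams fit_control_batch_params
#' @return A `pooled_matrix`.
#' @export
coconut <- function(studies, eb = TRUE, tol = 1e-6, max_iter = 200,
                    scale_floor = 1e-8) {
  params <- fit_control_batch_params(studies, eb = eb, tol = tol,
                                     max_iter = max_iter,
                                     scale_floor = scale_floor)
  apply_batch_params(studies, params)
}
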
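#' Simulation configuration for multi-study stretch expression data
#'
#' Describes a set of small expression studies emulating pooled cyclic-stretch
#' experiments: each study has its own additive location shift and
#' multiplicative scale (batch effects), control and stretched groups,
#' optionally second-hit groups, and a study-level stretch magnitude (e.g.
#' tidal volume in ml/kg) that scales the planted stretch effects through a
#' dose-response slope.
#'
#' Planted effects are expressed in units of the residual standard deviation
#' (`noise_sd`); in diagnostic no-noise configurations (`noise_sd = 0`) the
#' unit is one log2 expression unit.
#'
#' @param n_studies Number of studies (batches).
#' @param features Number of features (genes or miRNAs) per study.
#' @param samples_per_group Samples per (study, group); at least 2.
#' @param groups_present Character vector, or list of one vector per study,
#'   drawn from `"control"`, `"stretch"`, `"second_hit"`,
#'   `"stretch_second_hit"`. Every study must include `"control"`.
#' @param n_up,n_down Number of planted up-/down-regulated stretch features.
#' @param n_hit Number of planted second-hit-responsive features.
#' @param hit_overlap How many of the hit features coincide with stretch
#'   features (at most `min(n_hit, n_up + n_down)`).
#' @param effect_size Standardized mean shift of planted features (units of
#'   residual SD).
#' @param dose_response_slope Multiplier applied per unit of magnitude: the
#'   stretch effect in study *i* is `effect * (1 + slope * magnitude_i)`.
#' @param magnitude_per_study Nonnegative study-level stretch magnitude
#'   (recycled to `n_studies`).
#' @param batch_loc_sd SD of per-study additive shifts.
#' @param batch_scale_sd SD of per-study log multiplicative scales.
#' @param noise_sd Residual SD.
#' @param baseline_mean,baseline_sd Distribution of per-feature baseline
#'   expression (log2 scale).
#' @param feature_prefix Prefix for generated feature ids.
#' @param seed Integer seed governing all draws.
#'
#' @return A `sim_config` object (a validated list).
#' @export
sim_config <- function(n_studies = 3,
                       features = 200,
                       samples_per_group = 5,
                       groups_present = c("control", "stretch"),
                       n_up = 10, n_down = 10,
                       n_hit = 0, hit_overlap = 0,
                       effect_size = 1.5,
                       dose_response_slope = 0,
                       magnitude_per_study = 0,
                       batch_loc_sd = 1,
                       batch_scale_sd = 0.1,
                       noise_sd = 1,
                       baseline_mean = 8,
                       baseline_sd = 2,
                       feature_prefix = "gene",
                       seed = 1L) {
  assert_positive_int(n_studies, "n_studies")
  assert_positive_int(features, "features")
  assert_positive_int(samples_per_group, "samples_per_group")
  if (samples_per_group < 2) {
    abort("`samples_per_group` must be at least 2.",
          class = "stretchsig_validation_error")
  }
  for (nm in c("n_up", "n_down", "n_hit", "hit_overlap")) {
    x <- get(nm)
    if (length(x) != 1 || !is.finite(x) || x < 0 || x != as.integer(x)) {
      abort(sprintf("`%s` must be a single nonnegative integer.", nm),
            class = "stretchsig_validation_error")
    }
  }
  if (n_up + n_down + n_hit > features) {
    abort("`n_up + n_down + n_hit` must not exceed `features`.",
          class = "stretchsig_validation_error")
  }
  if (hit_overlap > min(n_hit, n_up + n_down)) {
    abort("`hit_overlap` cannot exceed min(n_hit, n_up + n_down).",
          class = "stretchsig_validation_error")
  }
  allowed <- c("control", "stretch", "second_hit", "stretch_second_hit")
  if (!is.list(groups_present)) {
    groups_present <- rep(list(groups_present), n_studies)
  }
  if (length(groups_present) != n_studies) {
    abort("`groups_present` must have one entry per study.",
          class = "stretchsig_validation_error")
  }
  for (i in seq_along(groups_present)) {
    g <- groups_present[[i]]
    if (!all(g %in% allowed)) {
      abort(sprintf("`groups_present` for study %d contains unknown group(s): %s",
                    i, paste(setdiff(g, allowed), collapse = ", ")),
            class = "stretchsig_validation_error")
    }
    if (!"control" %in% g) {
      abort(sprintf("`groups_present`: study %d has no control group; every study needs controls for control-anchored normalization.", i),
            class = "stretchsig_validation_error")
    }
  }
  assert_nonneg(c(batch_loc_sd, batch_scale_sd, noise_sd, baseline_sd),
                "batch_loc_sd/batch_scale_sd/noise_sd/baseline_sd")
  magnitude_per_study <- rep_len(as.numeric(magnitude_per_study), n_studies)
  assert_nonneg(magnitude_per_study, "magnitude_per_study")
  if (!is.finite(effect_size)) {
    abort("`effect_size` must be finite.", class = "stretchsig_validation_error")
  }
  assert_positive_int(seed, "seed")

  structure(
    list(
      n_studies = as.integer(n_studies), features = as.integer(features),
      samples_per_group = as.integer(samples_per_group),
      groups_present = lapply(groups_present, unique),
      n_up = as.integer(n_up), n_down = as.integer(n_down),
      n_hit = as.integer(n_hit), hit_overlap = as.integer(hit_overlap),
      effect_size = effect_size, dose_response_slope = dose_response_slope,
      magnitude_per_study = magnitude_per_study,
      batch_loc_sd = batch_loc_sd, batch_scale_sd = batch_scale_sd,
      noise_sd = noise_sd, baseline_mean = baseline_mean,
      baseline_sd = baseline_sd, feature_prefix = feature_prefix,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d studies x %d features, %d/group; planted up/down/hit = %d/%d/%d, effect %.2g SD, seed %d\n",
    x$n_studies, x$features, x$samples_per_group,
    x$n_up, x$n_down, x$n_hit, x$effect_size, x$seed
  ))
  invisible(x)
}

#' Copy a simulation configuration with a new seed
#'
#' Convenience for generating an independent cohort under identical study
#' conditions (combine with the `truth` argument of [generate_studies()] to
#' carry the same planted signature).
#'
#' @param config A [sim_config()].
#' @param seed New integer seed.
#' @return The updated `sim_config`.
#' @export
reseed_config <- function(config, seed) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be a sim_config.", class = "stretchsig_validation_error")
  }
  config$seed <- assert_positive_int(seed, "seed")
  config
}

group_is_stretch <- function(g) g %in% c("stretch", "stretch_second_hit")
group_is_hit     <- function(g) g %in% c("second_hit", "stretch_second_hit")

#' Generate synthetic multi-study expression data with planted structure
#'
#' Simulates one expression study per batch under an additive log2-scale
#' model: `baseline + batch shift + batch scale * (stretch effect * stretch *
#' (1 + slope * magnitude) + hit effect * hit + noise)`. The returned ground
#' truth records planted feature sets, per-feature effects and per-study batch
#' parameters so downstream recovery can be verified.
#'
#' @param config A [sim_config()].
#' @param truth Optional `synthetic_truth` from a previous call: reuse its
#'   planted feature sets and effects (batch parameters and noise are still
#'   drawn fresh from `config$seed`), e.g. to generate an independent test
#'   cohort carrying the same planted signature.
#'
#' @return A list with `studies` (list of [expr_study()] objects) and `truth`
#'   (a `synthetic_truth` object).
#' @export
generate_studies <- function(config, truth = NULL) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created with sim_config().",
          class = "stretchsig_validation_error")
  }
  set.seed(config$seed)
  p <- config$features
  feat_ids <- sprintf("%s_%04d", config$feature_prefix, seq_len(p))

  baseline <- rnorm(p, config$baseline_mean, config$baseline_sd)
  effect_unit <- if (config$noise_sd > 0) config$noise_sd else 1

  if (is.null(truth)) {
    idx <- sample.int(p)
    up_idx <- idx[seq_len(config$n_up)]
    down_idx <- idx[config$n_up + seq_len(config$n_down)]
    stretch_idx <- c(up_idx, down_idx)
    overlap_idx <- if (config$hit_overlap > 0) stretch_idx[seq_len(config$hit_overlap)] else integer()
    fresh_hit <- config$n_hit - config$hit_overlap
    rest <- idx[-seq_len(config$n_up + config$n_down)]
    hit_idx <- c(overlap_idx, if (fresh_hit > 0) rest[seq_len(fresh_hit)] else integer())

    stretch_effect <- numeric(p)
    stretch_effect[up_idx] <- config$effect_size * effect_unit
    stretch_effect[down_idx] <- -config$effect_size * effect_unit
    hit_effect <- numeric(p)
    hit_effect[hit_idx] <- config$effect_size * effect_unit
  } else {
    if (!inherits(truth, "synthetic_truth")) {
      abort("`truth` must be a synthetic_truth object.",
            class = "stretchsig_validation_error")
    }
    if (!setequal(truth$effects$feature_id, feat_ids)) {
      abort("`truth` was generated for a different feature universe.",
            class = "stretchsig_validation_error")
    }
    eff <- truth$effects[match(feat_ids, truth$effects$feature_id), ]
    stretch_effect <- eff$stretch_effect
    hit_effect <- eff$hit_effect
    up_idx <- which(feat_ids %in% truth$up_features)
    down_idx <- which(feat_ids %in% truth$down_features)
    hit_idx <- which(feat_ids %in% truth$hit_features)
  }

  shifts <- rnorm(config$n_studies, 0, config$batch_loc_sd)
  scales <- exp(rnorm(config$n_studies, 0, config$batch_scale_sd))

  studies <- vector("list", config$n_studies)
  for (i in seq_len(config$n_studies)) {
    groups <- config$groups_present[[i]]
    grp <- rep(groups, each = config$samples_per_group)
    n_s <- length(grp)
    stretch <- as.integer(group_is_stretch(grp))
    hit <- as.integer(group_is_hit(grp))
    mag <- config$magnitude_per_study[i]
    study_id <- sprintf("study_%02d", i)
    sample_ids <- sprintf("%s_s%02d", study_id, seq_len(n_s))

    dose <- 1 + config$dose_response_slope * mag
    signal <- outer(stretch_effect * dose, stretch) + outer(hit_effect, hit)
    noise <- matrix(rnorm(p * n_s, 0, config$noise_sd), p, n_s)
    y <- baseline + shifts[i] + scales[i] * (signal + noise)
    dimnames(y) <- list(feat_ids, sample_ids)

    studies[[i]] <- expr_study(
      study_id = study_id,
      expr = y,
      samples = tibble(
        sample_id = sample_ids, study_id = study_id,
        stretch = stretch, second_hit = hit,
        magnitude = ifelse(stretch == 1L, mag, 0)
      )
    )
  }

  out_truth <- structure(
    list(
      up_features = sort(feat_ids[up_idx]),
      down_features = sort(feat_ids[down_idx]),
      hit_features = sort(feat_ids[hit_idx]),
      effects = tibble(
        feature_id = feat_ids,
        stretch_effect = stretch_effect,
        hit_effect = hit_effect
      ),
      batches = tibble(
        study_id = sprintf("study_%02d", seq_len(config$n_studies)),
        shift = shifts, scale = scales,
        magnitude = config$magnitude_per_study
      ),
      seed = config$seed,
      config = config
    ),
    class = "synthetic_truth"
  )

  list(studies = studies, truth = out_truth)
}

#' Generate a synthetic miRNA-to-gene target map
#'
#' Builds a two-column target map (`mirna_id`, `gene_id`) in which every
#' planted stretch feature of `truth` is a target of at least one synthetic
#' miRNA, plus `n_decoys` decoy targets drawn from non-planted features.
#' Stands in for a table of experimentally validated miRNA targets.
#'
#' @param truth A `synthetic_truth` from [generate_studies()].
#' @param config The [sim_config()] used to generate `truth`.
#' @param n_mirnas Number of synthetic miRNA ids.
#' @param n_decoys Number of decoy (non-planted) target genes.
#' @param mirna_ids Optional explicit miRNA ids (length `n_mirnas`).
#'
#' @return A tibble with columns `mirna_id`, `gene_id`; no miRNA has an empty
#'   target set.
#' @export
generate_target_map <- function(truth, config, n_mirnas = 6, n_decoys = 0,
                                mirna_ids = NULL) {
  if (!inherits(truth, "synthetic_truth")) {
    abort("`truth` must come from generate_studies().",
          class = "stretchsig_validation_error")
  }
  assert_positive_int(n_mirnas, "n_mirnas")
  planted <- sort(c(truth$up_features, truth$down_features))
  nonplanted <- setdiff(truth$effects$feature_id, c(planted, truth$hit_features))
  if (n_decoys > length(nonplanted)) {
    abort("`n_decoys` exceeds the number of non-planted features.",
          class = "stretchsig_validation_error")
  }
  if (n_mirnas > length(planted) + n_decoys) {
    abort("more miRNAs requested than available targets; some target sets would be empty.",
          class = "stretchsig_validation_error")
  }
  if (is.null(mirna_ids)) {
    mirna_ids <- sprintf("mir_%03d", seq_len(n_mirnas))
  }
  set.seed(child_seed(truth$seed, 1L))
  decoys <- sort(sample(nonplanted, n_decoys))
  genes <- c(planted, decoys)
  assignment <- rep_len(mirna_ids, length(genes))[sample.int(length(genes))]
  tibble(mirna_id = assignment, gene_id = genes) |>
    arrange(.data$mirna_id, .data$gene_id)
}
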
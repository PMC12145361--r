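#' Simulate a full three-tier discovery bundle
#'
#' Generates the input ensemble the discovery workflow expects: (1) miRNA
#' studies with a planted up/down miRNA signature, (2) cell gene-expression
#' studies with planted stretch- and second-hit-responsive genes (some
#' second-hit groups present), (3) animal gene-expression studies carrying
#' the same planted gene signature with study-level stretch magnitudes
#' (tidal-volume analog) and a dose-response slope, plus (4) a miRNA-target
#' map in which the planted genes are targets of the planted miRNAs and
#' decoy targets dilute the map. A fraction of non-planted genes is absent
#' from the animal tier, emulating partial feature availability across
#' platforms.
#'
#' @param seed Integer seed for the whole bundle.
#' @param n_genes Gene universe size (default 240).
#' @param n_mirnas miRNA universe size (default 60).
#' @param n_up_genes,n_down_genes Planted stretch gene counts (default 8/4).
#' @param effect_size Planted effect in residual-SD units (default 1.5).
#' @param magnitudes Study-level stretch magnitudes of the animal tier.
#' @param dose_response_slope Effect multiplier per unit magnitude
#'   (default 0.03).
#' @param animal_drop_frac Fraction of non-planted genes missing from the
#'   animal tier (default 0.2).
#' @param n_decoy_targets Decoy targets of the planted miRNAs (default 40).
#' @return A list: `mirna_studies`, `mirna_truth`, `cell_studies`,
#'   `cell_truth`, `animal_studies`, `animal_truth`, `target_map`.
#' @export
simulate_discovery_bundle <- function(seed = 1L, n_genes = 240, n_mirnas = 60,
                                      n_up_genes = 8, n_down_genes = 4,
                                      effect_size = 1.5,
                                      magnitudes = c(0, 10, 15, 30),
                                      dose_response_slope = 0.03,
                                      animal_drop_frac = 0.2,
                                      n_decoy_targets = 40) {
  mirna_cfg <- sim_config(
    n_studies = 3, features = n_mirnas, samples_per_group = 4,
    groups_present = c("control", "stretch"),
    n_up = 3, n_down = 3, effect_size = 2,
    batch_loc_sd = 1, batch_scale_sd = 0.1, noise_sd = 1,
    feature_prefix = "mir", seed = child_seed(seed, 11L)
  )
  mirna_gen <- generate_studies(mirna_cfg)

  cell_cfg <- sim_config(
    n_studies = 3, features = n_genes, samples_per_group = 5,
    groups_present = list(
      c("control", "stretch"),
      c("control", "stretch", "second_hit", "stretch_second_hit"),
      c("control", "stretch", "second_hit")
    ),
    n_up = n_up_genes, n_down = n_down_genes,
    n_hit = 10, hit_overlap = 2, effect_size = effect_size,
    batch_loc_sd = 1, batch_scale_sd = 0.1, noise_sd = 1,
    feature_prefix = "gene", seed = child_seed(seed, 12L)
  )
  cell_gen <- generate_studies(cell_cfg)

  animal_cfg <- sim_config(
    n_studies = length(magnitudes), features = n_genes,
    samples_per_group = 6, groups_present = c("control", "stretch"),
    n_up = n_up_genes, n_down = n_down_genes,
    effect_size = effect_size, dose_response_slope = dose_response_slope,
    magnitude_per_study = magnitudes,
    batch_loc_sd = 1, batch_scale_sd = 0.1, noise_sd = 1,
    feature_prefix = "gene", seed = child_seed(seed, 14L)
  )
  animal_gen <- generate_studies(animal_cfg, truth = cell_gen$truth)

  planted_mirnas <- c(mirna_gen$truth$up_features, mirna_gen$truth$down_features)
  target_map <- generate_target_map(
    cell_gen$truth, cell_cfg, n_mirnas = length(planted_mirnas),
    n_decoys = n_decoy_targets, mirna_ids = planted_mirnas
  )
  # background targets of non-signature miRNAs, so filtering is a real step
  set.seed(child_seed(seed, 13L))
  planted_genes <- c(cell_gen$truth$up_features, cell_gen$truth$down_features)
  other_mirnas <- setdiff(rownames(mirna_gen$studies[[1]]$expr), planted_mirnas)
  background_genes <- setdiff(cell_gen$truth$effects$feature_id,
                              c(planted_genes, unique(target_map$gene_id)))
  n_bg <- min(length(background_genes), 3 * length(other_mirnas))
  if (n_bg > 0) {
    target_map <- bind_rows(target_map, tibble(
      mirna_id = rep_len(other_mirnas, n_bg),
      gene_id = sample(background_genes, n_bg)
    )) |> arrange(.data$mirna_id, .data$gene_id)
  }

  # emulate partial feature availability in the animal platforms
  keep_planted <- planted_genes
  droppable <- setdiff(cell_gen$truth$effects$feature_id, keep_planted)
  dropped <- sample(droppable, round(animal_drop_frac * length(droppable)))
  animal_studies <- lapply(animal_gen$studies, function(s) {
    keep <- setdiff(rownames(s$expr), dropped)
    expr_study(s$study_id, s$expr[keep, , drop = FALSE], s$samples)
  })

  list(
    mirna_studies = mirna_gen$studies, mirna_truth = mirna_gen$truth,
    cell_studies = cell_gen$studies, cell_truth = cell_gen$truth,
    animal_studies = animal_studies, animal_truth = animal_gen$truth,
    target_map = target_map
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "stretchsig_stage_error")) stop(e)
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
          class = "stretchsig_stage_error", parent = e)
  })
}

#' Run the full stretch-signature discovery workflow
#'
#' Executes the three-step discovery analysis on pooled studies:
#'
#' * **Step 1 (miRNA)** — co-normalize the miRNA studies with the
#'   control-anchored batch model, fit the two-factor differential-expression
#'   model, select the miRNA signature at `mirna_alpha`, score all samples
#'   and compute the AUROC with bootstrap CI.
#' * **Step 2 (cell genes)** — restrict the gene universe to targets of the
#'   Step-1 miRNAs, co-normalize the cell studies, run the two-factor model
#'   on the targeted universe and select the large gene signature at
#'   `gene_alpha`.
#' * **Step 3 (animal validation)** — intersect the gene signature with the
#'   features available in all animal studies, co-normalize the animal
#'   studies, score, refine with greedy AUROC-maximizing forward selection,
#'   and evaluate the optimized signature (bootstrap CI, random-signature
#'   null, leave-one-study-out, score-magnitude Spearman correlation, group
#'   comparison).
#'
#' Cell and animal tiers are optional; the workflow stops after the last
#' feasible step. Stage failures carry the stage name; artifacts written
#' before a failure are retained.
#'
#' @param mirna_studies List of [expr_study()] objects (miRNA tier).
#' @param cell_studies Optional list of cell gene-expression studies.
#' @param animal_studies Optional list of animal validation studies.
#' @param target_map Tibble `mirna_id`, `gene_id` (required for Step 2).
#' @param mirna_alpha Adjusted-p threshold for miRNA selection
#'   (default 0.1).
#' @param gene_alpha Adjusted-p threshold for gene selection (default 0.01).
#' @param stretch_only Exclude genes also significant for the second hit
#'   (default `FALSE`).
#' @param eb,tol,max_iter Co-normalization settings.
#' @param max_size Maximum optimized signature size (default 10).
#' @param B Bootstrap/null replicates (default 1000).
#' @param null_threshold AUROC threshold for the null exceedance.
#' @param seed Integer seed for all stochastic steps.
#' @param out_dir Optional directory: each stage writes its standard-format
#'   artifact there (TSV signatures/tables/scores, JSON evaluation and run
#'   log).
#' @return A `discovery_run` list with elements `mirna`, `gene`, `animal`
#'   holding each step's intermediates and results.
#' @export
run_discovery <- function(mirna_studies, cell_studies = NULL,
                          animal_studies = NULL, target_map = NULL,
                          mirna_alpha = 0.1, gene_alpha = 0.01,
                          stretch_only = FALSE, eb = TRUE, tol = 1e-6,
                          max_iter = 200, max_size = 10, B = 1000,
                          null_threshold = 0.9, seed = 1L, out_dir = NULL) {
  for (a in c(mirna_alpha, gene_alpha)) {
    if (!is.finite(a) || a <= 0 || a >= 1) {
      abort("thresholds must lie in (0, 1).", class = "stretchsig_validation_error")
    }
  }
  emit <- function(writer, obj, file) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      writer(obj, file.path(out_dir, file))
    }
  }

  # Step 1: miRNA signature
  mirna <- stage("mirna_discovery", {
    pooled <- coconut(mirna_studies, eb = eb, tol = tol, max_iter = max_iter)
    de <- run_de(pooled)
    sig <- select_signature(de, mirna_alpha, label = "mirna_signature")
    sc <- score_samples(pooled, sig)
    acc <- auroc_ci(sc$score, pooled$samples$stretch, B = B,
                    seed = child_seed(seed, 1L))
    emit(write_de_tsv, de, "mirna_de.tsv")
    emit(write_signature_tsv, sig, "mirna_signature.tsv")
    emit(write_scores_tsv, sc, "mirna_scores.tsv")
    list(pooled = pooled, de = de, signature = sig, scores = sc, auroc = acc)
  })
  out <- structure(
    list(mirna = mirna, gene = NULL, animal = NULL,
         settings = list(mirna_alpha = mirna_alpha, gene_alpha = gene_alpha,
                         stretch_only = stretch_only, eb = eb, tol = tol,
                         max_iter = max_iter, max_size = max_size, B = B,
                         null_threshold = null_threshold, seed = seed)),
    class = "discovery_run"
  )
  if (is.null(cell_studies) || is.null(target_map)) {
    return(out)
  }

  # Step 2: miRNA-target gene signature in cell studies
  out$gene <- stage("gene_discovery", {
    pooled <- coconut(cell_studies, eb = eb, tol = tol, max_iter = max_iter)
    sig_mirnas <- c(out$mirna$signature$up, out$mirna$signature$down)
    universe <- filter_by_targets(rownames(pooled$expr), target_map, sig_mirnas)
    if (!length(universe)) {
      abort("no cell-study feature is a target of the selected miRNAs.",
            class = "stretchsig_validation_error")
    }
    de <- run_de(pooled$expr[universe, , drop = FALSE], pooled$samples)
    sig <- select_signature(de, gene_alpha, stretch_only = stretch_only,
                            label = "gene_signature")
    emit(write_de_tsv, de, "gene_de.tsv")
    emit(write_signature_tsv, sig, "gene_signature.tsv")
    list(pooled = pooled, universe = universe, de = de, signature = sig)
  })
  if (is.null(animal_studies)) {
    return(out)
  }

  # Step 3: animal validation + greedy refinement
  out$animal <- stage("animal_validation", {
    avail <- intersect_features(animal_studies)
    sig_avail <- signature_set(
      up = intersect(out$gene$signature$up, avail),
      down = intersect(out$gene$signature$down, avail),
      label = "available_gene_signature"
    )
    pooled <- coconut(animal_studies, eb = eb, tol = tol, max_iter = max_iter)
    sc <- score_samples(pooled, sig_avail)
    acc <- auroc_ci(sc$score, pooled$samples$stretch, B = B,
                    seed = child_seed(seed, 2L))
    mag <- ifelse(is.na(sc$magnitude), 0, sc$magnitude)
    spear_avail <- if (sd(mag) > 0) spearman_cor(sc$score, mag)
    cand_ids <- c(sig_avail$up, sig_avail$down)
    candidates <- out$gene$de[out$gene$de$feature_id %in% cand_ids,
                              c("feature_id", "direction", "padj_stretch")]
    opt <- greedy_optimize(pooled, candidates, max_size = max_size,
                           label = "optimized_signature")
    evaluation <- evaluate_signature(
      pooled, opt$signature, studies = animal_studies, B = B,
      seed = child_seed(seed, 3L), null_threshold = null_threshold,
      eb = eb, tol = tol, max_iter = max_iter
    )
    emit(write_signature_tsv, sig_avail, "available_signature.tsv")
    emit(write_scores_tsv, sc, "animal_scores.tsv")
    emit(write_signature_tsv, opt$signature, "optimized_signature.tsv")
    emit(function(x, p) readr::write_tsv(as_tibble(x), p), opt$trace,
         "greedy_trace.tsv")
    emit(write_evaluation_json, evaluation, "evaluation.json")
    list(pooled = pooled, available_signature = sig_avail, scores = sc,
         auroc = acc, magnitude_correlation = spear_avail,
         candidates = candidates, optimized_signature = opt$signature,
         trace = opt$trace, evaluation = evaluation)
  })
  if (!is.null(out_dir)) {
    jsonlite::write_json(out$settings, file.path(out_dir, "run_settings.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.discovery_run <- function(x, ...) {
  cat("<discovery_run>\n")
  cat(sprintf("  Step 1: %d up / %d down miRNAs, score AUROC %.3f (%.3f-%.3f)\n",
              length(x$mirna$signature$up), length(x$mirna$signature$down),
              x$mirna$auroc$auroc, x$mirna$auroc$ci_low, x$mirna$auroc$ci_high))
  if (!is.null(x$gene)) {
    cat(sprintf("  Step 2: %d-gene target universe -> %d up / %d down genes\n",
                length(x$gene$universe), length(x$gene$signature$up),
                length(x$gene$signature$down)))
  }
  if (!is.null(x$animal)) {
    cat(sprintf("  Step 3: %d genes available; full-signature AUROC %.3f\n",
                length(c(x$animal$available_signature$up,
                         x$animal$available_signature$down)),
                x$animal$auroc$auroc))
    cat(sprintf("          optimized to %d genes; ",
                length(c(x$animal$optimized_signature$up,
                         x$animal$optimized_signature$down))))
    cat(sprintf("AUROC %.3f (%.3f-%.3f), null exceedance %.4g\n",
                x$animal$evaluation$auroc$auroc,
                x$animal$evaluation$auroc$ci_low,
                x$animal$evaluation$auroc$ci_high,
                x$animal$evaluation$null$exceedance))
  }
  invisible(x)
}
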
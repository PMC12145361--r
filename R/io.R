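#' Read one expression study from TSV files
#'
#' Expression files are tab-separated, UTF-8, first column `feature_id`,
#' remaining columns one per sample (header row of sample ids), `NA` for
#' missing. Metadata files have columns `sample_id`, `study_id`, `stretch`
#' (0/1), `second_hit` (0/1), `magnitude` (float or NA) and may describe
#' several studies; only rows matching the expression file's samples are
#' used.
#'
#' @param path Path to the expression TSV.
#' @param metadata Path to the metadata TSV, or an already-read annotation
#'   tibble.
#' @param study_id Study id; defaults to the (single) study id found in the
#'   matching metadata rows.
#' @return An [expr_study()].
#' @export
read_expression_tsv <- function(path, metadata, study_id = NULL) {
  # cells are parsed with as.numeric (correctly rounded strtod) so that
  # write(read(x)) is an exact round trip
  raw <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE))
  probs <- readr::problems(raw)
  if (nrow(probs)) {
    abort(sprintf("parse error in '%s' at line %d: %s", path,
                  probs$row[1] + 1L, probs$expected[1]),
          class = "stretchsig_parse_error")
  }
  if (names(raw)[1] != "feature_id") {
    abort(sprintf("'%s': first column must be named 'feature_id'.", path),
          class = "stretchsig_parse_error")
  }
  if (anyDuplicated(raw$feature_id)) {
    dup <- unique(raw$feature_id[duplicated(raw$feature_id)])
    abort(sprintf("'%s': duplicated feature id(s): %s", path,
                  paste(utils::head(dup, 5), collapse = ", ")),
          class = "stretchsig_parse_error")
  }
  m <- vapply(raw[-1], function(col) {
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) & !(is.na(col) | col == "NA"))
    if (length(bad)) {
      abort(sprintf("'%s': non-numeric cell at line %d ('%s').", path,
                    bad[1] + 1L, col[bad[1]]),
            class = "stretchsig_parse_error")
    }
    v
  }, numeric(nrow(raw)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(raw)[-1]))
  rownames(m) <- raw$feature_id
  meta <- if (is.character(metadata)) read_metadata_tsv(metadata) else as_tibble(metadata)
  matched <- meta[meta$sample_id %in% colnames(m), , drop = FALSE]
  if (is.null(study_id)) {
    sid <- unique(matched$study_id)
    if (length(sid) != 1) {
      abort(sprintf("'%s': samples map to %d study ids; pass `study_id` explicitly.",
                    path, length(sid)),
            class = "stretchsig_parse_error")
    }
    study_id <- sid
  }
  # every metadata row of this study must have a matrix column
  orphans <- setdiff(meta$sample_id[meta$study_id == study_id], colnames(m))
  if (length(orphans)) {
    abort(sprintf("'%s': metadata row(s) without matrix column: %s", path,
                  paste(orphans, collapse = ", ")),
          class = "stretchsig_parse_error")
  }
  expr_study(study_id = study_id, expr = m, samples = matched)
}

#' @rdname read_expression_tsv
#' @export
read_metadata_tsv <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), study_id = readr::col_character(),
    stretch = readr::col_integer(), second_hit = readr::col_integer(),
    magnitude = readr::col_double()
  ), progress = FALSE)
  if (anyDuplicated(meta$sample_id)) {
    dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
    abort(sprintf("'%s': duplicated sample id(s): %s", path,
                  paste(dup, collapse = ", ")),
          class = "stretchsig_parse_error")
  }
  meta
}

#' Write studies as expression + metadata TSV files
#'
#' Each study is written as `<study_id>_expression.tsv`; one shared
#' `metadata.tsv` covers all samples. The dialect round-trips losslessly
#' through [read_expression_tsv()].
#'
#' @param studies List of [expr_study()] objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_studies_tsv <- function(studies, dir) {
  check_studies(studies)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- map_chr(studies, function(s) {
    p <- file.path(dir, paste0(s$study_id, "_expression.tsv"))
    write_expression_tsv(s, p)
    p
  })
  meta_path <- file.path(dir, "metadata.tsv")
  readr::write_tsv(bind_rows(lapply(studies, function(s) s$samples)), meta_path)
  invisible(c(paths, meta_path))
}

#' @rdname write_studies_tsv
#' @param study An [expr_study()].
#' @param path Output path.
#' @export
write_expression_tsv <- function(study, path) {
  df <- bind_cols(tibble(feature_id = rownames(study$expr)),
                  as_tibble(study$expr))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Signature, DE-table, score and target-map TSV dialects
#'
#' Signatures are two-column TSVs (`feature_id`, `direction` in
#' `up`/`down`); DE tables, score reports and target maps are written with
#' their full column sets. All are plain UTF-8 TSVs that round-trip exactly.
#'
#' @param sig A [signature_set()].
#' @param path File path.
#' @return The read counterparts return the corresponding object; writers
#'   return the path invisibly.
#' @export
write_signature_tsv <- function(sig, path) {
  readr::write_tsv(tidy(sig), path)
  invisible(path)
}

#' @rdname write_signature_tsv
#' @export
read_signature_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    feature_id = readr::col_character(), direction = readr::col_character()
  ), progress = FALSE)
  signature_set(up = df$feature_id[df$direction == "up"],
                down = df$feature_id[df$direction == "down"],
                label = sub("\\.tsv$", "", basename(path)))
}

#' @rdname write_signature_tsv
#' @param de A DE table from [run_de()].
#' @export
write_de_tsv <- function(de, path) {
  readr::write_tsv(de, path)
  invisible(path)
}

#' @rdname write_signature_tsv
#' @param scores A `score_report` from [score_samples()].
#' @export
write_scores_tsv <- function(scores, path) {
  readr::write_tsv(as_tibble(scores), path)
  invisible(path)
}

#' @rdname write_signature_tsv
#' @export
read_target_map_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    mirna_id = readr::col_character(), gene_id = readr::col_character()
  ), progress = FALSE)
}

#' @rdname write_signature_tsv
#' @param target_map Tibble with `mirna_id`, `gene_id`.
#' @export
write_target_map_tsv <- function(target_map, path) {
  readr::write_tsv(target_map[, c("mirna_id", "gene_id")], path)
  invisible(path)
}

#' Serialize an evaluation report (or ground truth) to JSON
#'
#' @param report An `evaluation_report` from [evaluate_signature()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_evaluation_json <- function(report, path) {
  x <- list(
    signature = list(label = report$signature$label,
                     up = report$signature$up, down = report$signature$down),
    auroc = report$auroc[c("auroc", "ci_low", "ci_high", "n_pos", "n_neg",
                           "B", "conf")],
    null = list(k_up = report$null$k_up, k_down = report$null$k_down,
                B = report$null$B, threshold = report$null$threshold,
                exceedance = report$null$exceedance,
                median_auroc = stats::median(report$null$null_aurocs)),
    leave_one_out = report$leave_one_out,
    magnitude_correlation = report$magnitude_correlation,
    seed = report$seed
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_evaluation_json
#' @param truth A `synthetic_truth` from [generate_studies()].
#' @export
write_truth_json <- function(truth, path) {
  x <- list(
    up_features = truth$up_features, down_features = truth$down_features,
    hit_features = truth$hit_features, effects = truth$effects,
    batches = truth$batches, seed = truth$seed
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
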
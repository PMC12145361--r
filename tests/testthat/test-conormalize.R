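test_that("feature intersection is sorted, deterministic, and validated", {
  a <- make_tiny_study("a")
  b <- make_tiny_study("b")
  expect_identical(intersect_features(list(a, b)), sort(rownames(a$expr)))

  rownames(b$expr) <- c(rownames(a$expr)[2:6], "fXX")
  expect_identical(intersect_features(list(a, b)), sort(rownames(a$expr)[2:6]))

  rownames(b$expr) <- paste0("g", 1:6)
  expect_error(intersect_features(list(a, b)),
               class = "stretchsig_empty_intersection")
})

test_that("a single study is its own reference: unit batch parameters and identity pooling", {
  s <- make_tiny_study("solo", n_features = 10, n_ctrl = 4, n_case = 4)
  params <- fit_control_batch_params(list(s), eb = FALSE)
  expect_equal(unname(params$gamma_star[, 1]), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(params$delta2_star[, 1]), rep(1, 10), tolerance = 1e-12)

  pm <- coconut(list(s), eb = FALSE)
  expect_lt(max(abs(pm$expr - s$expr[rownames(pm$expr), ])), 1e-8)
})

test_that("a constant +3 batch shift is recovered exactly and removed on pooling", {
  pair <- shifted_pair_studies(delta = 3)
  params <- fit_control_batch_params(list(pair$a, pair$b), eb = FALSE)
  # on the standardized scale the recovered location difference is 3 / sigma
  expect_equal(unname(params$gamma_star[, "B"] - params$gamma_star[, "A"]),
               unname(3 / params$sigma), tolerance = 1e-10)

  pm <- apply_batch_params(list(pair$a, pair$b), params)
  ctrl_a <- rowMeans(pm$expr[, pm$samples$study_id == "A" & pm$samples$stretch == 0])
  ctrl_b <- rowMeans(pm$expr[, pm$samples$study_id == "B" & pm$samples$stretch == 0])
  expect_equal(ctrl_a, ctrl_b, tolerance = 1e-10)

  # the planted case-control contrast of the shifted study is untouched
  raw_diff <- rowMeans(pair$b$expr[, 4:6]) - rowMeans(pair$b$expr[, 1:3])
  b_cols <- pm$samples$study_id == "B"
  adj_diff <- rowMeans(pm$expr[, b_cols & pm$samples$stretch == 1]) -
    rowMeans(pm$expr[, b_cols & pm$samples$stretch == 0])
  expect_equal(unname(adj_diff), unname(raw_diff), tolerance = 1e-10)
})

test_that("empirical-Bayes iteration converges to the requested tolerance", {
  g <- generate_studies(sim_config(n_studies = 3, features = 100,
                                   samples_per_group = 6, seed = 2))
  params <- fit_control_batch_params(g$studies, eb = TRUE, tol = 1e-6)
  shrunk <- params$hyper[params$hyper$shrunk, ]
  expect_gt(nrow(shrunk), 0)
  expect_true(all(shrunk$converge_delta < 1e-6))
  expect_true(all(shrunk$iterations <= params$max_iter))
  expect_true(all(params$delta2_star > 0))
})

test_that("degenerate inputs are rejected with the offending study named", {
  s1 <- make_tiny_study("one_ctrl", n_ctrl = 1, n_case = 5)
  s2 <- make_tiny_study("fine")
  expect_error(fit_control_batch_params(list(s1, s2)), "one_ctrl")

  s3 <- make_tiny_study("nonfinite")
  s3$expr[1, 1] <- NA
  expect_error(fit_control_batch_params(list(s3, s2)), "nonfinite")

  params <- fit_control_batch_params(list(s2), eb = FALSE)
  expect_error(apply_batch_params(list(make_tiny_study("stranger")), params),
               "stranger")
})

test_that("zero-variance features are floored and flagged instead of dropped", {
  s <- make_tiny_study("flat", n_features = 5)
  s$expr[1, ] <- 7  # constant feature
  params <- fit_control_batch_params(list(s, make_tiny_study("other")),
                                     eb = FALSE)
  expect_true("f01" %in% params$floored_features)
  expect_true(all(is.finite(params$gamma_star)))
})

test_that("batch correction is invertible given its parameters", {
  g <- generate_studies(sim_config(n_studies = 3, features = 60,
                                   samples_per_group = 5, seed = 13))
  pm <- coconut(g$studies, eb = TRUE)
  raw <- do.call(cbind, lapply(g$studies, function(s) s$expr[rownames(pm$expr), ]))
  expect_lt(max(abs(stretchsig:::invert_batch_params(pm) - raw)), 1e-8)
})

test_that("with noise and EB, pooling tightens cross-study control means in nearly all runs", {
  improved <- vapply(1:20, function(seed) {
    g <- generate_studies(sim_config(n_studies = 3, features = 80,
                                     samples_per_group = 8, batch_loc_sd = 1.5,
                                     seed = seed))
    common <- intersect_features(g$studies)
    ctrl_means <- function(mat, samples) {
      vapply(split(seq_len(ncol(mat)), samples$study_id), function(i) {
        rowMeans(mat[, i[samples$stretch[i] == 0], drop = FALSE])
      }, numeric(nrow(mat)))
    }
    pairdiff <- function(cm) {
      pr <- utils::combn(ncol(cm), 2)
      mean(apply(pr, 2, function(p) mean(abs(cm[, p[1]] - cm[, p[2]]))))
    }
    pm <- coconut(g$studies, eb = TRUE)
    raw <- do.call(cbind, lapply(g$studies, function(s) s$expr[common, ]))
    pairdiff(ctrl_means(pm$expr, pm$samples)) <
      pairdiff(ctrl_means(raw, pm$samples))
  }, logical(1))
  expect_gte(mean(improved), 0.95)
})

test_that("pooling is deterministic for a fixed generator seed", {
  cfg <- sim_config(n_studies = 2, features = 30, seed = 21)
  pm1 <- coconut(generate_studies(cfg)$studies)
  pm2 <- coconut(generate_studies(cfg)$studies)
  expect_identical(pm1$expr, pm2$expr)
})
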
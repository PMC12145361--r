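test_that("with a constant second hit the model reduces to the pooled-variance t-test", {
  set.seed(1)
  y <- rnorm(12, 8)
  stretch <- rep(c(0, 1), each = 6)
  fit <- fit_feature_model(y, stretch, second_hit = rep(0, 12))
  ht <- stats::t.test(y[stretch == 1], y[stretch == 0], var.equal = TRUE)
  expect_equal(fit$p_stretch, ht$p.value, tolerance = 1e-10)
  expect_equal(fit$beta_stretch, unname(ht$estimate[1] - ht$estimate[2]),
               tolerance = 1e-10)
  expect_true(is.na(fit$beta_hit))
})

test_that("two-factor coefficients and p-values match an independent lm() fit", {
  set.seed(7)
  for (rep in 1:5) {
    stretch <- sample(rep(c(0, 1), each = 6))
    hit <- sample(rep(c(0, 1), times = c(8, 4)))
    if (qr(cbind(1, stretch, hit))$rank < 3) next
    y <- rnorm(12, 8) + 0.9 * stretch - 0.4 * hit
    fit <- fit_feature_model(y, stretch, hit)
    cf <- summary(stats::lm(y ~ stretch + hit))$coefficients
    expect_equal(fit$beta_stretch, cf["stretch", "Estimate"], tolerance = 1e-10)
    expect_equal(fit$beta_hit, cf["hit", "Estimate"], tolerance = 1e-10)
    expect_equal(fit$p_stretch, cf["stretch", "Pr(>|t|)"], tolerance = 1e-10)
    expect_equal(fit$p_hit, cf["hit", "Pr(>|t|)"], tolerance = 1e-10)
  }
})

test_that("degenerate fits are reported untested, not as errors", {
  stretch <- rep(c(0, 1), each = 4)
  const <- fit_feature_model(rep(5, 8), stretch, rep(0, 8))
  expect_false(const$tested)
  expect_equal(const$beta_stretch, 0)
  expect_true(is.na(const$p_stretch))

  collinear <- fit_feature_model(rnorm(8), stretch, stretch)
  expect_false(collinear$tested)
  expect_true(is.na(collinear$p_stretch))

  expect_error(fit_feature_model(rnorm(4), rep(1, 4), rep(0, 4)),
               class = "stretchsig_validation_error")
})

test_that("Benjamini-Hochberg adjustment handles the hand-worked cases", {
  expect_equal(adjust_bh(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.37), 0.37)
  expect_error(adjust_bh(c(0.5, 1.2)), class = "stretchsig_validation_error")
  expect_error(adjust_bh(c(-0.1, 0.5)), class = "stretchsig_validation_error")
})

test_that("NA p-values are excluded from the family and returned as NA", {
  p <- c(0.01, NA, 0.02, 0.03, NA, 0.04)
  adj <- adjust_bh(p)
  expect_true(all(is.na(adj[c(2, 5)])))
  expect_equal(adj[!is.na(p)], adjust_bh(c(0.01, 0.02, 0.03, 0.04)))
})

test_that("adjustment agrees with the brute-force step-up definition and dominates raw p", {
  set.seed(33)
  for (rep in 1:50) {
    p <- round(stats::runif(sample(3:40, 1)), 3)
    adj <- adjust_bh(p)
    expect_equal(adj, bh_brute_force(p), tolerance = 1e-15)
    expect_true(all(adj >= p & adj <= 1))
  }
})

test_that("signature selection applies thresholds, directions and the stretch-only partition", {
  de <- tibble::tibble(
    feature_id = c("A", "B", "C", "D"),
    beta_stretch = c(2, 0.1, -1.5, 1),
    beta_hit = c(0, 0, 0, 2),
    p_stretch = c(1e-4, 0.4, 1e-4, 1e-4),
    p_hit = c(0.9, 0.9, 0.9, 1e-5),
    padj_stretch = c(0.005, 0.5, 0.002, 0.004),
    padj_hit = c(0.9, 0.9, 0.9, 0.001),
    direction = c("up", "up", "down", "up"),
    tested = TRUE
  )
  sig <- select_signature(de, alpha = 0.01)
  expect_identical(sig$up, c("A", "D"))
  expect_identical(sig$down, "C")
  expect_identical(attr(sig, "counts"),
                   c(stretch_only = 2L, hit_only = 0L, both = 1L))

  sig_only <- select_signature(de, alpha = 0.01, stretch_only = TRUE)
  expect_identical(sig_only$up, "A")

  expect_error(select_signature(de, alpha = 1e-5),
               class = "stretchsig_empty_signature")
})

test_that("signature selection is monotone in alpha", {
  g <- generate_studies(sim_config(n_studies = 1, features = 100,
                                   samples_per_group = 30, seed = 44))
  de <- run_de(coconut(g$studies, eb = FALSE))
  alphas <- c(0.001, 0.01, 0.05, 0.2)
  sigs <- lapply(alphas, function(a) {
    tryCatch(select_signature(de, a), error = function(e) NULL)
  })
  for (i in seq_len(length(sigs) - 1)) {
    if (is.null(sigs[[i]]) || is.null(sigs[[i + 1]])) next
    expect_true(all(sigs[[i]]$up %in% sigs[[i + 1]]$up))
    expect_true(all(sigs[[i]]$down %in% sigs[[i + 1]]$down))
  }
})

test_that("planted features are recovered at alpha = 0.01", {
  g <- generate_studies(sim_config(n_studies = 1, features = 100,
                                   samples_per_group = 50, n_up = 10,
                                   n_down = 10, effect_size = 1.5, seed = 55))
  de <- run_de(coconut(g$studies, eb = FALSE))
  sig <- select_signature(de, alpha = 0.01)
  planted <- c(g$truth$up_features, g$truth$down_features)
  found <- c(sig$up, sig$down)
  expect_gte(mean(planted %in% found), 0.9)
})

test_that("target filtering is plain set algebra with a warning for unknown miRNAs", {
  tm <- tibble::tibble(mirna_id = c("m1", "m1"), gene_id = c("g1", "g2"))
  expect_identical(filter_by_targets(c("g2", "g3"), tm, "m1"), "g2")
  expect_identical(
    filter_by_targets(character(), tm, "m1"), character()
  )
  expect_warning(out <- filter_by_targets(c("g1"), tm, c("m1", "mX")), "mX")
  expect_identical(out, "g1")
  empty <- tibble::tibble(mirna_id = character(), gene_id = character())
  expect_identical(filter_by_targets(c("g1"), empty, character()), character())
})

test_that("decoy-diluted target maps filter DE genes back to the planted set", {
  cfg <- sim_config(n_studies = 2, features = 80, samples_per_group = 40,
                    n_up = 5, n_down = 5, effect_size = 2, seed = 66)
  g <- generate_studies(cfg)
  tm <- generate_target_map(g$truth, cfg, n_mirnas = 4, n_decoys = 10)
  de <- run_de(coconut(g$studies, eb = FALSE))
  sig <- select_signature(de, alpha = 0.01)
  selected <- c(sig$up, sig$down)
  planted <- c(g$truth$up_features, g$truth$down_features)
  filtered <- filter_by_targets(selected, tm, unique(tm$mirna_id))
  # decoys are non-planted, so filtering keeps exactly the planted DE genes
  # (plus any decoy that happened to reach significance by chance)
  expect_setequal(setdiff(filtered, unique(tm$gene_id)), character())
  expect_true(all(intersect(selected, planted) %in% filtered))
})
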
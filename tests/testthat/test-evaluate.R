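test_that("AUROC handles separation, ties and the enumerated example", {
  expect_equal(auroc(c(1, 2, 9, 10), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(rep(3, 6), rep(c(0, 1), 3)), 0.5)
  expect_equal(auroc(c(3, 1, 2, 4), c(0, 1, 0, 1)), 0.5)
  expect_error(auroc(1:4, rep(1, 4)), class = "stretchsig_single_class")
})

test_that("AUROC agrees with pROC on random tied instances", {
  skip_if_not_installed("pROC")
  set.seed(12)
  for (i in 1:50) {
    n <- sample(6:20, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(1:5, n, replace = TRUE)  # heavy ties
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auroc(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("AUROC is rank-based: invariant to monotone transforms, complement under negation", {
  set.seed(13)
  scores <- rnorm(30)
  labels <- rep(c(0, 1), 15)
  a <- auroc(scores, labels)
  expect_equal(auroc(exp(scores), labels), a)
  expect_equal(auroc(rank(scores), labels), a)
  expect_equal(auroc(-scores, labels), 1 - a)
})

test_that("bootstrap CI is deterministic, bounded, and degenerate at perfect separation", {
  scores <- c(rnorm(10, 0), rnorm(10, 10))
  labels <- rep(c(0, 1), each = 10)
  res <- auroc_ci(scores, labels, B = 200, seed = 5)
  expect_equal(res$auroc, 1)
  expect_equal(res$ci_high, 1)
  expect_equal(res$ci_low, 1)  # every stratified resample still separates
  res2 <- auroc_ci(scores, labels, B = 200, seed = 5)
  expect_identical(res, res2)
  expect_error(auroc_ci(scores, labels, B = 50),
               class = "stretchsig_validation_error")
})

test_that("bootstrap CI covers 0.5 at roughly nominal rate under the null", {
  set.seed(6)
  covered <- vapply(1:40, function(i) {
    scores <- rnorm(60)
    labels <- rep(c(0, 1), 30)
    res <- auroc_ci(scores, labels, B = 300, seed = i)
    res$ci_low <= 0.5 && res$ci_high >= 0.5
  }, logical(1))
  expect_gte(mean(covered), 0.8)
})

test_that("random-signature null is reproducible and respects its bounds", {
  set.seed(14)
  m <- matrix(rexp(50 * 30) + 0.1, 50, 30,
              dimnames = list(sprintf("f%02d", 1:50), sprintf("s%02d", 1:30)))
  labels <- rep(c(0, 1), 15)
  nd <- random_signature_null(m, labels, k_up = 4, k_down = 2, B = 200,
                              seed = 3)
  expect_identical(nd$null_aurocs,
                   random_signature_null(m, labels, k_up = 4, k_down = 2,
                                         B = 200, seed = 3)$null_aurocs)
  expect_true(all(nd$null_aurocs >= 0 & nd$null_aurocs <= 1))
  expect_equal(random_signature_null(m, labels, k_up = 4, k_down = 2, B = 50,
                                     seed = 3, threshold = 0)$exceedance, 1)
  expect_error(random_signature_null(m, labels, k_up = 40, k_down = 20,
                                     B = 10, seed = 1),
               class = "stretchsig_validation_error")
})

test_that("leave-one-study-out: symmetry on identical studies and one row per study", {
  s1 <- make_tiny_study("dup1", n_features = 8, n_ctrl = 4, n_case = 4,
                        offset = 2, seed = 9)
  s2 <- make_tiny_study("dup2", n_features = 8, n_ctrl = 4, n_case = 4,
                        offset = 2, seed = 9)
  sig <- signature_set(up = rownames(s1$expr)[1:3])
  loso <- leave_one_study_out(list(s1, s2), sig, B = 100, seed = 2)
  expect_equal(nrow(loso), 2)
  expect_equal(loso$auroc[1], loso$auroc[2], tolerance = 1e-8)

  three <- list(s1, s2, make_tiny_study("dup3", n_features = 8, n_ctrl = 4,
                                        n_case = 4, offset = 2, seed = 9))
  expect_equal(nrow(leave_one_study_out(three, sig, B = 100, seed = 2)), 3)
})

test_that("excluding a label-corrupted study restores the best AUROC", {
  g <- generate_studies(sim_config(n_studies = 3, features = 40,
                                   samples_per_group = 12, n_up = 8,
                                   n_down = 0, effect_size = 2, seed = 31))
  studies <- g$studies
  # corrupt study 2: shuffle its stretch labels
  set.seed(8)
  studies[[2]]$samples$stretch <- sample(studies[[2]]$samples$stretch)
  sig <- signature_set(up = g$truth$up_features)
  loso <- leave_one_study_out(studies, sig, B = 100, seed = 4)
  expect_identical(loso$excluded_study[which.max(loso$auroc)], "study_02")
})

test_that("rounds left with a single class are flagged, not fatal", {
  ctrl_only <- make_tiny_study("ctrl_only", n_ctrl = 6, n_case = 0)
  with_cases <- make_tiny_study("with_cases", n_ctrl = 4, n_case = 4,
                                offset = 1.5)
  sig <- signature_set(up = rownames(ctrl_only$expr)[1:2])
  loso <- leave_one_study_out(list(ctrl_only, with_cases), sig, B = 100,
                              seed = 1)
  flagged <- loso[loso$excluded_study == "with_cases", ]
  expect_true(flagged$flagged)
  expect_true(is.na(flagged$auroc))
  expect_false(loso$flagged[loso$excluded_study == "ctrl_only"])
})

test_that("Spearman correlation handles monotone, antitone and tied data", {
  expect_equal(spearman_cor(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_cor(1:8, -(1:8))$rho, -1)
  x <- c(1, 2, 2, 3, 4, 4, 5)
  y <- c(2, 1, 3, 3, 5, 6, 5)
  got <- spearman_cor(x, y)
  ref <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
  expect_error(spearman_cor(rep(1, 5), 1:5),
               class = "stretchsig_validation_error")
  expect_error(spearman_cor(1:2, 1:2), class = "stretchsig_validation_error")
})

test_that("group comparison: pooled t-test for two groups, ANOVA + Tukey beyond", {
  x <- c(1, 2, 3, 1, 2, 3)
  same <- compare_groups(x, rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  set.seed(15)
  g1 <- rnorm(8, 0); g2 <- rnorm(8, 1)
  res <- compare_groups(c(g1, g2), rep(c("a", "b"), each = 8))
  sp <- sqrt((7 * var(g1) + 7 * var(g2)) / 14)
  t_manual <- (mean(g1) - mean(g2)) / (sp * sqrt(2 / 8))
  expect_equal(abs(res$statistic), abs(t_manual), tolerance = 1e-10)
  expect_equal(res$p.value, 2 * pt(abs(t_manual), 14, lower.tail = FALSE),
               tolerance = 1e-10)

  scores <- c(rnorm(6, 0), rnorm(6, 2), rnorm(6, 4))
  grp <- rep(c("a", "b", "c"), each = 6)
  res3 <- compare_groups(scores, grp)
  expect_identical(res3$method, "anova")
  ref <- anova(stats::lm(scores ~ grp))
  expect_equal(res3$p.value, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  expect_equal(nrow(res3$tukey), 3)

  expect_error(compare_groups(1:3, c("a", "a", "b")),
               class = "stretchsig_validation_error")
})

test_that("evaluate_signature bundles accuracy, null, robustness and tidiers work", {
  g <- generate_studies(sim_config(n_studies = 3, features = 50,
                                   samples_per_group = 8, n_up = 6, n_down = 2,
                                   effect_size = 2, dose_response_slope = 0.05,
                                   magnitude_per_study = c(10, 15, 30),
                                   seed = 91))
  pooled <- coconut(g$studies)
  sig <- signature_set(up = g$truth$up_features, down = g$truth$down_features)
  rep <- evaluate_signature(pooled, sig, studies = g$studies, B = 150,
                            seed = 10)
  expect_s3_class(rep, "evaluation_report")
  expect_true(rep$auroc$ci_low <= rep$auroc$auroc &&
                rep$auroc$auroc <= rep$auroc$ci_high)
  expect_equal(nrow(rep$leave_one_out), 3)
  expect_false(is.null(rep$magnitude_correlation))

  gl <- glance(rep)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$auroc, rep$auroc$auroc)
  td <- tidy(rep)
  expect_identical(td, rep$leave_one_out)
  expect_s3_class(autoplot(rep$scores), "ggplot")
  expect_s3_class(autoplot(rep$null), "ggplot")
})
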
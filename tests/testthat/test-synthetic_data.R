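test_that("generation is deterministic and respects the presence floor", {
  c1 <- small_collection(seed = 3)
  c2 <- small_collection(seed = 3)
  expect_identical(c1$datasets[[2]]$values, c2$datasets[[2]]$values)
  expect_identical(c1$presence, c2$presence)
  c3 <- small_collection(seed = 4)
  expect_false(identical(c1$datasets[[1]]$values, c3$datasets[[1]]$values))

  # brute-force scan of the presence mask against the L* floor
  design <- planted_design(n_genes = 500, n_datasets = 16,
                           samples_per_dataset = rep(4, 16),
                           clusters = c(50), noise_sd = 0.3,
                           min_presence = 13, missing_fraction = 0.15, seed = 1)
  coll <- generate_collection(design)
  per_gene <- vapply(rownames(coll$presence), function(g)
    sum(vapply(coll$datasets, function(d) g %in% rownames(d$values), TRUE)),
    0L)
  expect_true(all(per_gene >= 13))
  expect_identical(unname(rowSums(coll$presence)), as.numeric(per_gene))
})

test_that("zero-noise planted clusters are perfectly tight and anti-correlated", {
  coll <- small_collection(noise_sd = 0, missing_fraction = 0)
  truth <- attr(coll, "truth")
  norm <- normalise_collection(coll)
  # identical raw profiles stay identical through normalisation: zero MSE
  expect_equal(cluster_mse(truth$clusters[[1]], norm), 0, tolerance = 1e-12)
  for (l in seq_along(coll$datasets)) {
    raw <- coll$datasets[[l]]
    # pairwise Pearson correlation within a planted cluster is exactly 1
    x <- raw$values[intersect(truth$clusters[[1]], rownames(raw$values)), ]
    cc <- cor(t(x))
    expect_equal(max(abs(cc - 1)), 0, tolerance = 1e-9)
    # anti-correlated pair: generated mean profiles at exactly rho = -1
    expect_equal(cluster_profile_correlation(truth$clusters[[1]],
                                             truth$clusters[[2]], raw),
                 -1, tolerance = 1e-9)
    # the (non-linear) normalisation preserves strong anti-correlation
    expect_lt(cluster_profile_correlation(truth$clusters[[1]],
                                          truth$clusters[[2]],
                                          norm$datasets[[l]]), -0.95)
  }
})

test_that("infeasible designs are rejected", {
  expect_error(planted_design(10, 2, c(4, 4), clusters = c(8, 8)),
               "exceed n_genes")
  expect_error(planted_design(10, 4, rep(4, 4), min_presence = 4,
                              missing_fraction = 0.5),
               "incompatible")
  expect_error(planted_design(10, 2, c(4, 4), noise_sd = -1), "non-negative")
  expect_error(planted_design(10, 2, c(4, 4),
                              clusters = c(5), anticorrelated_pairs = list(c(1, 3))),
               "index the planted clusters")
})

test_that("clinical generator plants recoverable survival and ER structure", {
  sigs <- list(hyp = sprintf("H%03d", 1:40))
  # null effect: the Cox CI covers 0 in most seeded replicates
  covered <- vapply(1:30, function(s) {
    cohort <- generate_clinical(
      clinical_design(n_samples = 120, signature_effects = c(hyp = 0),
                      n_background_genes = 200, seed = s), sigs)
    cx <- cox_hr(hypoxia_score(sigs$hyp, cohort), cohort)
    abs(cx$beta) < 1.96 * cx$se
  }, TRUE)
  expect_gte(mean(covered), 0.9)

  # planted fold-change of 2 recovered through the ER ANOVA pipeline
  cohort <- generate_clinical(
    clinical_design(n_samples = 400, er_fold_changes = c(hyp = 2),
                    n_background_genes = 2000, seed = 11), sigs)
  est <- signature_er_test(sigs$hyp, cohort)
  expect_gt(est$fold_change, 1.5)
  expect_lt(est$fold_change, 2.5)
  expect_lt(est$p_log_fold_change, 1e-6)

  # survival invariants
  expect_true(all(cohort$os_time > 0))
  expect_true(all(cohort$os_event %in% c(0, 1)))
  cohort2 <- generate_clinical(
    clinical_design(n_samples = 400, er_fold_changes = c(hyp = 2),
                    n_background_genes = 2000, seed = 11), sigs)
  expect_identical(cohort$expression, cohort2$expression)
})

test_that("clinical generator rejects bad configurations", {
  expect_error(clinical_design(100, censoring_rate = -0.1), "censoring_rate")
  expect_error(clinical_design(100, baseline_hazard = 0), "positive")
  d <- clinical_design(50)
  expect_error(generate_clinical(d, list()), "non-empty")
  expect_error(generate_clinical(d, list(a = character(0))), "non-empty")
})
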
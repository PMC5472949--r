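test_that("hypoxia scores are rank-scaled signature medians", {
  # medians [5, 1, 3, 9] -> HS [2/3, 0, 1/3, 1]
  x <- matrix(c(5, 1, 3, 9, 5, 1, 3, 9, 5, 1, 3, 9), 3, 4, byrow = TRUE,
              dimnames = list(c("S1", "S2", "S3"), NULL))
  coh <- fixed_cohort(x)
  hs <- hypoxia_score(c("S1", "S2", "S3"), coh)
  expect_equal(hs$scores, c(2 / 3, 0, 1 / 3, 1))
  # all medians tied: every score 0.5
  flat <- fixed_cohort(matrix(4, 3, 5, dimnames = list(c("A", "B", "C"), NULL)))
  expect_equal(hypoxia_score(c("A", "B"), flat)$scores, rep(0.5, 5))
  # invariant under strictly increasing transforms (rank-based; an odd
  # signature size makes the per-sample median a single order statistic)
  set.seed(3)
  y <- matrix(exp(rnorm(60)), 6, 10,
              dimnames = list(sprintf("g%d", 1:6), NULL))
  h1 <- hypoxia_score(rownames(y)[1:5], fixed_cohort(y))$scores
  h2 <- hypoxia_score(rownames(y)[1:5], fixed_cohort(y^3))$scores
  expect_equal(h1, h2)
  expect_true(all(h1 >= 0 & h1 <= 1))
  expect_error(hypoxia_score("MISSING", fixed_cohort(y)), "no signature gene")
})

test_that("Cox fit errors are raised for degenerate inputs", {
  y <- matrix(exp(rnorm(40)), 4, 10, dimnames = list(paste0("g", 1:4), NULL))
  no_events <- clinical_cohort(y, os_time = 1:10, os_event = rep(0L, 10),
                               normalise = FALSE)
  expect_error(cox_hr(rep(0.5, 10), no_events), "no events|variation")
  coh <- fixed_cohort(y)
  expect_error(cox_hr(rep(0.5, 10), coh), "no variation")
})

test_that("ROC AUC is the Mann-Whitney statistic with horizon labelling", {
  y <- matrix(exp(rnorm(20)), 2, 10, dimnames = list(c("g1", "g2"), NULL))
  # score identical to the outcome indicator: AUC = 1
  ev <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  coh <- clinical_cohort(y, os_time = c(rep(2, 4), rep(15, 6)),
                         os_event = ev, normalise = FALSE)
  r <- roc_auc(ev, coh, horizon_years = 10)
  expect_equal(r$auc, 1)
  # censored-before-horizon samples are excluded
  coh2 <- clinical_cohort(y, os_time = c(rep(2, 4), 3, rep(15, 5)),
                          os_event = c(rep(1, 4), 0, rep(0, 5)),
                          normalise = FALSE)
  r2 <- roc_auc(seq(0, 1, length.out = 10), coh2, horizon_years = 10)
  expect_identical(r2$n_positive + r2$n_negative, 9L)
  # independent score: AUC near 0.5 on a larger seeded cohort
  set.seed(8)
  n <- 400
  yy <- matrix(exp(rnorm(2 * n)), 2, n, dimnames = list(c("g1", "g2"), NULL))
  coh3 <- clinical_cohort(yy, os_time = rexp(n, 0.2), os_event = rep(1L, n),
                          normalise = FALSE)
  r3 <- roc_auc(runif(n), coh3, horizon_years = 5)
  expect_lt(abs(r3$auc - 0.5), 0.05)
  expect_error(roc_auc(runif(10), coh, horizon_years = 0.1), "one outcome class")
})

test_that("per-gene ER ANOVA equals the squared-t identity", {
  set.seed(12)
  n <- 60
  er <- rep(c("positive", "negative"), each = n / 2)
  y <- matrix(exp(rnorm(3 * n)), 3, n, dimnames = list(c("g1", "g2", "g3"), NULL))
  coh <- clinical_cohort(y, os_time = rep(1, n), os_event = rep(1L, n),
                         er_status = er, normalise = FALSE)
  for (g in rownames(y)) {
    got <- er_anova(coh, g)
    tt <- t.test(y[g, er == "positive"], y[g, er == "negative"],
                 var.equal = TRUE)
    expect_equal(got$p_value, tt$p.value, tolerance = 1e-12)
    expect_equal(got$fold_change,
                 mean(y[g, er == "positive"]) / mean(y[g, er == "negative"]),
                 tolerance = 1e-12)
  }
  # equal group means: fold change 1, p near 1
  z2 <- matrix(rep(c(5, 7), times = n / 2), 1, n,
               dimnames = list("flat", NULL))
  coh2 <- clinical_cohort(z2, rep(1, n), rep(1L, n), er, normalise = FALSE)
  got <- er_anova(coh2, "flat")
  expect_equal(got$fold_change, 1, tolerance = 1e-12)
  expect_gt(got$p_value, 0.99)
  # vectorised genome-wide path agrees with the single-gene path
  gw <- uncles:::er_stats_genomewide(coh)
  for (g in rownames(y)) {
    expect_equal(gw$p_value[gw$gene == toupper(g)], er_anova(coh, g)$p_value,
                 tolerance = 1e-12)
  }
})

test_that("signature-level ER test recovers a planted down-regulation", {
  sigs <- list(dn = sprintf("D%03d", 1:30))
  cohort <- generate_clinical(
    clinical_design(n_samples = 400, er_fold_changes = c(dn = 0.5),
                    n_background_genes = 2000, seed = 21), sigs)
  est <- signature_er_test(sigs$dn, cohort)
  expect_gt(est$fold_change, 0.45)
  expect_lt(est$fold_change, 0.56)
  expect_lt(est$p_log_fold_change, 1e-10)
  expect_error(signature_er_test("D001", cohort), "fewer than 2")
})

test_that("tightness test separates planted structure from random sets", {
  sigs <- list(tight = sprintf("T%03d", 1:40))
  cohort <- generate_clinical(
    clinical_design(n_samples = 150, n_background_genes = 800,
                    gene_noise_sd = 0.15, seed = 5), sigs)
  tt <- tightness_test(sigs$tight, cohort, n_random = 300, seed = 2)
  expect_lt(tt$p_value, 1e-6)
  # duplicated identical rows: zero dispersion, p ~ 0
  base <- exp(matrix(rnorm(20 * 50), 20, 50))
  dup <- rbind(base, matrix(base[1, ], 5, 50, byrow = TRUE))
  rownames(dup) <- sprintf("r%02d", 1:25)
  cohd <- fixed_cohort(dup)
  td <- tightness_test(sprintf("r%02d", 21:25), cohd, n_random = 100, seed = 1)
  expect_equal(td$mse, 0, tolerance = 1e-12)
  expect_lt(td$p_value, 1e-4)
  # a random set is unremarkable
  set.seed(9)
  rnd <- sample(rownames(cohort$expression), 40)
  tr <- tightness_test(rnd, cohort, n_random = 300, seed = 3)
  expect_gt(tr$p_value, 0.01)
})

test_that("sub-cluster discovery splits correlation blocks", {
  # two anti-correlated halves
  set.seed(4)
  s <- runif(80)
  up <- t(replicate(10, exp(s + rnorm(80, sd = 0.05))))
  dn <- t(replicate(10, exp(-s + rnorm(80, sd = 0.05))))
  x <- rbind(up, dn)
  rownames(x) <- c(sprintf("UP%02d", 1:10), sprintf("DN%02d", 1:10))
  coh <- fixed_cohort(x)
  sc <- subcluster_discovery(rownames(x), coh, min_size = 5)
  expect_length(sc$subclusters, 2)
  sets <- lapply(sc$subclusters, sort)
  expect_true(any(vapply(sets, identical, TRUE, sort(sprintf("UP%02d", 1:10)))))
  expect_true(any(vapply(sets, identical, TRUE, sort(sprintf("DN%02d", 1:10)))))
  # perfectly correlated genes form a single sub-cluster
  all_up <- up
  rownames(all_up) <- sprintf("u%02d", 1:10)
  one <- subcluster_discovery(rownames(all_up), fixed_cohort(all_up), min_size = 5)
  expect_length(one$subclusters, 1)
  # constant genes are excluded with a warning
  withc <- rbind(x, flat = rep(3, 80))
  expect_warning(subcluster_discovery(rownames(withc), fixed_cohort(withc)),
                 "constant")
})

test_that("signature correlations are Spearman on score vectors", {
  # anti-monotone signatures: correlation exactly -1
  s <- seq(0.1, 1, length.out = 20)
  x <- rbind(a1 = s, a2 = s * 2, b1 = 1.5 - s, b2 = 3 - 2 * s)
  coh <- fixed_cohort(x)
  sc <- signature_correlations(list(A = c("a1", "a2"), B = c("b1", "b2")), coh)
  expect_equal(diag(sc), c(A = 1, B = 1))
  expect_equal(sc["A", "B"], -1)
  expect_equal(sc, t(sc))
  # matches a direct rank-correlation recomputation
  set.seed(6)
  y <- matrix(exp(rnorm(100)), 5, 20, dimnames = list(paste0("g", 1:5), NULL))
  cohy <- fixed_cohort(y)
  sc2 <- signature_correlations(list(P = c("g1", "g2"), Q = c("g4", "g5")), cohy)
  hp <- apply(y[c("g1", "g2"), ], 2, median)
  hq <- apply(y[c("g4", "g5"), ], 2, median)
  expect_equal(sc2["P", "Q"], cor(rank(hp), rank(hq)), tolerance = 1e-12)
})

test_that("clinical probe-set rule uses variance with the percentile filter", {
  pr <- rbind(c(10, 12, 14, 16), c(100, 101, 99, 100.5))
  # both above q1; first has larger variance
  expect_identical(select_clinical_probeset(pr, q1 = 5), 1L)
  # only the low-variance probe passes the filter
  pr2 <- rbind(c(1, 1.2, 0.8, 1.1), c(10, 12, 14, 16))
  expect_identical(select_clinical_probeset(pr2, q1 = 5), 2L)
  pr3 <- rbind(c(1, 2, 1, 2), c(1, 4, 1, 4))
  expect_identical(select_clinical_probeset(pr3, q1 = 50), 2L)  # fallback
  expect_identical(select_clinical_probeset(pr[1, , drop = FALSE], 5), 1L)
})

test_that("profile correlation handles degenerate profiles", {
  x <- named_matrix(c(1, 2, 3, 3, 2, 1, 2, 2, 2), 3, c("a", "b", "flat"))
  ds <- expression_dataset(x, dataset_id = "d")
  expect_equal(cluster_profile_correlation("a", "b", ds), -1)
  expect_equal(cluster_profile_correlation("a", "a", ds), 1)
  expect_warning(r <- cluster_profile_correlation("a", "flat", ds), "constant")
  expect_true(is.na(r))
})
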
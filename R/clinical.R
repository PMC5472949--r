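#' Clinical cohort container
#'
#' Expression plus overall-survival and estrogen-receptor annotation for one
#' clinical dataset, sample-aligned.  Expression is quantile-normalised on
#' construction (the scale on which fold-changes are computed).
#'
#' @param expression genes x samples numeric matrix (gene ids as row names).
#' @param os_time positive overall-survival times (years).
#' @param os_event binary event indicator (1 = death observed).
#' @param er_status per-sample `"positive"`, `"negative"` or `NA`.
#' @param normalise quantile-normalise the expression (default TRUE; pass
#'   FALSE for matrices already normalised).
#' @return object of class `clinical_cohort`.
#' @export
clinical_cohort <- function(expression, os_time, os_event, er_status = NULL,
                            normalise = TRUE) {
  check_matrix(expression, "expression")
  if (is.null(rownames(expression)))
    stop_input("expression needs gene ids as row names")
  rownames(expression) <- canon_gene_id(rownames(expression))
  n <- ncol(expression)
  if (length(os_time) != n || length(os_event) != n)
    stop_input("os_time and os_event must have one entry per sample")
  if (any(os_time <= 0, na.rm = TRUE)) stop_input("os_time must be strictly positive")
  if (!all(os_event %in% c(0, 1))) stop_input("os_event must be binary")
  if (is.null(er_status)) er_status <- rep(NA_character_, n)
  if (length(er_status) != n) stop_input("er_status must have one entry per sample")
  er_status <- as.character(er_status)
  if (!all(er_status %in% c("positive", "negative") | is.na(er_status)))
    stop_input("er_status entries must be 'positive', 'negative' or NA")
  if (normalise) expression <- quantile_normalise(expression)
  structure(list(expression = expression, os_time = as.numeric(os_time),
                 os_event = as.integer(os_event), er_status = er_status),
            class = "clinical_cohort")
}

#' @export
print.clinical_cohort <- function(x, ...) {
  cat(sprintf(
    "clinical_cohort: %d genes x %d samples; %d events; ER + /- / NA: %d/%d/%d\n",
    nrow(x$expression), ncol(x$expression), sum(x$os_event),
    sum(x$er_status == "positive", na.rm = TRUE),
    sum(x$er_status == "negative", na.rm = TRUE), sum(is.na(x$er_status))))
  invisible(x)
}

#' Representative probe-set selection for clinical data
#'
#' Among the probe-sets of one gene, returns the index of the most variable
#' one (variance) among those whose expression exceeds the dataset-wide 25th
#' percentile in at least 25% of the samples; if none qualifies, the most
#' variable probe-set overall.
#'
#' @param probe_rows numeric matrix, one row per probe-set of the gene.
#' @param q1 dataset-wide 25th percentile of expression.
#' @return single probe-set row index.
#' @export
select_clinical_probeset <- function(probe_rows, q1) {
  check_matrix(probe_rows, "probe-set rows")
  if (nrow(probe_rows) == 1L) return(1L)
  v <- apply(probe_rows, 1, var)
  frac_above <- rowMeans(probe_rows > q1)
  qualifies <- frac_above >= 0.25
  pool <- if (any(qualifies)) which(qualifies) else seq_len(nrow(probe_rows))
  pool[which.max(v[pool])]
}

#' Hypoxia score of a signature over a cohort
#'
#' Summarises a gene signature per sample: the median expression of the
#' signature's (present) genes at each sample is ranked over samples
#' (average ranks on ties) and scaled to \[0, 1\] as (rank - 1)/(n - 1).
#' Being rank-based, the score is invariant under any strictly increasing
#' transform of the expression values.
#'
#' @param signature character vector of gene ids.
#' @param cohort a [clinical_cohort()].
#' @param signature_id label carried in the result.
#' @return object of class `hypoxia_score`: `signature_id`, `scores`
#'   (per-sample, in \[0, 1\]), `n_genes_used`.
#' @export
hypoxia_score <- function(signature, cohort, signature_id = "signature") {
  if (!inherits(cohort, "clinical_cohort"))
    stop_input("cohort must be a clinical_cohort")
  genes <- intersect(unique(canon_gene_id(signature)), rownames(cohort$expression))
  if (!length(genes)) stop_input("no signature gene is present in the cohort")
  x <- cohort$expression[genes, , drop = FALSE]
  med <- apply(x, 2, median)
  n <- length(med)
  scores <- if (n == 1) 0.5 else (rank(med) - 1) / (n - 1)
  structure(list(signature_id = signature_id, scores = unname(scores),
                 n_genes_used = length(genes)),
            class = "hypoxia_score")
}

#' @export
print.hypoxia_score <- function(x, ...) {
  cat(sprintf("hypoxia_score '%s': %d samples (from %d genes); mean %.3f\n",
              x$signature_id, length(x$scores), x$n_genes_used, mean(x$scores)))
  invisible(x)
}

as_score_vector <- function(hs) {
  if (inherits(hs, "hypoxia_score")) hs$scores else as.numeric(hs)
}

#' Univariate Cox proportional-hazards fit of a score
#'
#' Fits overall survival on a per-sample score (typically a
#' [hypoxia_score()]) by Cox partial likelihood with Efron tie handling.
#' The hazard ratio is per full 0-to-1 range of the score.
#'
#' @param hs a `hypoxia_score` or numeric per-sample score.
#' @param cohort a [clinical_cohort()].
#' @return object of class `cox_result`: `hazard_ratio`, `p_value` (Wald),
#'   `beta`, `se`, `n`, `n_events`.
#' @export
cox_hr <- function(hs, cohort) {
  if (!inherits(cohort, "clinical_cohort"))
    stop_input("cohort must be a clinical_cohort")
  s <- as_score_vector(hs)
  if (length(s) != ncol(cohort$expression))
    stop_input("score length does not match the cohort")
  if (sum(cohort$os_event) == 0) stop_input("no events in the cohort; cannot fit")
  if (sd(s) == 0) stop_input("score has no variation; cannot fit")
  fit <- survival::coxph(
    survival::Surv(cohort$os_time, cohort$os_event) ~ s, ties = "efron")
  sm <- summary(fit)
  structure(list(hazard_ratio = unname(exp(coef(fit))),
                 p_value = unname(sm$coefficients[1, "Pr(>|z|)"]),
                 beta = unname(coef(fit)),
                 se = unname(sm$coefficients[1, "se(coef)"]),
                 n = sm$n, n_events = sm$nevent),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH: HR = %.3f (beta = %.3f +/- %.3f), p = %.3g, %d/%d events\n",
              x$hazard_ratio, x$beta, x$se, x$p_value, x$n_events, x$n))
  invisible(x)
}

#' ROC AUC of a score for death within a horizon
#'
#' Labels each sample by whether death was observed within
#' `horizon_years`; samples censored before the horizon are excluded (their
#' label is unknown).  The AUC is the Mann-Whitney statistic of the score
#' between the two classes; the p-value comes from the normal-approximated
#' Mann-Whitney test.
#'
#' @param hs a `hypoxia_score` or numeric score.
#' @param cohort a [clinical_cohort()].
#' @param horizon_years outcome horizon (default 10).
#' @return list with `auc`, `p_value`, `n_positive`, `n_negative`.
#' @export
roc_auc <- function(hs, cohort, horizon_years = 10) {
  if (!inherits(cohort, "clinical_cohort"))
    stop_input("cohort must be a clinical_cohort")
  s <- as_score_vector(hs)
  pos <- cohort$os_event == 1 & cohort$os_time <= horizon_years
  unknown <- cohort$os_event == 0 & cohort$os_time < horizon_years
  keep <- !unknown
  pos <- pos[keep]
  s <- s[keep]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop_input("only one outcome class within the %g-year horizon", horizon_years)
  r <- rank(s)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  p <- wilcox.test(s[pos], s[!pos], exact = FALSE)$p.value
  list(auc = auc, p_value = p, n_positive = n1, n_negative = n0)
}

er_groups <- function(cohort) {
  if (all(is.na(cohort$er_status)))
    stop_input("no ER status available in the cohort")
  keep <- !is.na(cohort$er_status)
  if (length(unique(cohort$er_status[keep])) < 2)
    stop_input("both ER classes must be present")
  keep
}

#' Per-gene ER-status ANOVA and fold-change
#'
#' One-way two-group ANOVA of a gene's expression between ER-positive and
#' ER-negative samples.  The expression is standardised (zero mean, unit
#' population sd) before the ANOVA; the fold-change is the ratio of the
#' ER+ to the ER- group mean on the unstandardised (quantile-normalised,
#' positive-scale) expression.
#'
#' @param cohort a [clinical_cohort()] with ER annotation.
#' @param gene single gene id.
#' @return list with `fold_change` and `p_value`.
#' @export
er_anova <- function(cohort, gene) {
  if (!inherits(cohort, "clinical_cohort"))
    stop_input("cohort must be a clinical_cohort")
  gene <- canon_gene_id(gene)
  if (!gene %in% rownames(cohort$expression))
    stop_input("gene '%s' not in the cohort", gene)
  keep <- er_groups(cohort)
  x <- cohort$expression[gene, keep]
  grp <- factor(cohort$er_status[keep], levels = c("negative", "positive"))
  s <- pop_sd(x)
  z <- if (s > 0) (x - mean(x)) / s else x - mean(x)
  p <- anova(lm(z ~ grp))[["Pr(>F)"]][1]
  fc <- mean(x[grp == "positive"]) / mean(x[grp == "negative"])
  list(fold_change = fc, p_value = if (is.na(p)) 1 else p)
}

# vectorised genome-wide two-group ANOVA (F = t^2 identity) on the
# quantile-normalised expression; p-values are identical to per-gene
# er_anova since the F statistic is location/scale invariant
er_stats_genomewide <- function(cohort) {
  keep <- er_groups(cohort)
  x <- cohort$expression[, keep, drop = FALSE]
  grp <- cohort$er_status[keep]
  gpos <- grp == "positive"
  n1 <- sum(gpos); n0 <- sum(!gpos); n <- n1 + n0
  m1 <- rowMeans(x[, gpos, drop = FALSE])
  m0 <- rowMeans(x[, !gpos, drop = FALSE])
  ss1 <- rowSums((x[, gpos, drop = FALSE] - m1)^2)
  ss0 <- rowSums((x[, !gpos, drop = FALSE] - m0)^2)
  sp2 <- (ss1 + ss0) / (n - 2)
  tstat <- (m1 - m0) / sqrt(sp2 * (1 / n1 + 1 / n0))
  p <- stats::pf(tstat^2, 1, n - 2, lower.tail = FALSE)
  p[!is.finite(tstat)] <- 1
  data.frame(gene = rownames(x), fold_change = m1 / m0, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Signature-level ER differential-expression test
#'
#' Summarises a signature's relation to ER status against the genome-wide
#' background.  The signature fold-change is the geometric mean of its
#' member genes' ER+/ER- fold-changes.  Because the per-gene negative-log
#' p-values and fold-changes are approximately log-normal, significance is
#' assessed by one-way ANOVA comparing the signature's genes against all
#' other genes on log(-log p) and on log(fold-change).
#'
#' @param signature character vector of gene ids (>= 2 present in cohort).
#' @param cohort a [clinical_cohort()] with ER annotation.
#' @return list with `fold_change`, `p_log_neg_log_p`, `p_log_fold_change`,
#'   and `n_genes_used`.
#' @export
signature_er_test <- function(signature, cohort) {
  gw <- er_stats_genomewide(cohort)
  member <- gw$gene %in% unique(canon_gene_id(signature))
  if (sum(member) < 2)
    stop_input("fewer than 2 signature genes present in the cohort")
  fc <- exp(mean(log(gw$fold_change[member])))
  p_clamped <- pmin(pmax(gw$p_value, 1e-300), 1 - 1e-16)
  y1 <- log(-log(p_clamped))
  y2 <- log(gw$fold_change)
  grp <- factor(member)
  p_of <- function(y) {
    if (length(unique(y)) == 1) return(1)  # no between-group variance possible
    anova(lm(y ~ grp))[["Pr(>F)"]][1]
  }
  list(fold_change = fc,
       p_log_neg_log_p = p_of(y1),
       p_log_fold_change = p_of(y2),
       n_genes_used = sum(member))
}

# within-set MSE of a genes x samples matrix around the mean profile
mse_of_rows <- function(x) {
  mu <- colMeans(x)
  sum(sweep(x, 2, mu)^2) / (nrow(x) * ncol(x))
}

#' Random-set tightness test of a gene set in a cohort
#'
#' Measures how tightly a gene set is co-expressed compared with random
#' same-size gene sets.  The observed MSE (dispersion around the set's mean
#' profile, on per-gene standardised expression) is compared against the
#' MSEs of `n_random` random gene sets via a fitted normal null; the
#' p-value is the probability of the observed MSE or a smaller (more
#' favourable) one.
#'
#' @param gene_set character vector of >= 2 gene ids present in the cohort.
#' @param cohort a [clinical_cohort()].
#' @param n_random number of random same-size sets (default 1000).
#' @param seed integer seed for the random draws.
#' @return list with `mse`, `p_value`, `null_mean`, `null_sd`.
#' @export
tightness_test <- function(gene_set, cohort, n_random = 1000L, seed = 1L) {
  if (!inherits(cohort, "clinical_cohort"))
    stop_input("cohort must be a clinical_cohort")
  genes <- intersect(unique(canon_gene_id(gene_set)), rownames(cohort$expression))
  if (length(genes) < 2) stop_input("gene_set must have >= 2 genes in the cohort")
  G <- nrow(cohort$expression)
  if (length(genes) > G) stop_input("gene_set larger than the genome")
  x <- cohort$expression
  mu <- rowMeans(x)
  s <- apply(x, 1, pop_sd)
  s[s == 0] <- 1
  z <- (x - mu) / s
  obs <- mse_of_rows(z[genes, , drop = FALSE])
  set.seed(seed)
  null_mse <- vapply(seq_len(n_random), function(i)
    mse_of_rows(z[sample.int(G, length(genes)), , drop = FALSE]), 0)
  m <- mean(null_mse); sdev <- sd(null_mse)
  list(mse = obs, p_value = pnorm(obs, mean = m, sd = sdev),
       null_mean = m, null_sd = sdev)
}

#' Spearman-correlation sub-cluster discovery within a gene set
#'
#' Computes the pairwise Spearman correlation among the set's genes over
#' the cohort's samples, hierarchically clusters the genes on the distance
#' 1 - rho, cuts the tree at a correlation-distance threshold (or into a
#' target number of groups), and returns the sub-clusters of at least
#' `min_size` genes together with the tree-ordered correlation matrix for
#' heat-map display.  Constant genes (Spearman undefined) are excluded with
#' a warning.
#'
#' @param gene_set character vector of >= 3 gene ids.
#' @param cohort a [clinical_cohort()].
#' @param linkage hierarchical linkage (default `"average"`).
#' @param cut correlation-distance cut height (default 0.6); ignored when
#'   `k` is given.
#' @param k optional target number of sub-clusters.
#' @param min_size minimum sub-cluster size reported (default 5).
#' @return list with `subclusters` (named list of gene vectors),
#'   `correlation` (tree-ordered Spearman matrix) and `hclust`.
#' @export
subcluster_discovery <- function(gene_set, cohort, linkage = "average",
                                 cut = 0.6, k = NULL, min_size = 5L) {
  if (!inherits(cohort, "clinical_cohort"))
    stop_input("cohort must be a clinical_cohort")
  genes <- intersect(unique(canon_gene_id(gene_set)), rownames(cohort$expression))
  if (length(genes) < 3) stop_input("gene_set must have >= 3 genes in the cohort")
  x <- cohort$expression[genes, , drop = FALSE]
  const <- apply(x, 1, function(r) length(unique(r)) == 1)
  if (any(const)) {
    warning(sprintf("%d constant gene(s) excluded (Spearman undefined)",
                    sum(const)), call. = FALSE)
    x <- x[!const, , drop = FALSE]
    genes <- genes[!const]
  }
  if (nrow(x) < 3) stop_input("fewer than 3 non-constant genes remain")
  rho <- cor(t(x), method = "spearman")
  hc <- hclust(as.dist(1 - rho), method = linkage)
  lab <- if (is.null(k)) cutree(hc, h = cut) else cutree(hc, k = k)
  subs <- split(genes, lab)
  subs <- subs[order(-lengths(subs))]
  subs <- subs[lengths(subs) >= min_size]
  names(subs) <- if (length(subs)) paste0("sub", seq_along(subs)) else character(0)
  ord <- hc$order
  list(subclusters = subs, correlation = rho[ord, ord], hclust = hc)
}

#' Pairwise Spearman correlations between signature scores
#'
#' Summarises each signature by its [hypoxia_score()] over the cohort and
#' returns the matrix of pairwise Spearman correlations between the score
#' vectors.
#'
#' @param signatures named list of >= 2 gene-id vectors.
#' @param cohort a [clinical_cohort()].
#' @return symmetric correlation matrix with unit diagonal.
#' @export
signature_correlations <- function(signatures, cohort) {
  if (!is.list(signatures) || length(signatures) < 2)
    stop_input("need at least two signatures")
  if (is.null(names(signatures)))
    names(signatures) <- paste0("sig", seq_along(signatures))
  hs <- vapply(names(signatures), function(s)
    hypoxia_score(signatures[[s]], cohort, s)$scores,
    numeric(ncol(cohort$expression)))
  cor(hs, method = "spearman")
}

#' Pearson correlation between two gene sets' mean profiles in one dataset
#'
#' @param set_a,set_b character vectors of gene ids.
#' @param dataset an [expression_dataset()] (or genes x conditions matrix
#'   with gene-id row names).
#' @return Pearson correlation of the two mean condition-profiles; `NA`
#'   with a warning when a mean profile is constant (undefined).
#' @export
cluster_profile_correlation <- function(set_a, set_b, dataset) {
  x <- if (inherits(dataset, "expression_dataset")) dataset$values else dataset
  check_matrix(x, "dataset values")
  a <- intersect(unique(canon_gene_id(set_a)), rownames(x))
  b <- intersect(unique(canon_gene_id(set_b)), rownames(x))
  if (!length(a) || !length(b))
    stop_input("both sets need at least one gene in the dataset")
  pa <- colMeans(x[a, , drop = FALSE])
  pb <- colMeans(x[b, , drop = FALSE])
  if (sd(pa) == 0 || sd(pb) == 0) {
    warning("constant mean profile; correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(pa, pb)
}
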
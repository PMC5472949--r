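#' Design for a synthetic multi-dataset expression collection
#'
#' Describes a collection of L heterogeneous datasets (3-7 conditions each)
#' with planted consistently co-expressed gene clusters, optional
#' anti-correlated cluster pairs, per-dataset missing genes subject to an L*
#' presence floor, and i.i.d. Gaussian measurement noise.
#'
#' @param n_genes total number of genes.
#' @param n_datasets number of datasets L.
#' @param samples_per_dataset integer vector of length L: conditions per
#'   dataset (typically 3-7).
#' @param clusters integer vector of planted cluster sizes (sum <= n_genes);
#'   remaining genes are unstructured background.
#' @param anticorrelated_pairs list of length-2 integer vectors: cluster
#'   index pairs whose latent profiles are negations of each other.
#' @param noise_sd standard deviation of the additive Gaussian noise on
#'   planted genes.
#' @param min_presence L*: every gene is present in at least this many
#'   datasets.
#' @param missing_fraction probability that a gene is missing from any one
#'   dataset (before the L* floor is enforced by redrawing).
#' @param seed integer seed; the whole collection is deterministic given the
#'   design.
#' @return object of class `planted_design`.
#' @export
planted_design <- function(n_genes, n_datasets, samples_per_dataset,
                           clusters = integer(0),
                           anticorrelated_pairs = list(),
                           noise_sd = 0.3, min_presence = n_datasets,
                           missing_fraction = 0, seed = 1L) {
  if (length(samples_per_dataset) != n_datasets)
    stop_input("samples_per_dataset must have length n_datasets = %d", n_datasets)
  if (any(samples_per_dataset < 2))
    stop_input("each dataset needs at least 2 conditions")
  if (sum(clusters) > n_genes)
    stop_input("planted cluster sizes (%d) exceed n_genes (%d)", sum(clusters), n_genes)
  if (min_presence < 1 || min_presence > n_datasets)
    stop_input("min_presence must be in 1..L")
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop_input("missing_fraction must be in [0, 1)")
  if ((1 - missing_fraction) * n_datasets < min_presence)
    stop_input("missing_fraction = %.2f is incompatible with min_presence = %d of %d datasets",
               missing_fraction, min_presence, n_datasets)
  if (noise_sd < 0) stop_input("noise_sd must be non-negative")
  for (p in anticorrelated_pairs)
    if (length(p) != 2 || any(p < 1) || any(p > length(clusters)))
      stop_input("anticorrelated_pairs must index the planted clusters")
  structure(list(n_genes = as.integer(n_genes),
                 n_datasets = as.integer(n_datasets),
                 samples_per_dataset = as.integer(samples_per_dataset),
                 clusters = as.integer(clusters),
                 anticorrelated_pairs = anticorrelated_pairs,
                 noise_sd = noise_sd,
                 min_presence = as.integer(min_presence),
                 missing_fraction = missing_fraction,
                 seed = as.integer(seed)),
            class = "planted_design")
}

# monotone piecewise-linear latent trajectory over d conditions, scaled to
# span [-1, 1]; mimics gradual up-/down-regulation through a time course
latent_profile <- function(d, direction = 1) {
  inc <- runif(d - 1)
  # zero out a random subset of gaps so the trajectory is piecewise linear
  # (flat stretches) rather than strictly increasing everywhere
  flat <- runif(d - 1) < 0.3
  if (all(flat)) flat[sample.int(d - 1, 1)] <- FALSE
  inc[flat] <- 0
  y <- cumsum(c(0, inc))
  y <- 2 * (y - min(y)) / (max(y) - min(y)) - 1
  direction * y
}

#' Generate a synthetic dataset collection with planted clusters
#'
#' Creates L one-colour datasets on a shared gene universe.  Genes in a
#' planted cluster share, within each dataset, a common monotone latent
#' condition profile (negated for the second member of an anti-correlated
#' pair) plus i.i.d. Gaussian noise of sd `noise_sd`; background genes are
#' independent unit-variance noise.  All genes share a common scale so that
#' quantile normalisation is a near-identity on the planted structure (the
#' per-gene z-scoring of the pipeline removes any baseline offset anyway).
#' Each gene is present in at least L* datasets; missingness is
#' drawn per (gene, dataset) and redrawn for genes falling under the floor.
#'
#' @param design a [planted_design()].
#' @return a `dataset_collection` (un-normalised) with an attribute `truth`:
#'   list of `clusters` (gene-id vectors), `anticorrelated_pairs` and the
#'   design.
#' @seealso [normalise_collection()] to apply the per-dataset normalisation
#'   before clustering.
#' @export
generate_collection <- function(design) {
  if (!inherits(design, "planted_design"))
    stop_input("design must be a planted_design")
  set.seed(design$seed)
  G <- design$n_genes
  L <- design$n_datasets
  genes <- sprintf("G%05d", seq_len(G))
  # planted memberships: consecutive blocks from the top
  membership <- rep(0L, G)
  pos <- 0L
  truth_clusters <- vector("list", length(design$clusters))
  for (ci in seq_along(design$clusters)) {
    idx <- pos + seq_len(design$clusters[ci])
    membership[idx] <- ci
    truth_clusters[[ci]] <- genes[idx]
    pos <- pos + design$clusters[ci]
  }
  names(truth_clusters) <- paste0("planted", seq_along(truth_clusters))

  # presence mask with per-gene floor enforced by redrawing offending rows
  presence <- matrix(runif(G * L) >= design$missing_fraction, G, L)
  if (design$missing_fraction > 0) {
    bad <- which(rowSums(presence) < design$min_presence)
    while (length(bad)) {
      presence[bad, ] <- runif(length(bad) * L) >= design$missing_fraction
      bad <- bad[rowSums(presence[bad, , drop = FALSE]) < design$min_presence]
    }
  }

  # second member of an anti-correlated pair gets the negated profile
  neg_of <- integer(length(design$clusters))
  for (p in design$anticorrelated_pairs) neg_of[p[2]] <- p[1]

  datasets <- vector("list", L)
  for (l in seq_len(L)) {
    d <- design$samples_per_dataset[l]
    profs <- vector("list", length(design$clusters))
    for (ci in seq_along(design$clusters)) {
      profs[[ci]] <- if (neg_of[ci] > 0) -profs[[neg_of[ci]]]
                     else latent_profile(d, sample(c(-1, 1), 1))
    }
    x <- matrix(rnorm(G * d), G, d)   # background: unit-variance noise
    for (ci in seq_along(design$clusters)) {
      rows <- which(membership == ci)
      x[rows, ] <- matrix(profs[[ci]], length(rows), d, byrow = TRUE) +
        matrix(rnorm(length(rows) * d, sd = design$noise_sd), length(rows), d)
    }
    here <- presence[, l]
    x <- x[here, , drop = FALSE]
    dimnames(x) <- list(genes[here], paste0("t", seq_len(d)))
    datasets[[l]] <- expression_dataset(x, "one_colour",
                                        dataset_id = sprintf("D%02d", l))
  }
  coll <- build_collection(datasets, design$min_presence)
  attr(coll, "truth") <- list(clusters = truth_clusters,
                              anticorrelated_pairs = design$anticorrelated_pairs,
                              design = design)
  coll
}

#' Design for a synthetic clinical cohort
#'
#' Describes a cohort whose expression carries latent per-signature activity
#' scores, whose overall-survival hazard is log-linear in those scores, and
#' whose estrogen-receptor (ER) status shifts signature genes by a target
#' fold-change.
#'
#' @param n_samples number of patients.
#' @param signature_effects named numeric vector: log-hazard coefficient
#'   (beta) per signature; names must match the signature list passed to
#'   [generate_clinical()].
#' @param er_fold_changes named numeric vector: target ER+/ER- fold-change
#'   of each signature's genes (1 = no effect).
#' @param censoring_rate expected fraction of censored samples in \[0, 1).
#' @param baseline_hazard positive baseline exponential hazard (per year).
#' @param n_background_genes unstructured genes added to the genome.
#' @param gene_noise_sd log-scale measurement noise per gene.
#' @param seed integer seed.
#' @return object of class `clinical_design`.
#' @export
clinical_design <- function(n_samples, signature_effects = numeric(0),
                            er_fold_changes = numeric(0),
                            censoring_rate = 0.2, baseline_hazard = 0.1,
                            n_background_genes = 1000, gene_noise_sd = 0.2,
                            seed = 1L) {
  if (n_samples < 2) stop_input("n_samples must be >= 2")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop_input("censoring_rate must be in [0, 1)")
  if (baseline_hazard <= 0) stop_input("baseline_hazard must be positive")
  structure(list(n_samples = as.integer(n_samples),
                 signature_effects = signature_effects,
                 er_fold_changes = er_fold_changes,
                 censoring_rate = censoring_rate,
                 baseline_hazard = baseline_hazard,
                 n_background_genes = as.integer(n_background_genes),
                 gene_noise_sd = gene_noise_sd,
                 seed = as.integer(seed)),
            class = "clinical_design")
}

#' Generate a synthetic clinical cohort
#'
#' Each signature has a latent per-sample activity score uniform on \[0, 1\].
#' Signature genes multiply a per-gene baseline by `exp(score - 0.5)`, by
#' the signature's ER fold-change for ER-positive samples, and by log-normal
#' noise, so the per-sample median of a signature's genes increases
#' monotonically with its score.  Survival times are exponential with hazard
#' `baseline_hazard * exp(sum(beta * score))`; censoring times are uniform
#' on (0, tau) with tau solved so the expected censored fraction matches
#' `censoring_rate`.
#'
#' @param design a [clinical_design()].
#' @param signatures non-empty named list of gene-id vectors.
#' @return a [clinical_cohort()] (quantile-normalised expression) with an
#'   attribute `truth`: per-signature scores, betas, fold-changes and ER
#'   labels.
#' @export
generate_clinical <- function(design, signatures) {
  if (!inherits(design, "clinical_design"))
    stop_input("design must be a clinical_design")
  if (!is.list(signatures) || length(signatures) == 0 ||
      is.null(names(signatures)) || any(lengths(signatures) == 0))
    stop_input("signatures must be a non-empty named list of gene sets")
  set.seed(design$seed)
  n <- design$n_samples
  sig_names <- names(signatures)
  betas <- fcs <- setNames(numeric(length(signatures)), sig_names)
  betas[names(design$signature_effects)] <- design$signature_effects
  fcs[] <- 1
  fcs[names(design$er_fold_changes)] <- design$er_fold_changes

  scores <- matrix(runif(n * length(signatures)), n,
                   dimnames = list(NULL, sig_names))
  er <- ifelse(rbinom(n, 1, 0.5) == 1, "positive", "negative")

  sig_genes <- lapply(signatures, canon_gene_id)
  genes <- unique(unlist(sig_genes))
  if (design$n_background_genes > 0)
    genes <- c(genes, sprintf("BG%05d", seq_len(design$n_background_genes)))
  G <- length(genes)
  base <- exp(rnorm(G, mean = 2, sd = 0.5))
  logx <- matrix(rnorm(G * n, sd = design$gene_noise_sd), G, n,
                 dimnames = list(genes, sprintf("S%04d", seq_len(n))))
  logx <- logx + log(base)
  for (s in sig_names) {
    rows <- match(sig_genes[[s]], genes)
    logx[rows, ] <- logx[rows, ] +
      rep(scores[, s] - 0.5, each = length(rows)) +
      log(fcs[s]) * rep(er == "positive", each = length(rows))
  }
  x <- exp(logx)

  lambda <- design$baseline_hazard * exp(drop(scores %*% betas))
  os_time <- rexp(n, rate = lambda)
  os_event <- rep(1L, n)
  if (design$censoring_rate > 0) {
    cens_frac <- function(tau) mean((1 - exp(-lambda * tau)) / (lambda * tau))
    tau <- uniroot(function(tau) cens_frac(tau) - design$censoring_rate,
                   lower = 1e-6, upper = 1e6, tol = 1e-8)$root
    cens <- runif(n, 0, tau)
    os_event <- as.integer(os_time <= cens)
    os_time <- pmin(os_time, cens)
  }
  cohort <- clinical_cohort(x, os_time = os_time, os_event = os_event,
                            er_status = er, normalise = TRUE)
  attr(cohort, "truth") <- list(scores = scores, betas = betas,
                                er_fold_changes = fcs, er = er,
                                signatures = sig_genes, design = design)
  cohort
}
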
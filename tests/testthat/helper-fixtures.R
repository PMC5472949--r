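# shared fixtures and small oracles, all built in code

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# small planted collection used by several module tests
small_collection <- function(noise_sd = 0.2, seed = 7, missing_fraction = 0.1) {
  design <- planted_design(
    n_genes = 200, n_datasets = 4, samples_per_dataset = c(4, 5, 6, 4),
    clusters = c(30, 40), anticorrelated_pairs = list(c(1, 2)),
    noise_sd = noise_sd, min_presence = 3,
    missing_fraction = missing_fraction, seed = seed)
  generate_collection(design)
}

# matrix with gene-id rownames from a vector spec
named_matrix <- function(values, nrow, ids = NULL) {
  m <- matrix(values, nrow = nrow, byrow = TRUE)
  rownames(m) <- if (is.null(ids)) sprintf("G%03d", seq_len(nrow)) else ids
  m
}

# independent quantile-normalisation oracle: per-element loop over explicit
# rank means, averaging the rank means each tie group spans
qn_oracle <- function(x) {
  rank_means <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    for (i in seq_len(nrow(x))) {
      lo <- sum(x[, j] < x[i, j]) + 1
      hi <- sum(x[, j] <= x[i, j])
      out[i, j] <- mean(rank_means[lo:hi])
    }
  }
  out
}

# exhaustive minimum-SSE bipartition oracle for tiny k-means instances
best_two_partition <- function(x) {
  n <- nrow(x)
  best <- NULL; best_sse <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    g1 <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    g2 <- setdiff(seq_len(n), g1)
    sse <- function(g) {
      if (length(g) == 0) return(Inf)
      mu <- colMeans(x[g, , drop = FALSE])
      sum(sweep(x[g, , drop = FALSE], 2, mu)^2)
    }
    s <- sse(g1) + sse(g2)
    if (s < best_sse) { best_sse <- s; best <- list(g1, g2) }
  }
  best
}

# partition contents as a canonical sorted list of sorted gene sets
contents_of <- function(p) {
  sets <- uncles:::partition_contents(p)
  sets[order(vapply(sets, `[[`, "", 1))]
}

# tiny clinical cohort on a fixed positive scale, not re-normalised,
# so expression values are fully controlled by the test
fixed_cohort <- function(expression, os_time = NULL, os_event = NULL,
                         er_status = NULL) {
  n <- ncol(expression)
  if (is.null(os_time)) os_time <- seq_len(n)
  if (is.null(os_event)) os_event <- rep(1L, n)
  clinical_cohort(expression, os_time, os_event, er_status, normalise = FALSE)
}
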
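#' Hard partition of a gene set
#'
#' A complete hard partition: a K x G binary membership matrix over the
#' dataset's genes, every gene in exactly one cluster.  Rows (clusters) may
#' be empty (all-zero) so that K is preserved across partitions that must be
#' aligned for consensus averaging.
#'
#' @param membership K x G binary matrix; column names are gene ids.
#' @param source named list of provenance (`method`, `dataset_id`, `K`, and
#'   for stochastic methods `seed`).
#' @return object of class `partition`.
#' @export
partition <- function(membership, source = list()) {
  if (!is.matrix(membership)) stop_input("membership must be a matrix")
  if (is.null(colnames(membership))) stop_input("membership needs gene ids as column names")
  if (nrow(membership) < 2) stop_input("a partition needs K >= 2 clusters")
  if (!all(membership %in% c(0, 1)) || !all(colSums(membership) == 1))
    stop_input("membership must be binary with every column summing to 1")
  structure(list(K = nrow(membership),
                 gene_ids = colnames(membership),
                 membership = membership,
                 source = source),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  sz <- rowSums(x$membership)
  cat(sprintf("partition: K = %d over %d genes (%s); cluster sizes %s\n",
              x$K, length(x$gene_ids),
              paste(unlist(x$source), collapse = "/"),
              paste(sz, collapse = ", ")))
  invisible(x)
}

# labels (1..K) -> K x G binary membership
labels_to_membership <- function(labels, K, gene_ids) {
  m <- matrix(0L, K, length(labels))
  m[cbind(labels, seq_along(labels))] <- 1L
  colnames(m) <- gene_ids
  m
}

check_cluster_input <- function(data, K) {
  check_matrix(data, "clustering input")
  if (is.null(rownames(data))) stop_input("clustering input needs gene ids as row names")
  if (K < 2) stop_input("K must be >= 2")
  if (K > nrow(data)) stop_input("K (%d) exceeds the number of genes (%d)", K, nrow(data))
}

# Kaufman seeding on a precomputed Euclidean distance matrix: first centre
# minimises the total distance to all points; each next centre maximises the
# summed positive reduction in the other points' nearest-centre distances
kaufman_centres <- function(D, K) {
  n <- nrow(D)
  centres <- which.min(rowSums(D))
  while (length(centres) < K) {
    dnear <- apply(D[, centres, drop = FALSE], 1, min)
    cand <- setdiff(seq_len(n), centres)
    gains <- colSums(pmax(dnear - D[, cand, drop = FALSE], 0)) - dnear[cand]
    centres <- c(centres, cand[which.max(gains)])
  }
  centres
}

#' k-means with deterministic Kaufman initialisation
#'
#' Kaufman seeding: the first centre is the point minimising the total
#' Euclidean distance to all points; each further centre is the point
#' maximising the summed positive reduction in the other points'
#' nearest-centre distances.  Lloyd iterations (squared-Euclidean
#' assignment, mean update) then run to convergence (no assignment change)
#' or `max_iter` sweeps.  A cluster emptied during Lloyd is re-seeded with
#' the point farthest from its current centre.  The whole procedure is
#' deterministic: the same input always yields the same partition.
#'
#' @param data genes x conditions numeric matrix with gene-id row names.
#' @param K number of clusters (2 <= K <= genes).
#' @param max_iter Lloyd iteration cap.
#' @return a [partition()].
#' @export
kmeans_ka <- function(data, K, max_iter = 300L) {
  check_cluster_input(data, K)
  n <- nrow(data)
  centroids <- data[kaufman_centres(as.matrix(dist(data)), K), , drop = FALSE]
  assign_old <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(data^2), rep(1, K)) - 2 * data %*% t(centroids) +
      outer(rep(1, n), rowSums(centroids^2))
    lab <- max.col(-d2, ties.method = "first")
    empty <- setdiff(seq_len(K), unique(lab))
    if (length(empty)) {
      cur <- d2[cbind(seq_len(n), lab)]
      for (k in empty) {   # re-seed with the point farthest from its centre
        far <- which.max(cur)
        lab[far] <- k
        cur[far] <- -Inf
      }
    }
    if (all(lab == assign_old)) break
    assign_old <- lab
    for (k in seq_len(K))
      centroids[k, ] <- colMeans(data[lab == k, , drop = FALSE])
  }
  partition(labels_to_membership(assign_old, K, rownames(data)),
            source = list(method = "kmeans_ka", K = K))
}

# factor pair (r, c) with r * c = K and |r - c| minimal, r <= c
som_grid_dims <- function(K) {
  r <- floor(sqrt(K))
  while (K %% r != 0) r <- r - 1
  as.integer(c(r, K %/% r))
}

#' Self-organising map clustering with bubble neighbourhood
#'
#' Trains a rectangular SOM whose units are the clusters: grid dimensions
#' are the factor pair of K closest to square (4 x 4 for K = 16).  The
#' neighbourhood is a hard-radius bubble; the radius decays linearly from
#' max(grid dims)/2 to 1 and the learning rate from 0.5 to 0.01 over
#' `epochs * G` online updates in seeded random order.  Each gene is then
#' assigned to its best-matching unit.  Units left empty are retained as
#' empty clusters so K is preserved for relabelling and consensus.
#'
#' @param data genes x conditions numeric matrix with gene-id row names.
#' @param K number of units/clusters.
#' @param seed integer seed (the only stochastic base method).
#' @param epochs passes over the data (total updates = epochs * G).
#' @return a [partition()].
#' @export
som_cluster <- function(data, K, seed = 1L, epochs = 100L) {
  check_cluster_input(data, K)
  G <- nrow(data)
  dims <- som_grid_dims(K)
  grid <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2])))
  storage.mode(grid) <- "double"
  set.seed(seed)
  # codebook initialised at well-spread data points (Kaufman seeding) so
  # that similar clusters do not start on a shared unit; the seeded random
  # presentation order is the method's stochastic element
  W <- data[kaufman_centres(as.matrix(dist(data)), K), , drop = FALSE]
  T_total <- as.integer(epochs) * G
  idx <- sample.int(G, T_total, replace = TRUE)
  tt <- seq_len(T_total)
  alpha <- 0.5 + (0.01 - 0.5) * (tt - 1) / max(T_total - 1, 1)
  radius <- max(dims) / 2 + (1 - max(dims) / 2) * (tt - 1) / max(T_total - 1, 1)
  W <- som_train(unname(data), unname(W), grid, idx, alpha, radius)
  d2 <- outer(rowSums(data^2), rep(1, K)) - 2 * data %*% t(W) +
    outer(rep(1, G), rowSums(W^2))
  lab <- max.col(-d2, ties.method = "first")
  partition(labels_to_membership(lab, K, rownames(data)),
            source = list(method = "som", K = K, seed = seed))
}

#' Hierarchical clustering with Ward's criterion
#'
#' Agglomerative clustering on Euclidean distances with Ward's
#' minimum-variance linkage (`ward.D2`), cut into exactly K groups.
#'
#' @param data genes x conditions numeric matrix with gene-id row names.
#' @param K number of clusters.
#' @return a [partition()].
#' @export
hc_ward <- function(data, K) {
  check_cluster_input(data, K)
  hc <- hclust(dist(data), method = "ward.D2")
  lab <- cutree(hc, k = K)
  partition(labels_to_membership(unname(lab), K, rownames(data)),
            source = list(method = "hc_ward", K = K))
}

# gene sets of the non-empty clusters, each sorted; order-insensitive
# partition content for comparisons
partition_contents <- function(p) {
  sets <- apply(p$membership, 1, function(r) sort(p$gene_ids[r == 1]),
                simplify = FALSE)
  sets[lengths(sets) > 0]
}
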
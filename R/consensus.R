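#' Min-min relabelling of a partition against a reference
#'
#' Aligns the clusters of `target` to those of `reference` so that
#' element-by-element averaging across partitions is meaningful.  The K x K
#' cost matrix holds, for each (reference cluster i, target cluster j), the
#' size of the symmetric difference of their gene sets restricted to the
#' genes shared by the two partitions.  Matching is greedy min-first: the
#' globally minimal unmatched (i, j) pair is matched repeatedly, so the
#' best-fitting clusters are aligned with the highest priority even if
#' poorer clusters end up matched badly.  Ties are broken by the lowest
#' (i, j) index pair, row first.
#'
#' @param reference,target [partition()] objects with the same K.
#' @return `target` with its membership rows permuted into reference order
#'   and marked as aligned.
#' @export
relabel_min_min <- function(reference, target) {
  if (!inherits(reference, "partition") || !inherits(target, "partition"))
    stop_input("reference and target must be partitions")
  K <- reference$K
  if (target$K != K)
    stop_input("K mismatch: reference %d vs target %d", K, target$K)
  shared <- intersect(reference$gene_ids, target$gene_ids)
  if (length(shared) == 0) stop_input("partitions share no genes")
  ri <- reference$membership[, match(shared, reference$gene_ids), drop = FALSE]
  ti <- target$membership[, match(shared, target$gene_ids), drop = FALSE]
  # |A symdiff B| = |A| + |B| - 2|A & B|, computed on the shared genes
  inter <- ri %*% t(ti)
  cost <- outer(rowSums(ri), rep(1, K)) + outer(rep(1, K), rowSums(ti)) - 2 * inter
  perm <- greedy_min_match(cost)
  target$membership <- target$membership[perm, , drop = FALSE]
  target$aligned <- TRUE
  target
}

# greedy min-first assignment on a K x K cost matrix: repeatedly match the
# globally minimal open (i, j) pair, ties broken by lowest (i, j) row-major;
# returns perm with perm[i] = column matched to row i
greedy_min_match <- function(cost) {
  K <- nrow(cost)
  perm <- integer(K)
  open_i <- rep(TRUE, K)
  open_j <- rep(TRUE, K)
  for (step in seq_len(K)) {
    sub <- cost
    sub[!open_i, ] <- Inf
    sub[, !open_j] <- Inf
    best <- which(sub == min(sub), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    perm[best[1]] <- best[2]
    open_i[best[1]] <- FALSE
    open_j[best[2]] <- FALSE
  }
  perm
}

#' Fuzzy consensus partition matrix (CoPaM)
#'
#' Element-by-element average of relabelled hard partitions, weighted by
#' gene presence: a gene's membership is averaged only over the partitions
#' whose dataset actually measured that gene, so per-dataset missing genes
#' do not dilute the consensus.  Each supported gene's fuzzy column sums to
#' one; `support` records how many partitions included each gene.
#'
#' @param partitions list of [partition()] objects sharing one K, all
#'   relabelled against a common reference (see [relabel_min_min()]).  The
#'   reference itself counts as aligned.
#' @param collection the `dataset_collection` whose gene universe the CoPaM
#'   spans.
#' @return object of class `copam`: `K`, `gene_ids`, `fuzzy` (K x G),
#'   `support` (per-gene partition count).
#' @export
build_copam <- function(partitions, collection) {
  if (!length(partitions)) stop_input("no partitions given")
  K <- partitions[[1]]$K
  if (!all(vapply(partitions, function(p) p$K, 0L) == K))
    stop_input("all partitions must share the same K")
  if (!all(vapply(partitions, function(p) isTRUE(p$aligned), TRUE)))
    stop_input("partitions must be relabelled against a common reference before averaging")
  universe <- collection$gene_universe
  G <- length(universe)
  fuzzy <- matrix(0, K, G, dimnames = list(NULL, universe))
  support <- integer(G)
  for (p in partitions) {
    j <- match(p$gene_ids, universe)
    keep <- !is.na(j)
    fuzzy[, j[keep]] <- fuzzy[, j[keep]] + p$membership[, keep, drop = FALSE]
    support[j[keep]] <- support[j[keep]] + 1L
  }
  pos <- support > 0
  fuzzy[, pos] <- sweep(fuzzy[, pos, drop = FALSE], 2, support[pos], "/")
  structure(list(K = K, gene_ids = universe, fuzzy = fuzzy, support = support),
            class = "copam")
}

#' @export
print.copam <- function(x, ...) {
  cat(sprintf("copam: K = %d x %d genes; support %d-%d partitions/gene\n",
              x$K, length(x$gene_ids), min(x$support), max(x$support)))
  invisible(x)
}

#' Difference threshold binarisation (DTB) of a CoPaM
#'
#' Assigns each gene to its maximum-membership cluster if and only if that
#' membership exceeds the membership in every other cluster by at least
#' delta; otherwise the gene is left unassigned (all-zero column).  delta
#' ranges from 0 (loosest; a strict unique maximum is still required, so
#' exact ties stay unassigned) to 1 (only genes with full membership in a
#' single cluster survive).
#'
#' @param copam a [build_copam()] result.
#' @param delta tuning parameter in \[0, 1\].
#' @return K x G binary matrix (gene ids as column names); columns of
#'   unassigned genes are all zero.
#' @export
dtb_binarise <- function(copam, delta) {
  if (!inherits(copam, "copam")) stop_input("copam must be a copam object")
  if (length(delta) != 1 || delta < 0 || delta > 1)
    stop_input("delta must be a single value in [0, 1]")
  f <- copam$fuzzy
  G <- ncol(f)
  kstar <- max.col(t(f), ties.method = "first")
  m <- f[cbind(kstar, seq_len(G))]
  f2 <- f
  f2[cbind(kstar, seq_len(G))] <- -Inf
  second <- apply(f2, 2, max)
  tol <- 1e-12
  assigned <- if (delta > 0) (m - second) >= (delta - tol) else (m - second) > tol
  out <- matrix(0L, copam$K, G, dimnames = list(NULL, copam$gene_ids))
  out[cbind(kstar[assigned], which(assigned))] <- 1L
  out
}

#' Consensus clustering of a dataset collection (UNCLES type A)
#'
#' The full type-A consensus pipeline for finding gene clusters consistently
#' co-expressed across all datasets: each base clustering method is applied
#' to every dataset at each K (R = C x L partitions per K), the partitions
#' are min-min relabelled against the first one, averaged into a
#' presence-weighted fuzzy CoPaM, and binarised with DTB at every delta of
#' the grid.  Every non-empty binarised cluster is emitted as a candidate
#' tagged with its provenance (K, delta, cluster index) for M-N scatter-plot
#' selection ([mn_select()]).
#'
#' @param collection a `dataset_collection`; normalised automatically if its
#'   datasets are not already normalised.
#' @param k_values integer vector of cluster counts (default the 8-40 grid).
#' @param methods subset of `c("kmeans_ka", "som", "hc_ward")`.
#' @param delta_grid DTB tuning values (default 0 to 1 in steps of 0.1).
#' @param seed root seed for the stochastic SOM runs (expanded
#'   deterministically per K and dataset).
#' @param som_epochs training passes for the SOM base method.
#' @return object of class `uncles_fit` with `candidates` (list of gene-set
#'   candidates with provenance), `copams` (one per K), and the normalised
#'   collection.
#' @export
uncles <- function(collection,
                   k_values = c(8L, 9L, 10L, 16L, 18L, 24L, 30L, 40L),
                   methods = c("kmeans_ka", "som", "hc_ward"),
                   delta_grid = seq(0, 1, by = 0.1),
                   seed = 1L, som_epochs = 100L) {
  if (!inherits(collection, "dataset_collection"))
    stop_input("collection must be a dataset_collection")
  methods <- match.arg(methods, c("kmeans_ka", "som", "hc_ward"),
                       several.ok = TRUE)
  k_values <- as.integer(k_values)
  if (!all(vapply(collection$datasets, function(d) d$normalised, TRUE)))
    collection <- normalise_collection(collection)
  candidates <- list()
  copams <- list()
  for (K in k_values) {
    parts <- list()
    for (m in methods) {
      for (l in seq_along(collection$datasets)) {
        ds <- collection$datasets[[l]]
        p <- switch(m,
          kmeans_ka = kmeans_ka(ds$values, K),
          som = som_cluster(ds$values, K,
                            seed = as.integer(seed + 97L * K + l),
                            epochs = som_epochs),
          hc_ward = hc_ward(ds$values, K))
        p$source$dataset_id <- ds$dataset_id
        parts[[length(parts) + 1L]] <- p
      }
    }
    parts[[1]]$aligned <- TRUE   # the reference for this K
    for (i in seq_along(parts)[-1])
      parts[[i]] <- relabel_min_min(parts[[1]], parts[[i]])
    cp <- build_copam(parts, collection)
    copams[[as.character(K)]] <- cp
    for (delta in delta_grid) {
      b <- dtb_binarise(cp, delta)
      for (k in seq_len(K)) {
        genes <- cp$gene_ids[b[k, ] == 1L]
        if (length(genes))
          candidates[[length(candidates) + 1L]] <-
            list(genes = genes, K = K, delta = delta, index = k,
                 size = length(genes))
      }
    }
  }
  structure(list(candidates = candidates, copams = copams,
                 k_values = k_values, delta_grid = delta_grid,
                 methods = methods, seed = seed, collection = collection),
            class = "uncles_fit")
}

#' @export
print.uncles_fit <- function(x, ...) {
  cat(sprintf(
    "uncles_fit: %d candidate clusters from K in {%s} x %d delta values (methods: %s)\n",
    length(x$candidates), paste(x$k_values, collapse = ", "),
    length(x$delta_grid), paste(x$methods, collapse = ", ")))
  invisible(x)
}

#' @export
summary.uncles_fit <- function(object, ...) {
  sz <- vapply(object$candidates, function(cc) cc$size, 0L)
  cat(sprintf("Consensus candidates: %d (sizes %d-%d, median %.0f)\n",
              length(sz), min(sz), max(sz), median(sz)))
  cat(sprintf("Gene universe: %d genes over %d datasets (L* = %d)\n",
              length(object$collection$gene_universe),
              length(object$collection$datasets),
              object$collection$min_presence))
  invisible(object)
}
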
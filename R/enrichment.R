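#' Exact upper-tail hypergeometric probability
#'
#' Computes \eqn{P(X \ge k)} for \eqn{X \sim}
#' Hypergeometric(\eqn{N, K, n}): the probability that a draw of \eqn{n}
#' items without replacement from a universe of \eqn{N} items, \eqn{K} of
#' which are marked, contains at least \eqn{k} marked items.  This is the
#' one-sided enrichment p-value for the overlap between a cluster of size
#' \eqn{n} and a gene list of size \eqn{K} in a universe of \eqn{N} genes.
#'
#' The tail is summed in log space from \eqn{k} upwards using log-gamma
#' binomial coefficients, so extreme tails (down to ~1e-300 and below the
#' double-precision underflow limit of the naive sum) are computed to full
#' relative accuracy.
#'
#' @param N universe size.
#' @param K number of marked items in the universe (list size).
#' @param n draw size (cluster size).
#' @param k observed overlap.
#' @return upper-tail probability, a single number in \[0, 1\].
#' @examples
#' hypergeom_tail(10, 5, 5, 5)   # 1 / choose(10, 5)
#' hypergeom_tail(15588, 1172, 598, 145)
#' @export
hypergeom_tail <- function(N, K, n, k) {
  for (v in list(N = N, K = K, n = n, k = k)) {
    if (length(v) != 1L || !is.finite(v) || v < 0 || v != round(v))
      stop_input("N, K, n and k must be single non-negative integers")
  }
  if (K > N) stop_input("K (%d) exceeds N (%d)", K, N)
  if (n > N) stop_input("n (%d) exceeds N (%d)", n, N)
  if (k > n) stop_input("k (%d) exceeds n (%d)", k, n)
  if (k > K) stop_input("k (%d) exceeds K (%d)", k, K)
  if (k == 0) return(1)
  hi <- min(K, n)
  # support of the sum also requires n - i <= N - K
  lo <- max(k, n - (N - K))
  if (lo > hi) return(0)
  i <- lo:hi
  logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(logp)
  min(1, exp(m + log(sum(exp(logp - m)))))
}

#' Hypergeometric overlap test between a cluster and a target gene list
#'
#' The target list is first intersected with the study universe (genes never
#' measured cannot enrich anything), then the upper-tail hypergeometric
#' probability of the observed overlap is computed with [hypergeom_tail()].
#' Gene identifiers are compared case-insensitively after trimming
#' whitespace.
#'
#' @param cluster character vector of gene ids; must be a subset of
#'   `universe`.
#' @param target_list character vector of gene ids (any background; reduced
#'   to the universe internally).
#' @param universe character vector of all genes in the study.
#' @return an object of class `overlap_result`: a list with `universe_size`,
#'   `list_size` (after reduction to the universe), `cluster_size`,
#'   `overlap`, `p_value` and `overlapping_genes`.
#' @export
overlap_test <- function(cluster, target_list, universe) {
  universe <- unique(canon_gene_id(universe))
  cluster <- unique(canon_gene_id(cluster))
  target_list <- unique(canon_gene_id(target_list))
  if (!all(cluster %in% universe))
    stop_input("cluster contains %d gene(s) outside the universe",
               sum(!cluster %in% universe))
  in_univ <- intersect(target_list, universe)
  ov <- intersect(cluster, in_univ)
  res <- list(
    universe_size = length(universe),
    list_size = length(in_univ),
    cluster_size = length(cluster),
    overlap = length(ov),
    p_value = hypergeom_tail(length(universe), length(in_univ),
                             length(cluster), length(ov)),
    overlapping_genes = sort(ov)
  )
  class(res) <- "overlap_result"
  res
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "Hypergeometric overlap: k = %d of list K = %d in cluster n = %d (universe N = %d)\n  upper-tail p = %.3g\n",
    x$overlap, x$list_size, x$cluster_size, x$universe_size, x$p_value))
  invisible(x)
}

#' Venn-region counts of a cluster against two gene sets
#'
#' Partitions a cluster's genes into the four regions of a two-set Venn
#' diagram: only in `set_a`, only in `set_b`, in both, in neither.
#'
#' @param cluster,set_a,set_b character vectors of gene ids.
#' @return named integer vector `c(a_only, b_only, both, neither)`; the four
#'   counts sum to the cluster size.
#' @export
venn_counts <- function(cluster, set_a, set_b) {
  cluster <- unique(canon_gene_id(cluster))
  set_a <- canon_gene_id(set_a)
  set_b <- canon_gene_id(set_b)
  in_a <- cluster %in% set_a
  in_b <- cluster %in% set_b
  c(a_only = sum(in_a & !in_b),
    b_only = sum(!in_a & in_b),
    both = sum(in_a & in_b),
    neither = sum(!in_a & !in_b))
}

#' Per-gene appearance counts across several gene lists
#'
#' For a named collection of gene lists (e.g. independently derived
#' transcription-factor target lists), counts in how many lists each gene
#' appears and returns the union, the intersection, and every "in at least m
#' lists" subset.
#'
#' @param lists named list of character vectors.
#' @return a list with `counts` (named integer vector over the union),
#'   `union`, `intersection`, and `at_least` (list indexed by m = 1..length
#'   of `lists` of the genes appearing in >= m lists).
#' @export
multi_list_consensus <- function(lists) {
  if (!is.list(lists) || length(lists) == 0)
    stop_input("lists must be a non-empty list of gene-id vectors")
  lists <- lapply(lists, function(x) unique(canon_gene_id(x)))
  counts <- table(unlist(lists, use.names = FALSE))
  counts <- setNames(as.integer(counts), names(counts))
  counts <- counts[order(names(counts))]
  m_max <- length(lists)
  at_least <- lapply(seq_len(m_max), function(m) names(counts)[counts >= m])
  list(counts = counts,
       union = names(counts),
       intersection = at_least[[m_max]],
       at_least = at_least)
}
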
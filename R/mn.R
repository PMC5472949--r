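#' Dispersion (modified mean-square error) of a gene set across a collection
#'
#' Per dataset l with D_l conditions, over the subset C_l of the set's genes
#' measured there: MSE_l = sum over genes of the squared Euclidean distance
#' to the set's mean profile, divided by |C_l| * D_l.  The returned value is
#' the mean of MSE_l over the datasets containing at least one of the genes
#' (a singleton contributes 0).  Computed on the datasets' (normalised)
#' expression values.
#'
#' @param gene_set character vector of gene ids in the collection universe.
#' @param collection a `dataset_collection`.
#' @return non-negative scalar.
#' @export
cluster_mse <- function(gene_set, collection) {
  if (!inherits(collection, "dataset_collection"))
    stop_input("collection must be a dataset_collection")
  gene_set <- unique(canon_gene_id(gene_set))
  if (!length(gene_set)) stop_input("gene_set is empty")
  per_ds <- numeric(0)
  for (ds in collection$datasets) {
    rows <- intersect(gene_set, rownames(ds$values))
    if (!length(rows)) next
    x <- ds$values[rows, , drop = FALSE]
    mu <- colMeans(x)
    per_ds <- c(per_ds, sum(sweep(x, 2, mu)^2) / (nrow(x) * ncol(x)))
  }
  if (!length(per_ds))
    stop_input("no gene of the set is present in any dataset")
  mean(per_ds)
}

#' M-N plane distances of a set of candidate clusters
#'
#' Places each candidate on the M-N plane -- dispersion (MSE) on the
#' horizontal axis, log10 cluster size on the vertical axis -- after
#' min-max normalising both axes to \[0, 1\] over the current candidate set,
#' and returns each candidate's Euclidean distance to the top-left corner
#' (minimal dispersion, maximal size).  Smaller distances mean better
#' clusters.  An axis with no spread over the candidates contributes zero to
#' every distance.
#'
#' @param mse numeric vector of candidate dispersions.
#' @param size integer vector of candidate sizes (>= 1).
#' @return numeric vector of distances.
#' @export
mn_distances <- function(mse, size) {
  if (length(mse) != length(size) || !length(mse))
    stop_input("mse and size must be non-empty vectors of equal length")
  if (any(size < 1)) stop_input("cluster sizes must be >= 1")
  norm01 <- function(v) {
    r <- range(v)
    if (r[2] - r[1] <= 0) return(rep(NA_real_, length(v)))  # degenerate axis
    (v - r[1]) / (r[2] - r[1])
  }
  mse_n <- norm01(mse)
  size_n <- norm01(log10(size))
  mse_term <- if (all(is.na(mse_n))) rep(0, length(mse)) else mse_n
  size_term <- if (all(is.na(size_n))) rep(0, length(size)) else 1 - size_n
  sqrt(mse_term^2 + size_term^2)
}

#' Sequential M-N scatter-plot cluster selection with overlap removal
#'
#' Repeatedly: compute M-N distances over the remaining candidates, select
#' the candidate closest to the top-left corner, then remove it together
#' with every candidate sharing at least one gene with it, and recompute the
#' axis normalisation over what remains.  Stops when `max_clusters` have
#' been selected or the plane is empty.  Distance ties are broken in favour
#' of the larger cluster, then the lower (K, delta, index) provenance.
#'
#' @param candidates list of candidates, each a list with `genes`, `K`,
#'   `delta`, `index`, `size` and `mse` (as emitted by [uncles()] after
#'   [cluster_mse()] annotation, or see [mn_select()]).
#' @param max_clusters maximum number of clusters to select.
#' @return object of class `mn_selection`: `clusters` (list of selected
#'   candidates with their distances) and `table` (rank, distance, K, delta,
#'   size, mse).
#' @export
select_clusters <- function(candidates, max_clusters = 10L) {
  if (!length(candidates)) stop_input("no candidates to select from")
  need <- c("genes", "K", "delta", "index", "size", "mse")
  if (!all(vapply(candidates, function(cc) all(need %in% names(cc)), TRUE)))
    stop_input("each candidate needs fields %s", paste(need, collapse = ", "))
  remaining <- candidates
  selected <- list()
  while (length(remaining) && length(selected) < max_clusters) {
    d <- mn_distances(vapply(remaining, function(cc) as.numeric(cc$mse), 0),
                      vapply(remaining, function(cc) as.numeric(cc$size), 0))
    tied <- which(d <= min(d) + 1e-12)
    if (length(tied) > 1) {
      key <- vapply(remaining[tied], function(cc)
        c(-cc$size, cc$K, cc$delta, cc$index), numeric(4))
      tied <- tied[order(key[1, ], key[2, ], key[3, ], key[4, ])]
    }
    best <- tied[1]
    win <- remaining[[best]]
    win$distance <- d[best]
    selected[[length(selected) + 1L]] <- win
    overlaps <- vapply(remaining, function(cc)
      length(intersect(cc$genes, win$genes)) > 0, TRUE)
    remaining <- remaining[!overlaps]
  }
  num <- function(field) vapply(selected, function(cc) as.numeric(cc[[field]]), 0)
  tab <- data.frame(
    rank = seq_along(selected),
    distance = num("distance"),
    K = as.integer(num("K")),
    delta = num("delta"),
    size = as.integer(num("size")),
    mse = num("mse"))
  structure(list(clusters = selected, table = tab), class = "mn_selection")
}

#' Score and select the best consensus clusters of a fit
#'
#' Annotates every candidate of an [uncles()] fit with its dispersion
#' ([cluster_mse()] over the fit's collection) and runs the sequential M-N
#' selection ([select_clusters()]).
#'
#' @param fit an `uncles_fit`.
#' @param max_clusters maximum number of clusters to select.
#' @return an `mn_selection`.
#' @export
mn_select <- function(fit, max_clusters = 10L) {
  if (!inherits(fit, "uncles_fit")) stop_input("fit must be an uncles_fit")
  cands <- lapply(fit$candidates, function(cc) {
    cc$mse <- cluster_mse(cc$genes, fit$collection)
    cc
  })
  sel <- select_clusters(cands, max_clusters = max_clusters)
  sel$all_candidates <- cands
  sel
}

#' @export
print.mn_selection <- function(x, ...) {
  cat("M-N scatter-plot selection:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
plot.mn_selection <- function(x, ...) {
  if (is.null(x$all_candidates)) {
    plot(x$table$mse, log10(x$table$size), xlab = "MSE (dispersion)",
         ylab = "log10 size", main = "Selected clusters", ...)
    text(x$table$mse, log10(x$table$size), labels = x$table$rank, pos = 3)
    return(invisible(x))
  }
  mse <- vapply(x$all_candidates, `[[`, 0, "mse")
  size <- vapply(x$all_candidates, `[[`, 0L, "size")
  plot(mse, log10(size), pch = 16, col = "grey60",
       xlab = "MSE (dispersion)", ylab = "log10 size",
       main = "M-N scatter plot", ...)
  points(x$table$mse, log10(x$table$size), pch = 21, bg = "red3", cex = 1.4)
  text(x$table$mse, log10(x$table$size), labels = x$table$rank, pos = 3)
  invisible(x)
}
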
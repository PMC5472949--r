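#' Construct an expression dataset
#'
#' A light container for one dataset: a genes x conditions numeric matrix
#' with gene ids as row names, a platform kind deciding its normalisation
#' (`one_colour` intensities are quantile-normalised and z-scored per gene;
#' `two_colour` log-ratios are only zero-centred per gene) and an id.
#'
#' @param values numeric matrix, genes in rows (row names = gene ids),
#'   conditions in columns.
#' @param platform_kind `"one_colour"` or `"two_colour"`.
#' @param dataset_id character scalar.
#' @param normalised logical; marks whether [normalise_dataset()] has been
#'   applied.
#' @return object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, platform_kind = c("one_colour", "two_colour"),
                               dataset_id = "D1", normalised = FALSE) {
  check_matrix(values, "expression values")
  platform_kind <- match.arg(platform_kind)
  if (is.null(rownames(values)))
    stop_input("expression matrix must carry gene ids as row names")
  rownames(values) <- canon_gene_id(rownames(values))
  if (anyDuplicated(rownames(values)))
    stop_input("duplicate gene ids in dataset '%s'; summarise probes first", dataset_id)
  if (ncol(values) < 1L)
    stop_input("dataset '%s' has no conditions", dataset_id)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("c", seq_len(ncol(values)))
  structure(list(values = values, platform_kind = platform_kind,
                 dataset_id = as.character(dataset_id),
                 normalised = isTRUE(normalised),
                 flagged_genes = character(0)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset '%s': %d genes x %d conditions (%s%s)\n",
              x$dataset_id, nrow(x$values), ncol(x$values), x$platform_kind,
              if (x$normalised) ", normalised" else ""))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Quantile normalisation of an expression matrix
#'
#' Forces all columns to share the same empirical distribution: each value
#' is replaced by the mean, across columns, of the values at its rank, so
#' every column's sorted vector equals the vector of per-rank cross-column
#' means.  Ties within a column receive the mean of the rank means they
#' span.  Within-column rank order is preserved.  A one-row matrix collapses
#' to the row mean in every column (the one-value distribution).
#'
#' @param x numeric matrix without missing cells.
#' @return matrix of the same shape, same dimnames.
#' @examples
#' quantile_normalise(rbind(c(5, 4), c(2, 3)))
#' @export
quantile_normalise <- function(x) {
  check_matrix(x, "expression matrix")
  if (ncol(x) == 1L) return(x)
  if (nrow(x) == 1L) {
    x[] <- mean(x)
    return(x)
  }
  rank_means <- rowMeans(apply(x, 2, sort))
  cs <- c(0, cumsum(rank_means))
  out <- x
  for (j in seq_len(ncol(x))) {
    lo <- rank(x[, j], ties.method = "min")
    hi <- rank(x[, j], ties.method = "max")
    out[, j] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  out
}

#' Collapse replicate samples to per-condition medians
#'
#' @param x numeric matrix (rows = genes, columns = samples).
#' @param replicate_map factor/character vector of length `ncol(x)` naming
#'   the condition of each sample, or a named list of column indices per
#'   condition.
#' @return matrix with one column per condition (first-appearance order),
#'   each cell the median over that condition's replicates.
#' @export
summarise_replicates <- function(x, replicate_map) {
  check_matrix(x, "expression matrix")
  if (is.list(replicate_map)) {
    idx <- replicate_map
    if (is.null(names(idx))) stop_input("replicate_map list must be named by condition")
    all_idx <- unlist(idx, use.names = FALSE)
    if (anyDuplicated(all_idx) || !setequal(all_idx, seq_len(ncol(x))))
      stop_input("every sample must be assigned to exactly one condition")
  } else {
    if (length(replicate_map) != ncol(x))
      stop_input("replicate_map must assign each of the %d samples", ncol(x))
    conds <- unique(as.character(replicate_map))
    idx <- lapply(conds, function(cn) which(as.character(replicate_map) == cn))
    names(idx) <- conds
  }
  if (any(lengths(idx) == 0L)) stop_input("empty condition group in replicate_map")
  out <- vapply(idx, function(j) apply(x[, j, drop = FALSE], 1, median),
                numeric(nrow(x)))
  if (nrow(x) == 1L) out <- matrix(out, nrow = 1, dimnames = list(rownames(x), names(idx)))
  rownames(out) <- rownames(x)
  out
}

#' Pick the representative probe for a gene
#'
#' Among probes where at least 25% of samples exceed `q1` (the first
#' quartile of all expression values in the dataset), returns the index of
#' the probe with the largest coefficient of variation (sd/|mean|,
#' population sd).  If no probe qualifies, the maximum-CV probe overall is
#' returned.  A zero-mean probe with positive sd counts as infinite CV; an
#' all-constant zero-mean probe is excluded (lowest index returned, with a
#' warning, if nothing else remains).
#'
#' @param probe_rows numeric matrix, one row per probe of the same gene.
#' @param q1 first quartile of the whole dataset's expression values.
#' @return single probe row index.
#' @export
select_representative_probe <- function(probe_rows, q1) {
  check_matrix(probe_rows, "probe rows")
  if (nrow(probe_rows) == 1L) return(1L)
  cv <- apply(probe_rows, 1, function(r) {
    s <- pop_sd(r)
    m <- mean(r)
    if (m == 0) {
      if (s > 0) Inf else NA_real_   # constant zero probe: no spread at all
    } else s / abs(m)
  })
  frac_above <- rowMeans(probe_rows > q1)
  qualifies <- frac_above >= 0.25 & !is.na(cv)
  pool <- if (any(qualifies)) which(qualifies) else which(!is.na(cv))
  if (length(pool) == 0L) {
    warning("all probes constant at zero; returning the first", call. = FALSE)
    return(1L)
  }
  pool[which.max(cv[pool])]
}

#' Normalise one dataset according to its platform kind
#'
#' One-colour datasets are quantile-normalised and then each gene's profile
#' shifted and scaled to zero mean and unit standard deviation (population
#' sd, denominator n).  Two-colour log-ratio datasets are only zero-centred
#' per gene.  Constant one-colour genes cannot be scaled; their rows are set
#' to zero and recorded in `$flagged_genes`.
#'
#' @param ds an [expression_dataset()].
#' @return the dataset, normalised (`$normalised = TRUE`).
#' @export
normalise_dataset <- function(ds) {
  if (!inherits(ds, "expression_dataset"))
    stop_input("ds must be an expression_dataset")
  if (ds$normalised) return(ds)   # idempotent
  x <- ds$values
  flagged <- character(0)
  if (ds$platform_kind == "one_colour") {
    x <- quantile_normalise(x)
    mu <- rowMeans(x)
    s <- apply(x, 1, pop_sd)
    const <- s == 0
    s[const] <- 1
    x <- (x - mu) / s
    x[const, ] <- 0
    flagged <- rownames(x)[const]
  } else {
    x <- x - rowMeans(x)
  }
  ds$values <- x
  ds$normalised <- TRUE
  ds$flagged_genes <- flagged
  ds
}

#' Assemble a multi-dataset collection over a shared gene universe
#'
#' The gene universe is the set of genes present in at least `min_presence`
#' of the L datasets (the L* inclusion rule for analyses tolerating
#' per-dataset missing genes).  Genes below the threshold are dropped;
#' datasets keep only universe genes.
#'
#' @param datasets list of [expression_dataset()] objects.
#' @param min_presence L*: minimum number of datasets a gene must appear in.
#' @return object of class `dataset_collection` with fields `datasets`,
#'   `gene_universe`, `presence` (gene x dataset logical matrix),
#'   `min_presence` and `n_dropped`.
#' @export
build_collection <- function(datasets, min_presence) {
  if (!length(datasets) || !all(vapply(datasets, inherits, TRUE, "expression_dataset")))
    stop_input("datasets must be a non-empty list of expression_dataset objects")
  L <- length(datasets)
  if (min_presence < 1 || min_presence > L)
    stop_input("min_presence must be in 1..%d", L)
  ids <- lapply(datasets, function(d) rownames(d$values))
  all_genes <- sort(unique(unlist(ids)))
  presence <- vapply(ids, function(g) all_genes %in% g, logical(length(all_genes)))
  if (length(all_genes) == 1L) presence <- matrix(presence, nrow = 1)
  dimnames(presence) <- list(all_genes,
                             vapply(datasets, function(d) d$dataset_id, ""))
  keep <- rowSums(presence) >= min_presence
  if (!any(keep)) stop_input("no gene reaches min_presence = %d", min_presence)
  universe <- all_genes[keep]
  presence <- presence[keep, , drop = FALSE]
  datasets <- lapply(datasets, function(d) {
    d$values <- d$values[rownames(d$values) %in% universe, , drop = FALSE]
    d
  })
  structure(list(datasets = datasets, gene_universe = universe,
                 presence = presence, min_presence = as.integer(min_presence),
                 n_dropped = sum(!keep)),
            class = "dataset_collection")
}

#' @export
print.dataset_collection <- function(x, ...) {
  cat(sprintf(
    "dataset_collection: L = %d datasets, %d genes present in >= L* = %d (%d dropped)\n",
    length(x$datasets), length(x$gene_universe), x$min_presence, x$n_dropped))
  invisible(x)
}

#' Normalise every dataset of a collection in place
#'
#' @param collection a `dataset_collection`.
#' @return the collection with every member dataset passed through
#'   [normalise_dataset()].
#' @export
normalise_collection <- function(collection) {
  if (!inherits(collection, "dataset_collection"))
    stop_input("collection must be a dataset_collection")
  collection$datasets <- lapply(collection$datasets, normalise_dataset)
  collection
}
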
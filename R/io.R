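#' Read an expression matrix from tab-separated text
#'
#' Expects a header row of sample/condition labels and a first column of
#' gene (or probe) identifiers.  Missing cells are rejected: the package's
#' unit of missingness is a whole gene absent from a dataset, not a cell.
#'
#' @param path file path.
#' @return numeric matrix with gene ids as row names.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_input("%s: need an id column plus >= 1 sample column", path)
  ids <- trimws(as.character(df[[1]]))
  x <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(x)) {
    bad <- which(is.na(suppressWarnings(as.numeric(x))) & !is.na(x))[1]
    stop_input("%s: non-numeric expression value near row %d",
               path, (bad - 1) %% nrow(x) + 2)
  }
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1, ]
    stop_input("%s: missing value at row %d (gene %s); drop the gene instead",
               path, bad[1] + 1, ids[bad[1]])
  }
  rownames(x) <- ids
  x
}

#' Write an expression matrix as tab-separated text
#'
#' First column `gene`, header row of condition labels, floats with 6
#' significant digits.
#'
#' @param x numeric matrix with gene-id row names.
#' @param path output path.
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(gene = rownames(x), signif(x, 6), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then gene ids, tab-separated.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop_input("%s: GMT line with fewer than 3 fields", path)
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(ln)
    strsplit(ln, "\t", fixed = TRUE)[[1]][1], "", USE.NAMES = FALSE)
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional per-set description column (defaults to the
#'   set names).
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  if (is.null(names(sets))) stop_input("sets must be named")
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a replicate map (sample to condition) from TSV
#'
#' Two columns: sample label, condition label.
#'
#' @param path file path.
#' @return character vector of conditions named by sample.
#' @export
read_replicate_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_input("%s: replicate map needs (sample, condition)", path)
  setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Read a probe-to-gene map from TSV
#'
#' Two columns: probe id, gene id.
#'
#' @param path file path.
#' @return character vector of gene ids named by probe.
#' @export
read_probe_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_input("%s: probe map needs (probe, gene)", path)
  setNames(canon_gene_id(df[[2]]), trimws(as.character(df[[1]])))
}

#' Collapse probe rows to one representative row per gene
#'
#' Applies the representative-probe rule to every gene with multiple
#' probes: `"cv"` (cell-line rule, [select_representative_probe()]:
#' maximum coefficient of variation among probes above the first quartile
#' in >= 25% of samples) or `"variance"` (clinical rule,
#' [select_clinical_probeset()]).
#'
#' @param x probes x samples numeric matrix (probe ids as row names).
#' @param probe_map character vector of gene ids named by probe id.
#' @param rule `"cv"` or `"variance"`.
#' @return genes x samples matrix, one row per gene.
#' @export
summarise_probes <- function(x, probe_map, rule = c("cv", "variance")) {
  check_matrix(x, "probe matrix")
  rule <- match.arg(rule)
  genes <- probe_map[rownames(x)]
  if (anyNA(genes)) stop_input("%d probe(s) missing from the probe map",
                               sum(is.na(genes)))
  q1 <- quantile(x, 0.25, names = FALSE)
  picked <- vapply(split(seq_len(nrow(x)), genes), function(rows) {
    if (length(rows) == 1) return(rows)
    sub <- x[rows, , drop = FALSE]
    idx <- if (rule == "cv") select_representative_probe(sub, q1)
           else select_clinical_probeset(sub, q1)
    rows[idx]
  }, 0L)
  out <- x[picked, , drop = FALSE]
  rownames(out) <- names(picked)
  out
}

#' Write a gene x dataset presence mask as TSV
#'
#' @param collection a `dataset_collection`.
#' @param path output path.
#' @export
write_presence_tsv <- function(collection, path) {
  df <- data.frame(gene = rownames(collection$presence),
                   collection$presence * 1L, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read clinical metadata from TSV
#'
#' Columns: `sample`, `os_time`, `os_event`, `er_status` (er_status may be
#' empty/NA).
#'
#' @param path file path.
#' @return data frame.
#' @export
read_clinical_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "os_time", "os_event")
  if (!all(need %in% names(df)))
    stop_input("%s: clinical metadata needs columns %s", path,
               paste(need, collapse = ", "))
  if (!"er_status" %in% names(df)) df$er_status <- NA_character_
  df$er_status[df$er_status %in% c("", "NA")] <- NA_character_
  df
}

#' Serialise a partition to a two-column TSV (gene, cluster index)
#'
#' Unassigned genes are not possible in a complete hard partition; every
#' gene appears once.
#'
#' @param p a [partition()].
#' @param path output path.
#' @export
write_partition_tsv <- function(p, path) {
  lab <- apply(p$membership, 2, which.max)
  df <- data.frame(gene = p$gene_ids, cluster = as.integer(lab))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialise a CoPaM to TSV (genes x K fuzzy values + support)
#'
#' @param copam a [build_copam()] result.
#' @param path output path.
#' @export
write_copam_tsv <- function(copam, path) {
  df <- data.frame(gene = copam$gene_ids, t(signif(copam$fuzzy, 6)),
                   support = copam$support, check.names = FALSE)
  names(df)[2:(copam$K + 1)] <- paste0("cluster", seq_len(copam$K))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
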
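#' Run the full consensus-clustering workflow from a configuration
#'
#' Orchestrates simulate (or read + preprocess), cluster, select, enrich and
#' clinical stages, writing every intermediate artefact plus a
#' machine-readable JSON run manifest (inputs, seed, outputs with MD5
#' checksums).  Re-running with an identical configuration reproduces
#' identical outputs.
#'
#' The configuration is a YAML file or an equivalent nested list with the
#' sections:
#' \describe{
#'   \item{seed}{root seed; all stage randomness derives from it.}
#'   \item{outdir}{output directory (created if absent).}
#'   \item{simulate}{[planted_design()] arguments for a synthetic
#'     collection; mutually exclusive with `datasets`.}
#'   \item{datasets}{list of `path` / `platform` / optional `replicate_map`,
#'     `probe_map` entries plus a top-level `min_presence`.}
#'   \item{cluster}{`k_values`, `delta_grid`, `methods`, `som_epochs`
#'     (defaults: the 8-40 K grid, delta 0-1 by 0.1, all three methods).}
#'   \item{select}{`max_clusters` (default 10).}
#'   \item{enrich}{`lists_gmt`: gene lists tested against every selected
#'     cluster over the collection's gene universe.}
#'   \item{clinical}{`expression` + `metadata` TSV paths (or `simulate`
#'     with [clinical_design()] arguments), `signatures_gmt` (defaults to
#'     the selected clusters), `horizon_years`.}
#' }
#'
#' @param config path to a YAML file, or a nested list.
#' @return (invisibly) the run manifest list; written as
#'   `manifest.json` in `outdir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_input("config must be a list or a YAML path")
  seed <- as.integer(config$seed %||% 1L)
  outdir <- config$outdir %||% "uncles_out"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, outputs = character(0))
  note <- function(path) manifest$outputs <<- c(manifest$outputs, path)

  # ---- collection: simulate or read ----------------------------------
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    sim$seed <- as.integer(sim$seed %||% seed)
    if (!is.null(sim$anticorrelated_pairs))
      sim$anticorrelated_pairs <- lapply(sim$anticorrelated_pairs, unlist)
    design <- do.call(planted_design, sim)
    coll <- generate_collection(design)
    truth <- attr(coll, "truth")
    truth_path <- file.path(outdir, "truth.json")
    jsonlite::write_json(list(clusters = truth$clusters,
                              anticorrelated_pairs = truth$anticorrelated_pairs),
                         truth_path, auto_unbox = TRUE)
    note(truth_path)
    manifest$inputs <- list(simulate = sim)
  } else if (!is.null(config$datasets)) {
    datasets <- lapply(seq_along(config$datasets), function(i) {
      entry <- config$datasets[[i]]
      x <- read_expression_tsv(entry$path)
      if (!is.null(entry$probe_map))
        x <- summarise_probes(x, read_probe_map(entry$probe_map), rule = "cv")
      if (!is.null(entry$replicate_map)) {
        rm_ <- read_replicate_map(entry$replicate_map)
        x <- summarise_replicates(x, unname(rm_[colnames(x)]))
      }
      expression_dataset(x, entry$platform %||% "one_colour",
                         dataset_id = entry$id %||% sprintf("D%02d", i))
    })
    coll <- build_collection(datasets,
                             config$min_presence %||% length(datasets))
    manifest$inputs <- list(datasets = vapply(config$datasets, `[[`, "", "path"))
  } else stop_input("config needs either a 'simulate' or a 'datasets' section")

  coll <- normalise_collection(coll)
  for (ds in coll$datasets) {
    p <- file.path(outdir, paste0(ds$dataset_id, "_normalised.tsv"))
    write_expression_tsv(ds$values, p)
    note(p)
  }
  mask_path <- file.path(outdir, "presence_mask.tsv")
  write_presence_tsv(coll, mask_path)
  note(mask_path)

  # ---- cluster + select ----------------------------------------------
  cl <- config$cluster %||% list()
  fit <- uncles(coll,
                k_values = as.integer(cl$k_values %||% c(8, 9, 10, 16, 18, 24, 30, 40)),
                methods = unlist(cl$methods %||% c("kmeans_ka", "som", "hc_ward")),
                delta_grid = as.numeric(cl$delta_grid %||% seq(0, 1, 0.1)),
                seed = seed,
                som_epochs = as.integer(cl$som_epochs %||% 100L))
  cand_sets <- setNames(
    lapply(fit$candidates, `[[`, "genes"),
    vapply(fit$candidates, function(cc)
      sprintf("C%d_K%d_d%g", cc$index, cc$K, cc$delta), ""))
  cand_path <- file.path(outdir, "candidates.gmt")
  write_gmt(cand_sets, cand_path)
  note(cand_path)

  sel <- mn_select(fit, max_clusters = (config$select$max_clusters %||% 10L))
  sel_tab_path <- file.path(outdir, "selection.tsv")
  write.table(sel$table, sel_tab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  note(sel_tab_path)
  selected <- setNames(lapply(sel$clusters, `[[`, "genes"),
                       paste0("selected", seq_along(sel$clusters)))
  sel_gmt_path <- file.path(outdir, "selected_clusters.gmt")
  write_gmt(selected, sel_gmt_path)
  note(sel_gmt_path)

  # ---- enrichment -----------------------------------------------------
  if (!is.null(config$enrich$lists_gmt)) {
    lists <- read_gmt(config$enrich$lists_gmt)
    rows <- list()
    for (cn in names(selected)) for (ln in names(lists)) {
      r <- overlap_test(selected[[cn]], lists[[ln]], coll$gene_universe)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cn, list = ln, N = r$universe_size, K = r$list_size,
        n = r$cluster_size, k = r$overlap, p_value = r$p_value)
    }
    enr_path <- file.path(outdir, "enrichment.tsv")
    write.table(do.call(rbind, rows), enr_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    note(enr_path)
  }

  # ---- clinical -------------------------------------------------------
  if (!is.null(config$clinical)) {
    cc <- config$clinical
    if (!is.null(cc$simulate)) {
      cd <- cc$simulate
      cd$seed <- as.integer(cd$seed %||% (seed + 1L))
      sigs_for_sim <- cd$signatures %||% selected
      cd$signatures <- NULL
      cd$signature_effects <- unlist(cd$signature_effects %||% numeric(0))
      cd$er_fold_changes <- unlist(cd$er_fold_changes %||% numeric(0))
      cohort <- generate_clinical(do.call(clinical_design, cd), sigs_for_sim)
    } else {
      x <- read_expression_tsv(cc$expression)
      meta <- read_clinical_tsv(cc$metadata)
      if (!all(colnames(x) %in% meta$sample))
        stop_input("clinical metadata misses %d sample(s)",
                   sum(!colnames(x) %in% meta$sample))
      meta <- meta[match(colnames(x), meta$sample), ]
      cohort <- clinical_cohort(x, meta$os_time, meta$os_event, meta$er_status)
    }
    sigs <- if (!is.null(cc$signatures_gmt)) read_gmt(cc$signatures_gmt) else selected
    sigs <- sigs[vapply(sigs, function(s)
      length(intersect(canon_gene_id(s), rownames(cohort$expression))) > 0, TRUE)]
    if (length(sigs)) {
      hs_mat <- vapply(names(sigs), function(s)
        hypoxia_score(sigs[[s]], cohort, s)$scores,
        numeric(ncol(cohort$expression)))
      hs_path <- file.path(outdir, "hypoxia_scores.tsv")
      write.table(data.frame(sample = colnames(cohort$expression), hs_mat,
                             check.names = FALSE),
                  hs_path, sep = "\t", quote = FALSE, row.names = FALSE)
      note(hs_path)
      surv_rows <- lapply(names(sigs), function(s) {
        hs <- hypoxia_score(sigs[[s]], cohort, s)
        cx <- tryCatch(cox_hr(hs, cohort), error = function(e) NULL)
        rc <- tryCatch(roc_auc(hs, cohort, cc$horizon_years %||% 10),
                       error = function(e) NULL)
        data.frame(signature = s,
                   hr = cx$hazard_ratio %||% NA, cox_p = cx$p_value %||% NA,
                   auc = rc$auc %||% NA, auc_p = rc$p_value %||% NA)
      })
      surv_path <- file.path(outdir, "survival_summary.tsv")
      write.table(do.call(rbind, surv_rows), surv_path, sep = "\t",
                  quote = FALSE, row.names = FALSE)
      note(surv_path)
      subs <- list()
      for (s in names(sigs)) {
        sc <- tryCatch(
          subcluster_discovery(sigs[[s]], cohort,
                               cut = cc$subcluster_cut %||% 0.6,
                               min_size = cc$subcluster_min_size %||% 5L),
          error = function(e) NULL)
        if (!is.null(sc) && length(sc$subclusters))
          subs[paste0(s, "_", names(sc$subclusters))] <- sc$subclusters
      }
      if (length(subs)) {
        subs_path <- file.path(outdir, "subclusters.gmt")
        write_gmt(subs, subs_path)
        note(subs_path)
      }
    }
  }

  manifest$checksums <- as.list(tools::md5sum(manifest$outputs))
  manifest$n_candidates <- length(fit$candidates)
  manifest$selected_sizes <- vapply(sel$clusters, `[[`, 0L, "size")
  man_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
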
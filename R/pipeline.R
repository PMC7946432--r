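# Orchestration: end-to-end TRIBE edit discovery and stability analysis.

#' Run the TRIBE edit-discovery arm
#'
#' Calls edits in every experiment replicate against the control, intersects
#' replicates, annotates the common sites with gene/region/metagene
#' information, summarizes the regional distribution, and (given at least
#' five exonic sites) runs k-mer enrichment on intronless windows around
#' the common edits.  When `out_dir` is given, per-replicate bedGraphs, the
#' common-edit table (one fraction column per replicate, the heatmap
#' substrate), the region summary JSON and the enrichment table are
#' written, each stamped with version, config hash and seed.
#'
#' @param pileups named list of experiment `SiteCount` data.frames.
#' @param control control `SiteCount` data.frame (required).
#' @param index a [build_gene_index()].
#' @param genome a `DNAStringSet`.
#' @param call_config an [edit_call_config()].
#' @param flank,k,n_shuffles motif-stage parameters.
#' @param seed seed for the motif-stage shuffles.
#' @param out_dir optional output directory.
#' @return list with `edits` (per replicate), `common`, `annotated`,
#'   `region_summary`, `enrichment` (or `NULL`), `log` (per-stage counts).
#' @export
run_tribe <- function(pileups, control, index, genome,
                      call_config = edit_call_config(), flank = 100,
                      k = 8, n_shuffles = 100, seed = 1, out_dir = NULL) {
  if (is.null(control)) stopf("a control sample is required to call edits")
  if (length(pileups) < 2)
    stopf("replication required: supply >= 2 experiment pileups")
  nm <- names(pileups) %||% paste0("R", seq_along(pileups))
  names(pileups) <- nm
  log <- list()
  edits <- lapply(nm, function(s) {
    e <- call_edits(pileups[[s]], control, call_config)
    log[[paste0("sites_called_", s)]] <<- nrow(e)
    log[[paste0("no_control_", s)]] <<- attr(e, "no_control")
    e
  })
  names(edits) <- nm
  common <- intersect_replicates(edits)
  log$sites_common <- nrow(common)
  annotated <- annotate_edits(common, index)
  summary <- if (nrow(annotated) > 0) region_fractions(annotated) else NULL
  enrichment <- NULL
  if (nrow(annotated) > 0) {
    windows <- extract_edit_windows(annotated, index, genome, flank = flank)
    log$windows <- nrow(windows)
    if (sum(nchar(windows$seq) >= k) >= 5)
      enrichment <- kmer_enrichment(windows, k = k,
                                    n_shuffles = n_shuffles, seed = seed)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (s in nm)
      write_bedgraph(edits[[s]], file.path(out_dir, paste0(s, ".bedgraph")),
                     seed = seed)
    write_tsv_header(common, file.path(out_dir, "common_edits.tsv"),
                     seed = seed, config = call_config)
    write_tsv_header(annotated, file.path(out_dir, "annotated_edits.tsv"),
                     seed = seed, config = call_config)
    if (!is.null(summary))
      jsonlite::write_json(
        c(list(version = es_version(), seed = seed),
          summary[c("fractions", "other_counts",
                    "single_site_gene_count", "n_edits")]),
        file.path(out_dir, "region_summary.json"),
        auto_unbox = TRUE, digits = NA)
    if (!is.null(enrichment))
      write_tsv_header(enrichment, file.path(out_dir, "kmer_enrichment.tsv"),
                       seed = seed, config = list(k = k,
                                                  n_shuffles = n_shuffles))
  }
  list(edits = edits, common = common, annotated = annotated,
       region_summary = summary, enrichment = enrichment, log = log)
}

#' Run the stability arm
#'
#' Differential-expression classes on the exonic counts, the
#' target-vs-background contingency with chi-square, bootstrap class
#' fractions with Fisher-combined significance, optional ARE-score
#' stratification, and the optional intron-read nascent-transcription
#' control.
#'
#' @param exon_counts integer matrix (genes x samples).
#' @param labels condition per column (two levels; alphabetically first
#'   level is the reference of the log2 fold changes).
#' @param targets character vector of target gene ids.
#' @param intron_counts optional intron-read matrix for the nascent arm.
#' @param are_scores optional [gene_are_scores()] table.
#' @param alpha significance threshold.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @param p_adjust p-value adjustment for DE classes (`"none"` or `"BH"`).
#' @param out_dir optional output directory (DE table TSV + report JSON).
#' @return list with `de`, `contingency`, `bootstrap`, `are` (or `NULL`),
#'   `nascent` (or `NULL`), `seed`.
#' @export
run_stability <- function(exon_counts, labels, targets,
                          intron_counts = NULL, are_scores = NULL,
                          alpha = 0.05, n_boot = 1000, seed = 1,
                          p_adjust = "none", out_dir = NULL) {
  if (length(targets) == 0) stopf("a target gene list is required")
  if (length(labels) != ncol(exon_counts))
    stopf("design labels do not match the count-matrix columns")
  de <- classify_de(exon_counts, labels, alpha = alpha,
                    p_adjust = p_adjust, seed = seed)
  cont <- stability_contingency(de, targets)
  boot <- bootstrap_class_fractions(de, targets, n_boot = n_boot,
                                    seed = seed)
  are <- if (!is.null(are_scores))
    are_vs_change(are_scores, de, targets)
  nas <- if (!is.null(intron_counts))
    nascent_fraction_unchanged(intron_counts, labels, targets,
                               alpha = alpha, p_adjust = p_adjust,
                               seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_header(de, file.path(out_dir, "de_table.tsv"), seed = seed)
    report <- list(
      version = es_version(), seed = seed, alpha = alpha, n_boot = n_boot,
      contingency = as.data.frame.matrix(cont$table),
      chisq_statistic = cont$statistic, chisq_p = cont$p,
      class_fractions = as.data.frame.matrix(cont$class_fractions),
      bootstrap_ci = as.data.frame.table(boot$ci),
      combined_p = boot$combined_p,
      nascent_fractions = if (!is.null(nas)) as.list(nas$fractions),
      are = are)
    jsonlite::write_json(report, file.path(out_dir, "stability_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  list(de = de, contingency = cont, bootstrap = boot, are = are,
       nascent = nas, seed = seed)
}
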
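# Edit-site calling: experiment-vs-control comparison of per-position
# nucleotide tallies, thresholding and replicate intersection.

#' Edit-caller configuration
#'
#' Default thresholds follow the TRIBE convention: a site is retained with
#' coverage of at least 20 reads and at least 15% edited reads (both
#' inclusive), and the control must be covered by at least 20 reads with no
#' edited reads at all (`ctrl_max_alt_frac = 0`).
#'
#' @param min_coverage minimum experiment coverage (reads).
#' @param min_edit_frac minimum experiment edited fraction (inclusive).
#' @param ctrl_min_coverage minimum control coverage (reads).
#' @param ctrl_max_alt_frac maximum edited fraction tolerated in the
#'   control (inclusive).
#' @param strand_specific whether site strand comes from a strand-specific
#'   library; when `FALSE` the annotated gene strand decides orientation.
#' @return a validated list of class `EditCallConfig`.
#' @export
edit_call_config <- function(min_coverage = 20, min_edit_frac = 0.15,
                             ctrl_min_coverage = 20, ctrl_max_alt_frac = 0,
                             strand_specific = TRUE) {
  if (min_edit_frac < 0 || min_edit_frac > 1 ||
      ctrl_max_alt_frac < 0 || ctrl_max_alt_frac > 1)
    stopf("fractions must lie in [0, 1]")
  if (min_coverage < 1 || ctrl_min_coverage < 1)
    stopf("coverage thresholds must be >= 1")
  structure(as.list(environment()), class = "EditCallConfig")
}

site_key <- function(df) paste(df$contig, df$pos0, df$strand, sep = ":")

# Edited-read and reference-read counts in sense orientation.  ADAR edits
# sense-strand A to G; on a genomic '-' strand gene this is genomic T to C.
sense_counts <- function(df) {
  minus <- df$strand == "-"
  list(edited = ifelse(minus, df$nC, df$nG),
       refn = ifelse(minus, df$nT, df$nA),
       coverage = df$nA + df$nC + df$nG + df$nT)
}

#' Call edit sites from experiment vs. control tallies
#'
#' A site is reported iff (a) experiment coverage >= `min_coverage`,
#' (b) experiment edited fraction >= `min_edit_frac`, and (c) the control
#' is covered by >= `ctrl_min_coverage` reads with edited fraction <=
#' `ctrl_max_alt_frac`.  Only sense-strand A positions (genomic A under
#' '+' genes, genomic T under '-' genes) are considered.  Sites lacking
#' adequate control coverage are excluded, not called; their number is
#' attached as the `no_control` attribute.
#'
#' @param exp experiment `SiteCount` data.frame (`contig`, `pos0`, `ref`,
#'   `strand`, `nA`, `nC`, `nG`, `nT`, optional `sample_id`).
#' @param ctrl control `SiteCount` data.frame on the same reference.
#' @param cfg an [edit_call_config()].
#' @return `EditSite` data.frame (`contig`, `pos0`, `strand`,
#'   `edit_fraction`, `coverage`, `sample_id`) with attribute `no_control`.
#' @export
call_edits <- function(exp, ctrl, cfg = edit_call_config()) {
  stopifnot(inherits(cfg, "EditCallConfig"))
  keep <- (exp$ref == "A" & exp$strand %in% c("+", ".")) |
    (exp$ref == "T" & exp$strand == "-")
  exp <- exp[keep, , drop = FALSE]
  sc <- sense_counts(exp)
  frac <- ifelse(sc$coverage > 0, sc$edited / sc$coverage, 0)
  pass_exp <- sc$coverage >= cfg$min_coverage & frac >= cfg$min_edit_frac

  ckey <- site_key(ctrl)
  csc <- sense_counts(ctrl)
  cfrac <- ifelse(csc$coverage > 0, csc$edited / csc$coverage, 0)
  m <- match(site_key(exp), ckey)
  have_ctrl <- !is.na(m) & csc$coverage[m] >= cfg$ctrl_min_coverage
  pass_ctrl <- have_ctrl & cfrac[m] <= cfg$ctrl_max_alt_frac
  pass_ctrl[is.na(pass_ctrl)] <- FALSE

  no_control <- sum(pass_exp & !have_ctrl, na.rm = TRUE)
  sel <- pass_exp & pass_ctrl
  out <- data.frame(
    contig = exp$contig[sel], pos0 = exp$pos0[sel],
    strand = exp$strand[sel],
    edit_fraction = frac[sel], coverage = sc$coverage[sel],
    sample_id = if ("sample_id" %in% names(exp)) exp$sample_id[sel] else NA,
    stringsAsFactors = FALSE)
  stopifnot(all(out$coverage >= cfg$min_coverage),
            all(out$edit_fraction >= cfg$min_edit_frac))
  attr(out, "no_control") <- no_control
  out
}

#' Intersect replicate edit sets
#'
#' A site is common iff present (post-threshold) in every replicate, keyed
#' by `(contig, pos0, strand)`.  Per-replicate edit fractions are retained
#' in columns `frac_<sample>` for heatmap-style output.
#'
#' @param replicate_edits list (length >= 2) of `EditSite` data.frames from
#'   [call_edits()].
#' @return data.frame of common sites with per-replicate fraction columns.
#' @export
intersect_replicates <- function(replicate_edits) {
  if (length(replicate_edits) < 2) stopf("replication required: supply >= 2 replicate edit sets")
  keys <- lapply(replicate_edits, site_key)
  common <- Reduce(intersect, keys)
  nm <- names(replicate_edits) %||% paste0("R", seq_along(replicate_edits))
  if (length(common) == 0) {
    warnf("no edit sites common to all replicates")
    out <- data.frame(contig = character(), pos0 = integer(),
                      strand = character(), stringsAsFactors = FALSE)
    for (s in nm) out[[paste0("frac_", s)]] <- numeric()
    return(out)
  }
  first <- replicate_edits[[1]]
  idx <- match(common, keys[[1]])
  out <- data.frame(contig = first$contig[idx], pos0 = first$pos0[idx],
                    strand = first$strand[idx], stringsAsFactors = FALSE)
  for (r in seq_along(replicate_edits)) {
    out[[paste0("frac_", nm[r])]] <-
      replicate_edits[[r]]$edit_fraction[match(common, keys[[r]])]
  }
  out[order(out$contig, out$pos0), , drop = FALSE]
}

#' Write edit sites as bedGraph
#'
#' One line per site: `contig  pos0  pos0+1  edit_percentage` with the
#' percentage on a 0-100 scale, two decimals.  An empty set produces a file
#' holding only the header comment.
#'
#' @param edits `EditSite` data.frame.
#' @param path output path.
#' @param seed optional seed recorded in the header.
#' @return the path, invisibly.
#' @export
write_bedgraph <- function(edits, path, seed = NULL) {
  if (is.null(edits)) stopf("edits must not be NULL")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed = seed), con)
  if (nrow(edits) > 0) {
    writeLines(sprintf("%s\t%d\t%d\t%.2f", edits$contig, edits$pos0,
                       edits$pos0 + 1L, 100 * edits$edit_fraction), con)
  }
  invisible(path)
}

#' Read a bedGraph of edit sites
#'
#' @param path bedGraph path written by [write_bedgraph()].
#' @return data.frame (`contig`, `pos0`, `edit_fraction`).
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  if (length(body) == 0)
    return(data.frame(contig = character(), pos0 = integer(),
                      edit_fraction = numeric(), stringsAsFactors = FALSE))
  parts <- strsplit(lines[body], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 4)
  if (length(bad) > 0)
    stopf("malformed bedGraph line %d in %s", body[bad[1]], path)
  df <- data.frame(
    contig = vapply(parts, `[[`, "", 1),
    pos0 = as.integer(vapply(parts, `[[`, "", 2)),
    end = as.integer(vapply(parts, `[[`, "", 3)),
    pct = as.numeric(vapply(parts, `[[`, "", 4)),
    stringsAsFactors = FALSE)
  if (anyNA(df$pos0) || anyNA(df$pct) || any(df$end != df$pos0 + 1L))
    stopf("malformed bedGraph record in %s", path)
  data.frame(contig = df$contig, pos0 = df$pos0,
             edit_fraction = df$pct / 100, stringsAsFactors = FALSE)
}

# ---- pileup from alignments ------------------------------------------------

#' Per-position nucleotide tallies from a BAM file
#'
#' Pileup restricted to positions whose sense-strand reference base is A
#' (genomic A under '+' genes, genomic T under '-' genes), excluding bases
#' below Q20 and reads below MAPQ 10 (the unique-mapping filter is
#' approximated by the MAPQ threshold).
#'
#' @param bam path to a coordinate-sorted, indexed BAM file.
#' @param genome a `DNAStringSet` (see [read_genome()]).
#' @param index a [build_gene_index()].
#' @param min_base_quality,min_mapq quality filters.
#' @return `SiteCount` data.frame as consumed by [call_edits()].
#' @export
pileup_site_counts <- function(bam, genome, index,
                               min_base_quality = 20, min_mapq = 10) {
  if (!file.exists(bam)) stopf("BAM not found: %s", bam)
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam)))
    stopf("BAM must be coordinate-sorted and indexed (samtools sort/index): %s", bam)
  bf <- Rsamtools::BamFile(bam)
  contigs <- names(Rsamtools::scanBamHeader(bf)$targets)
  if (!all(contigs %in% names(genome)))
    stopf("contig(s) absent from genome: %s",
          paste(setdiff(contigs, names(genome)), collapse = ", "))
  p <- Rsamtools::pileup(
    bf,
    pileupParam = Rsamtools::PileupParam(
      max_depth = 100000L, min_base_quality = as.integer(min_base_quality),
      min_mapq = as.integer(min_mapq),
      distinguish_strands = FALSE, distinguish_nucleotides = TRUE,
      min_nucleotide_depth = 1L))
  if (nrow(p) == 0)
    return(data.frame(contig = character(), pos0 = integer(),
                      ref = character(), strand = character(),
                      nA = integer(), nC = integer(), nG = integer(),
                      nT = integer(), sample_id = character(),
                      stringsAsFactors = FALSE))
  key <- paste(p$seqnames, p$pos)
  ukey <- unique(key)
  tab <- data.frame(contig = sub(" .*", "", ukey),
                    pos0 = as.integer(sub(".* ", "", ukey)) - 1L,
                    nA = 0L, nC = 0L, nG = 0L, nT = 0L,
                    stringsAsFactors = FALSE)
  for (b in c("A", "C", "G", "T")) {
    sel <- p$nucleotide == b
    agg <- tapply(p$count[sel], key[sel], sum)
    tab[[paste0("n", b)]][match(names(agg), ukey)] <- as.integer(agg)
  }
  # gene strand at each position; positions outside annotated exons dropped
  gr <- GenomicRanges::GRanges(tab$contig,
                               IRanges::IRanges(tab$pos0 + 1L, tab$pos0 + 1L))
  hits <- GenomicRanges::findOverlaps(gr, index$exons, ignore.strand = TRUE)
  first <- !duplicated(S4Vectors::queryHits(hits))
  strand <- rep(NA_character_, nrow(tab))
  strand[S4Vectors::queryHits(hits)[first]] <- as.character(
    GenomicRanges::strand(index$exons))[S4Vectors::subjectHits(hits)[first]]
  tab$strand <- strand
  refb <- mapply(function(ctg, p0)
    as.character(Biostrings::subseq(genome[[ctg]], p0 + 1L, p0 + 1L)),
    tab$contig, tab$pos0, USE.NAMES = FALSE)
  tab$ref <- refb
  keep <- !is.na(tab$strand) &
    ((tab$ref == "A" & tab$strand == "+") |
       (tab$ref == "T" & tab$strand == "-"))
  tab <- tab[keep, c("contig", "pos0", "ref", "strand",
                     "nA", "nC", "nG", "nT")]
  tab$sample_id <- sub("\\.bam$", "", basename(bam))
  rownames(tab) <- NULL
  tab
}
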
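# Intron-read ("nascent transcript") analysis: intron intervals purged of
# all exon overlap, and the exon/intron comparison that separates
# transcriptional from posttranscriptional expression changes.

#' Build exon-purged intron intervals
#'
#' For each gene, introns are the gene span minus the union of every exon
#' of every transcript of every gene (so an interval overlapping another
#' gene's exon is excluded).  Genes with no residual intronic interval are
#' absent.
#'
#' @param models list of `TranscriptModel` (all isoforms, all genes).
#' @return data.frame (`gene_id`, `contig`, `start0`, `end0`, `strand`)
#'   with 0-based half-open coordinates; intervals disjoint and free of
#'   exon overlap.
#' @export
build_intron_annotation <- function(models) {
  idx <- build_gene_index(models)
  exon_union <- GenomicRanges::reduce(idx$exons, ignore.strand = TRUE)
  rows <- list()
  for (g in idx$spans$gene_id) {
    span <- idx$spans[idx$spans$gene_id == g]
    GenomicRanges::strand(span) <- "*"
    introns <- GenomicRanges::setdiff(span, exon_union,
                                      ignore.strand = TRUE)
    if (length(introns) == 0) next
    rows[[g]] <- data.frame(
      gene_id = g,
      contig = as.character(GenomicRanges::seqnames(introns)),
      start0 = GenomicRanges::start(introns) - 1L,
      end0 = GenomicRanges::end(introns),
      strand = as.character(GenomicRanges::strand(
        idx$spans[idx$spans$gene_id == g])),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows) %||%
    data.frame(gene_id = character(), contig = character(),
               start0 = integer(), end0 = integer(), strand = character())
  rownames(out) <- NULL
  # invariant: zero overlap with the global exon union
  if (nrow(out) > 0) {
    igr <- GenomicRanges::GRanges(out$contig,
                                  IRanges::IRanges(out$start0 + 1L,
                                                   out$end0))
    stopifnot(length(GenomicRanges::findOverlaps(
      igr, exon_union, ignore.strand = TRUE)) == 0)
  }
  out
}

#' Export intron intervals as a SAF-like table
#'
#' @param introns a [build_intron_annotation()] data.frame.
#' @param path output path (TSV: GeneID, Chr, Start, End, Strand; 1-based
#'   inclusive).
#' @return the path, invisibly.
#' @export
write_intron_saf <- function(introns, path) {
  saf <- data.frame(GeneID = introns$gene_id, Chr = introns$contig,
                    Start = introns$start0 + 1L, End = introns$end0,
                    Strand = introns$strand)
  write.table(saf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Nascent-transcription verdict from intron counts
#'
#' Runs the same normalization and permutation classifier as the exonic
#' arm on an intron-read count matrix and reports the class fractions of
#' the target genes.  A high unchanged fraction alongside exonic
#' downregulation is the signature of a posttranscriptional effect.
#'
#' @param intron_counts integer matrix (genes x samples) of intron reads.
#' @param labels condition per column.
#' @param targets character vector of target gene ids (>= 5 must have
#'   intronic counts).
#' @param alpha significance threshold passed to [classify_de()].
#' @param ... further arguments to [classify_de()].
#' @return list with `fractions` (down/unchanged/up among targets),
#'   `n_targets`, and the full `de` table.
#' @export
nascent_fraction_unchanged <- function(intron_counts, labels, targets,
                                       alpha = 0.05, ...) {
  if (length(targets) == 0) stopf("empty target set")
  present <- intersect(targets, rownames(intron_counts))
  if (length(present) < 5)
    stopf("fewer than 5 targets with intronic counts")
  de <- classify_de(intron_counts, labels, alpha = alpha, ...)
  cls <- de_class_factor(de$class[match(present, de$gene)])
  fr <- as.numeric(table(cls)) / length(present)
  names(fr) <- levels(cls)
  list(fractions = fr, n_targets = length(present), de = de)
}
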
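# Reference sequences, transcript models and coordinate arithmetic.
#
# All internal coordinates are 0-based half-open.  GTF (1-based inclusive)
# and bedGraph (0-based half-open) are converted at the I/O boundary only.

#' Construct a transcript model
#'
#' A transcript model holds the exon structure of a single transcript and
#' supports genome/mRNA coordinate conversion.  Exons are 0-based half-open
#' genomic intervals, sorted by start and non-overlapping.  `cds_span`, when
#' present, is the genomic min/max span of the coding sequence; its endpoints
#' must fall in exons.
#'
#' @param transcript_id,gene_id character identifiers.
#' @param contig contig (chromosome) name.
#' @param strand `"+"` or `"-"`.
#' @param exons integer matrix with two columns (start, end), 0-based
#'   half-open.
#' @param cds_span optional length-2 integer vector (start, end), 0-based
#'   half-open genomic span of the CDS.
#' @return An object of class `TranscriptModel`.
#' @export
transcript_model <- function(transcript_id, gene_id, contig, strand, exons,
                             cds_span = NULL) {
  if (!strand %in% c("+", "-"))
    stopf("strand must be '+' or '-', got '%s'", strand)
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] <= exons[, 1]))
    stopf("transcript %s: empty or inverted exon", transcript_id)
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stopf("transcript %s: overlapping exons", transcript_id)
  t <- structure(list(
    transcript_id = transcript_id, gene_id = gene_id,
    contig = contig, strand = strand, exons = exons,
    cds_span = if (!is.null(cds_span)) as.integer(cds_span)
  ), class = "TranscriptModel")
  if (!is.null(cds_span)) {
    if (is.na(genomic_to_mrna(t, cds_span[1])) ||
        is.na(genomic_to_mrna(t, cds_span[2] - 1L)))
      stopf("transcript %s: cds_span endpoints not exonic", transcript_id)
  }
  t
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s (gene %s) %s:%s strand %s, %d exon(s), mRNA %d nt%s\n",
              x$transcript_id, x$gene_id, x$contig,
              paste0(x$exons[1, 1], "-", x$exons[nrow(x$exons), 2]),
              x$strand, nrow(x$exons), mrna_length(x),
              if (is.null(x$cds_span)) " (non-coding)" else ""))
  invisible(x)
}

#' Total mRNA (spliced) length of a transcript
#' @param t a `TranscriptModel`.
#' @return integer, the sum of exon lengths.
#' @export
mrna_length <- function(t) sum(t$exons[, 2] - t$exons[, 1])

#' Convert genomic positions to mRNA positions
#'
#' Positions are 0-based.  On the minus strand, mRNA position 0 is the
#' 3'-most genomic base of the transcript (i.e. the 5' end of the mRNA).
#' Non-exonic positions map to `NA` (the "not exonic" sentinel), never to an
#' error.
#'
#' @param t a `TranscriptModel`.
#' @param gpos integer vector of 0-based genomic positions on `t`'s contig.
#' @return integer vector of 0-based mRNA positions, `NA` where not exonic.
#' @export
genomic_to_mrna <- function(t, gpos) {
  ex <- t$exons
  widths <- ex[, 2] - ex[, 1]
  cum <- cumsum(c(0L, widths))
  # exon index: largest i with start[i] <= gpos, then bounds check
  idx <- findInterval(gpos, ex[, 1])
  m <- rep(NA_integer_, length(gpos))
  ok <- idx >= 1 & !is.na(gpos)
  ok[ok] <- gpos[ok] < ex[idx[ok], 2]
  m[ok] <- cum[idx[ok]] + (gpos[ok] - ex[idx[ok], 1])
  if (t$strand == "-") m[ok] <- mrna_length(t) - 1L - m[ok]
  as.integer(m)
}

#' Convert mRNA positions to genomic positions
#'
#' Inverse of [genomic_to_mrna()]; the two compose to the identity on every
#' exonic position.
#'
#' @param t a `TranscriptModel`.
#' @param mpos integer vector of 0-based mRNA positions in `[0, mRNA length)`.
#' @return integer vector of 0-based genomic positions.
#' @export
mrna_to_genomic <- function(t, mpos) {
  L <- mrna_length(t)
  if (any(mpos < 0 | mpos >= L, na.rm = TRUE))
    stopf("mRNA position out of range [0, %d)", L)
  p <- if (t$strand == "-") L - 1L - mpos else mpos
  ex <- t$exons
  cum <- cumsum(c(0L, ex[, 2] - ex[, 1]))
  idx <- findInterval(p, cum, rightmost.closed = FALSE)
  as.integer(ex[idx, 1] + (p - cum[idx]))
}

#' 5'UTR / CDS / 3'UTR segment lengths of a coding transcript
#'
#' Splits the mRNA into its untranslated and coding segments, respecting
#' strand: the 5'UTR is the mRNA-coordinate prefix upstream of the CDS.
#' The three lengths always sum to the mRNA length.
#'
#' @param t a `TranscriptModel` with a `cds_span`.
#' @return named integer vector `c(utr5, cds, utr3)`.
#' @export
utr_cds_segments <- function(t) {
  if (is.null(t$cds_span))
    stopf("non-coding transcript %s: no CDS", t$transcript_id)
  L <- mrna_length(t)
  m1 <- genomic_to_mrna(t, t$cds_span[1])
  m2 <- genomic_to_mrna(t, t$cds_span[2] - 1L)
  cds_start <- min(m1, m2)             # mRNA position of first coding base
  cds_len <- abs(m2 - m1) + 1L
  c(utr5 = cds_start, cds = cds_len, utr3 = L - cds_start - cds_len)
}

# ---- annotation I/O --------------------------------------------------------

#' Load transcript models from a GTF file
#'
#' Reads `exon` and `CDS` features carrying `gene_id` and `transcript_id`
#' attributes and assembles one [transcript_model()] per transcript.  GTF
#' 1-based inclusive coordinates are converted to 0-based half-open.
#' Transcripts with CDS but no exon features are dropped with a warning.
#'
#' @param gtf_path path to a GTF file.
#' @return list of `TranscriptModel` objects.
#' @export
load_annotation <- function(gtf_path) {
  if (!file.exists(gtf_path)) stopf("GTF file not found: %s", gtf_path)
  lines <- readLines(gtf_path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) {
    bad <- which(body)[which(nf < 9)[1]]
    stopf("unparseable GTF line %d: expected 9 tab-separated fields", bad)
  }
  types <- vapply(fields, `[[`, "", 3)
  keep <- types %in% c("exon", "CDS")
  strands <- vapply(fields, `[[`, "", 7)
  if (any(keep & !strands %in% c("+", "-"))) {
    bad <- which(body)[which(keep & !strands %in% c("+", "-"))[1]]
    stopf("GTF line %d: strand must be '+' or '-'", bad)
  }
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[gr$type %in% c("exon", "CDS")]
  if (length(gr) == 0) return(list())
  tid <- as.character(gr$transcript_id)
  gid <- as.character(gr$gene_id)
  if (anyNA(tid) || anyNA(gid))
    stopf("GTF exon/CDS features must carry gene_id and transcript_id")
  typ <- as.character(gr$type)
  st <- GenomicRanges::start(gr) - 1L   # to 0-based half-open
  en <- GenomicRanges::end(gr)
  contig <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))

  models <- list()
  for (t in unique(tid)) {
    sel <- tid == t
    ex <- sel & typ == "exon"
    if (!any(ex)) {
      warnf("transcript %s has CDS but no exon features; dropped", t)
      next
    }
    cds <- sel & typ == "CDS"
    cds_span <- if (any(cds)) c(min(st[cds]), max(en[cds]))
    models[[t]] <- transcript_model(
      transcript_id = t, gene_id = gid[ex][1],
      contig = contig[ex][1], strand = strand[ex][1],
      exons = cbind(st[ex], en[ex]), cds_span = cds_span)
  }
  unname(models)
}

#' Write transcript models as GTF
#'
#' Emits `exon` features and, for coding transcripts, `CDS` features (the
#' CDS span intersected with the exons).  Round-trips with
#' [load_annotation()].
#'
#' @param models list of `TranscriptModel`.
#' @param path output path.
#' @param source value of the GTF source column.
#' @return the path, invisibly.
#' @export
write_gtf <- function(models, path, source = "editscope") {
  lines <- character()
  for (t in models) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     t$gene_id, t$transcript_id)
    for (i in seq_len(nrow(t$exons))) {
      lines <- c(lines, paste(t$contig, source, "exon",
                              t$exons[i, 1] + 1L, t$exons[i, 2],
                              ".", t$strand, ".", attrs, sep = "\t"))
    }
    if (!is.null(t$cds_span)) {
      for (i in seq_len(nrow(t$exons))) {
        a <- max(t$exons[i, 1], t$cds_span[1])
        b <- min(t$exons[i, 2], t$cds_span[2])
        if (a < b)
          lines <- c(lines, paste(t$contig, source, "CDS",
                                  a + 1L, b, ".", t$strand, ".", attrs,
                                  sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param fasta_path path to a (multi-record) FASTA file.
#' @return a named [Biostrings::DNAStringSet] with uppercase A/C/G/T/N.
#' @export
read_genome <- function(fasta_path) {
  g <- Biostrings::readDNAStringSet(fasta_path)
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g))) stopf("duplicate contig names in FASTA")
  bad <- Biostrings::alphabetFrequency(g)
  extra <- rowSums(bad[, !colnames(bad) %in% c("A", "C", "G", "T", "N"),
                       drop = FALSE])
  if (any(extra > 0)) stopf("genome alphabet restricted to A/C/G/T/N")
  g
}

#' Write a genome to FASTA
#' @param genome a named `DNAStringSet`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

# ---- gene model index ------------------------------------------------------

#' Build a gene model index
#'
#' Chooses one representative transcript per gene (the longest mRNA; ties
#' broken by lexicographically smallest transcript id) and builds searchable
#' exon and gene-span interval indexes used for edit assignment.
#'
#' @param models list of `TranscriptModel` (all isoforms).
#' @return an object of class `GeneModelIndex` with elements
#'   `representatives` (named list of `TranscriptModel` keyed by gene),
#'   `exons` (per-gene reduced exon `GRanges` with a `gene_id` column),
#'   `spans` (per-gene span `GRanges`), and `models` (the input list).
#' @export
build_gene_index <- function(models) {
  if (length(models) == 0) stopf("no transcript models supplied")
  gid <- vapply(models, `[[`, "", "gene_id")
  tid <- vapply(models, `[[`, "", "transcript_id")
  len <- vapply(models, mrna_length, 0L)
  reps <- list()
  for (g in unique(gid)) {
    sel <- which(gid == g)
    sel <- sel[order(-len[sel], tid[sel])]
    reps[[g]] <- models[[sel[1]]]
  }
  nex <- vapply(models, function(t) nrow(t$exons), 0L)
  ex <- GenomicRanges::GRanges(
    rep(vapply(models, `[[`, "", "contig"), nex),
    IRanges::IRanges(
      unlist(lapply(models, function(t) t$exons[, 1])) + 1L,
      unlist(lapply(models, function(t) t$exons[, 2]))),
    strand = rep(vapply(models, `[[`, "", "strand"), nex))
  ex$gene_id <- rep(gid, nex)
  # reduce per gene, keeping gene_id
  ex_by_gene <- S4Vectors::split(ex, ex$gene_id)
  red <- GenomicRanges::reduce(ex_by_gene)
  exons <- unlist(red, use.names = FALSE)
  exons$gene_id <- rep(names(red), lengths(red))
  # one span per gene and contig, strand-agnostic (a gene may carry
  # isoforms on both strands in pathological annotations)
  red_u <- GenomicRanges::reduce(ex_by_gene, ignore.strand = TRUE)
  spans <- unlist(range(red_u, ignore.strand = TRUE), use.names = FALSE)
  spans$gene_id <- rep(names(red_u),
                       lengths(range(red_u, ignore.strand = TRUE)))
  sp_strand <- vapply(S4Vectors::split(as.character(
    GenomicRanges::strand(ex)), ex$gene_id), function(s)
      if (length(unique(s)) == 1) s[1] else "*", "")
  GenomicRanges::strand(spans) <- sp_strand[spans$gene_id]
  structure(list(representatives = reps, exons = exons, spans = spans,
                 models = models),
            class = "GeneModelIndex")
}

#' @export
print.GeneModelIndex <- function(x, ...) {
  cat(sprintf("GeneModelIndex: %d genes, %d transcripts\n",
              length(x$representatives), length(x$models)))
  invisible(x)
}

#' Export intervals as BED6
#'
#' @param df data.frame with columns `contig`, `start0`, `end0`, `name`,
#'   `score`, `strand` (0-based half-open coordinates).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(df$contig, df$start0, df$end0,
                    df$name %||% ".", df$score %||% 0, df$strand %||% ".")
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
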
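# Assignment of called edits to genes, transcript regions and metagene
# coordinates; regional summary statistics.

REGION_LEVELS <- c("5UTR", "CDS", "3UTR", "noncoding_exon", "intron",
                   "intergenic")

# Region and metagene coordinate of one mRNA position on a representative
# transcript.  Metagene: 5'UTR -> [0,1), CDS -> [1,2), 3'UTR -> [2,3),
# each region scaled to unit length.
region_of_mpos <- function(tm, mpos) {
  if (is.null(tm$cds_span))
    return(list(region = "noncoding_exon", metagene_x = NA_real_))
  seg <- utr_cds_segments(tm)
  if (mpos < seg["utr5"]) {
    list(region = "5UTR", metagene_x = mpos / seg["utr5"])
  } else if (mpos < seg["utr5"] + seg["cds"]) {
    list(region = "CDS", metagene_x = 1 + (mpos - seg["utr5"]) / seg["cds"])
  } else {
    list(region = "3UTR",
         metagene_x = 2 + (mpos - seg["utr5"] - seg["cds"]) / seg["utr3"])
  }
}

#' Annotate edit sites with gene, region and metagene coordinate
#'
#' Each edit is assigned to the gene whose exon union contains it (matching
#' strand when the edit carries one).  When two genes' exons overlap the
#' site, the gene whose representative transcript places the site in a UTR
#' is preferred; remaining ties go to the lexicographically smaller gene
#' id.  Region and metagene coordinate come from the gene's representative
#' transcript; sites inside a gene span but outside exons are introns,
#' everything else intergenic.
#'
#' @param edits data.frame with columns `contig`, `pos0`, `strand`.
#' @param index a [build_gene_index()].
#' @return the input columns plus `gene_id`, `region`, `mrna_pos`,
#'   `metagene_x` (the latter present only for 5'UTR/CDS/3'UTR sites).
#' @export
annotate_edits <- function(edits, index) {
  stopifnot(inherits(index, "GeneModelIndex"))
  n <- nrow(edits)
  gene_id <- rep(NA_character_, n)
  region <- rep("intergenic", n)
  mrna_pos <- rep(NA_integer_, n)
  metagene_x <- rep(NA_real_, n)
  if (n == 0)
    return(cbind(edits, gene_id, region, mrna_pos, metagene_x))
  gr <- GenomicRanges::GRanges(edits$contig,
                               IRanges::IRanges(edits$pos0 + 1L,
                                                edits$pos0 + 1L))
  ex_hits <- GenomicRanges::findOverlaps(gr, index$exons,
                                         ignore.strand = TRUE)
  sp_hits <- GenomicRanges::findOverlaps(gr, index$spans,
                                         ignore.strand = TRUE)
  ex_strand <- as.character(GenomicRanges::strand(index$exons))
  sp_strand <- as.character(GenomicRanges::strand(index$spans))
  for (i in seq_len(n)) {
    s <- edits$strand[i]
    cand <- S4Vectors::subjectHits(ex_hits)[S4Vectors::queryHits(ex_hits) == i]
    if (s %in% c("+", "-"))
      cand <- cand[ex_strand[cand] == s]
    genes <- unique(index$exons$gene_id[cand])
    if (length(genes) > 0) {
      info <- lapply(genes, function(g) {
        tm <- index$representatives[[g]]
        mp <- genomic_to_mrna(tm, edits$pos0[i])
        if (is.na(mp)) return(list(region = "intron",
                                   metagene_x = NA_real_, mpos = NA_integer_))
        r <- region_of_mpos(tm, mp)
        list(region = r$region, metagene_x = r$metagene_x, mpos = mp)
      })
      is_utr <- vapply(info, function(x) x$region %in% c("5UTR", "3UTR"),
                       TRUE)
      ord <- order(-is_utr, genes)
      g <- genes[ord[1]]; inf <- info[[ord[1]]]
      gene_id[i] <- g
      region[i] <- inf$region
      mrna_pos[i] <- inf$mpos
      metagene_x[i] <- inf$metagene_x
    } else {
      cand <- S4Vectors::subjectHits(sp_hits)[S4Vectors::queryHits(sp_hits) == i]
      if (s %in% c("+", "-"))
        cand <- cand[sp_strand[cand] == s]
      genes <- sort(unique(index$spans$gene_id[cand]))
      if (length(genes) > 0) {
        gene_id[i] <- genes[1]
        region[i] <- "intron"
      }
    }
  }
  out <- cbind(edits, data.frame(gene_id = gene_id, region = region,
                                 mrna_pos = mrna_pos,
                                 metagene_x = metagene_x,
                                 stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Regional summary of annotated edits
#'
#' Fractions are computed over the three mRNA regions (5'UTR/CDS/3'UTR);
#' noncoding-exon, intron and intergenic edits are counted separately.
#' Also reports edits per gene and the number of genes edited at a single
#' site.
#'
#' @param annots output of [annotate_edits()].
#' @return list of class `RegionSummary`: `fractions` (named, sums to 1
#'   over mRNA regions), `other_counts`, `edits_per_gene`,
#'   `single_site_gene_count`, `n_edits`.
#' @export
region_fractions <- function(annots) {
  if (is.null(annots) || nrow(annots) == 0) stopf("no edits supplied")
  mr <- annots$region[annots$region %in% c("5UTR", "CDS", "3UTR")]
  if (length(mr) == 0) {
    warnf("no edits fall in mRNA regions; fractions reported as 0")
    fr <- setNames(rep(0, 3), c("5UTR", "CDS", "3UTR"))
  } else {
    fr <- table(factor(mr, levels = c("5UTR", "CDS", "3UTR"))) / length(mr)
    fr <- setNames(as.numeric(fr), names(fr))
  }
  other <- table(factor(annots$region,
                        levels = c("noncoding_exon", "intron", "intergenic")))
  epg <- table(annots$gene_id[!is.na(annots$gene_id)])
  structure(list(
    fractions = fr,
    other_counts = setNames(as.integer(other), names(other)),
    edits_per_gene = setNames(as.integer(epg), names(epg)),
    single_site_gene_count = sum(epg == 1),
    n_edits = nrow(annots)), class = "RegionSummary")
}

#' @export
print.RegionSummary <- function(x, ...) {
  cat(sprintf("RegionSummary: %d edits in %d genes (%d single-site)\n",
              x$n_edits, length(x$edits_per_gene),
              x$single_site_gene_count))
  cat(sprintf("  5'UTR %.1f%%  CDS %.1f%%  3'UTR %.1f%%\n",
              100 * x$fractions["5UTR"], 100 * x$fractions["CDS"],
              100 * x$fractions["3UTR"]))
  invisible(x)
}

#' Edits versus expression level
#'
#' Emits the scatter table behind "edits are independent of expression":
#' one row per gene in the expression map with its mean normalized count
#' and an edited flag, plus the Spearman correlation between expression
#' and per-gene edit count among edited genes (absent with fewer than two
#' edited genes).
#'
#' @param annots output of [annotate_edits()].
#' @param expression named numeric vector, gene id -> mean normalized
#'   count; must cover at least 90% of edited genes.
#' @return list with `table` (gene, expression, edited, n_edits) and `rho`.
#' @export
expression_independence <- function(annots, expression) {
  if (length(expression) == 0 || is.null(names(expression)))
    stopf("expression must be a non-empty named vector")
  edited_genes <- unique(annots$gene_id[!is.na(annots$gene_id)])
  covered <- mean(edited_genes %in% names(expression))
  if (length(edited_genes) > 0 && covered < 0.9)
    stopf("expression covers only %.0f%% of edited genes", 100 * covered)
  epg <- table(annots$gene_id[!is.na(annots$gene_id)])
  tab <- data.frame(
    gene = names(expression),
    expression = as.numeric(expression),
    edited = names(expression) %in% edited_genes,
    n_edits = as.integer(epg[names(expression)]),
    stringsAsFactors = FALSE)
  tab$n_edits[is.na(tab$n_edits)] <- 0L
  ed <- tab[tab$edited, ]
  rho <- if (nrow(ed) >= 2 && sd(ed$n_edits) > 0 && sd(ed$expression) > 0)
    cor(ed$expression, ed$n_edits, method = "spearman") else NA_real_
  list(table = tab, rho = rho)
}
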
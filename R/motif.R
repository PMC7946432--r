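# Motif windows around edits, k-mer enrichment against a
# dinucleotide-preserving shuffle null, and AU-rich-element scoring.

#' Spliced mRNA sequence of a transcript
#'
#' @param tm a `TranscriptModel`.
#' @param genome a `DNAStringSet`.
#' @return character scalar (DNA alphabet, 5'->3' on the mRNA).
#' @export
mrna_sequence <- function(tm, genome) {
  if (!tm$contig %in% names(genome))
    stopf("contig %s absent from genome", tm$contig)
  chunks <- Biostrings::extractAt(
    genome[[tm$contig]],
    IRanges::IRanges(tm$exons[, 1] + 1L, tm$exons[, 2]))
  s <- Biostrings::DNAString(paste(as.character(chunks), collapse = ""))
  if (tm$strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Extract intronless windows around edit sites
#'
#' Windows are taken in mRNA coordinates of each gene's representative
#' transcript (hence spliced/intronless), truncated at transcript ends
#' without padding, and transliterated to the RNA alphabet.
#'
#' @param annots annotated edits from [annotate_edits()] (non-exonic edits
#'   are skipped with a warning).
#' @param index a [build_gene_index()].
#' @param genome a `DNAStringSet`.
#' @param flank nucleotides on either side of the edited base.
#' @return data.frame (`gene_id`, `mrna_pos`, `win_start`, `seq`); `seq`
#'   is ACGU and at most `2*flank + 1` nt.
#' @export
extract_edit_windows <- function(annots, index, genome, flank = 100) {
  ok <- !is.na(annots$mrna_pos)
  if (any(!ok))
    warnf("%d non-exonic edit(s) skipped", sum(!ok))
  annots <- annots[ok, , drop = FALSE]
  rows <- lapply(seq_len(nrow(annots)), function(i) {
    tm <- index$representatives[[annots$gene_id[i]]]
    L <- mrna_length(tm)
    m <- annots$mrna_pos[i]
    a <- max(0L, m - flank)
    b <- min(L, m + flank + 1L)
    s <- substr(mrna_sequence(tm, genome), a + 1L, b)
    data.frame(gene_id = annots$gene_id[i], mrna_pos = m, win_start = a,
               seq = chartr("T", "U", s), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows) %||%
    data.frame(gene_id = character(), mrna_pos = integer(),
               win_start = integer(), seq = character())
}

# ---- dinucleotide-preserving shuffle ---------------------------------------

# Altschul-Erickson doublet shuffle: permutes a sequence uniformly among
# those with identical dinucleotide composition (and identical first and
# last characters).  Operates on any alphabet.
dinuc_shuffle <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  if (n < 3) return(s)
  first <- ch[1]; last <- ch[n]
  succ <- split(ch[-1], factor(ch[-n], levels = unique(ch[-n])))
  verts <- names(succ)
  # choose, for every vertex except the terminal one, a "last exit" edge
  # such that following last exits always reaches the terminal vertex
  repeat {
    lastedge <- vapply(succ, function(e) e[sample.int(length(e), 1)], "")
    ok <- TRUE
    for (v in setdiff(verts, last)) {
      cur <- v; seen <- character()
      while (cur != last) {
        if (cur %in% seen || !cur %in% names(lastedge)) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- lastedge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  pools <- list()
  for (v in verts) {
    e <- succ[[v]]
    if (v != last) e <- e[-match(lastedge[[v]], e)]
    pools[[v]] <- if (length(e)) e[sample.int(length(e))] else character()
  }
  out <- character(n)
  out[1] <- first
  ptr <- setNames(rep(1L, length(verts)), verts)
  cur <- first
  for (i in 2:n) {
    pool <- pools[[cur]]
    nxt <- if (ptr[[cur]] <= length(pool)) {
      p <- pool[ptr[[cur]]]
      ptr[[cur]] <- ptr[[cur]] + 1L
      p
    } else lastedge[[cur]]
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

kmer_table <- function(seqs, k, levels = NULL) {
  kmers <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, 1:(n - k + 1), k:n)
  }))
  if (is.null(levels)) table(kmers) else
    table(factor(kmers, levels = levels))
}

#' k-mer enrichment against a dinucleotide-preserving shuffle null
#'
#' Counts every k-mer across the supplied windows and compares each
#' observed count with its distribution over `n_shuffles` rounds of
#' per-window dinucleotide-preserving (Altschul-Erickson) shuffles:
#' `z = (obs - mean_null) / sd_null` and an empirical p-value
#' `(1 + #` rounds `>= obs) / (n_shuffles + 1)`.  Ranked by z, ties broken
#' by observed count then lexicographically.
#'
#' @param windows data.frame from [extract_edit_windows()] (or any with a
#'   `seq` column); at least 5 windows of length >= k required.
#' @param k k-mer length.
#' @param n_shuffles shuffle rounds (must be > 0).
#' @param seed integer seed for the shuffles.
#' @return data.frame (`kmer`, `observed`, `expected`, `z`, `p`), ranked.
#' @export
kmer_enrichment <- function(windows, k = 8, n_shuffles = 100, seed = 1) {
  if (n_shuffles < 1) stopf("null model required: n_shuffles must be >= 1")
  seqs <- windows$seq
  seqs <- seqs[nchar(seqs) >= k]
  if (length(seqs) == 0) stopf("all windows shorter than k")
  if (length(seqs) < 5) stopf("need at least 5 windows of length >= k")
  obs <- kmer_table(seqs, k)
  lev <- names(obs)
  set.seed(seed)
  nullm <- matrix(0L, length(lev), n_shuffles, dimnames = list(lev, NULL))
  for (r in seq_len(n_shuffles)) {
    sh <- vapply(seqs, dinuc_shuffle, "", USE.NAMES = FALSE)
    nullm[, r] <- as.integer(kmer_table(sh, k, levels = lev))
  }
  mu <- rowMeans(nullm)
  sdv <- apply(nullm, 1, sd)
  obs_n <- as.integer(obs)
  # counts are integers: a null sd below half a count is under-resolved,
  # so the sd is floored at 0.5 to keep rare k-mers from dominating with
  # unbounded z
  z <- (obs_n - mu) / pmax(sdv, 0.5)
  p <- (1 + rowSums(nullm >= obs_n)) / (n_shuffles + 1)
  out <- data.frame(kmer = lev, observed = obs_n, expected = mu,
                    z = z, p = p, stringsAsFactors = FALSE)
  out <- out[order(-out$z, -out$observed, out$kmer), ]
  rownames(out) <- NULL
  out
}

# ---- ARE scoring -----------------------------------------------------------

#' AU-rich-element scoring parameters
#'
#' Pentamer-plus-context parameterization of 3'UTR AU-richness: each
#' "AUUUA" occurrence (overlaps counted) scores `pentamer_point`;
#' consecutive pentamer start positions <= 10 nt apart add
#' `doublet_bonus_near`, 11-20 nt apart add `doublet_bonus_far`; pentamers
#' whose immediate neighbours on both sides exist and are A or U add
#' `au_block_bonus`.  UTRs of `min_utr_len` nt or shorter are not scored.
#'
#' @param pentamer_point,doublet_bonus_near,doublet_bonus_far,au_block_bonus
#'   non-negative point values.
#' @param min_utr_len minimum 3'UTR length (exclusive) for scoring.
#' @return list of class `AREScoreParams`.
#' @export
are_params <- function(pentamer_point = 1.0, doublet_bonus_near = 1.5,
                       doublet_bonus_far = 0.75, au_block_bonus = 0.5,
                       min_utr_len = 10) {
  p <- as.list(environment())
  if (any(unlist(p[1:4]) < 0)) stopf("bonuses must be >= 0")
  structure(p, class = "AREScoreParams")
}

#' Score AU-rich elements in an RNA sequence
#'
#' @param seq RNA string (ACGU; T accepted and transliterated).
#' @param params an [are_params()].
#' @return list of class `AREScoreResult` with `score`, `n_pentamers`,
#'   `n_near_doublets`, `n_far_doublets`, `n_au_flanked` and `scored`;
#'   sequences of length <= `min_utr_len` return `scored = FALSE` with an
#'   `NA` score (the "not scored" sentinel).
#' @export
are_score <- function(seq, params = are_params()) {
  s <- chartr("tT", "uU", seq)
  s <- toupper(s)
  if (grepl("[^ACGU]", s)) stopf("sequence alphabet must be ACGU (or ACGT)")
  n <- nchar(s)
  if (n <= params$min_utr_len)
    return(structure(list(score = NA_real_, n_pentamers = 0L,
                          n_near_doublets = 0L, n_far_doublets = 0L,
                          n_au_flanked = 0L, scored = FALSE),
                     class = "AREScoreResult"))
  starts <- if (n >= 5)
    which(substring(s, 1:(n - 4), 5:n) == "AUUUA") else integer()
  np <- length(starts)
  d <- diff(starts)
  near <- sum(d <= 10)
  far <- sum(d >= 11 & d <= 20)
  ch <- strsplit(s, "")[[1]]
  flanked <- sum(vapply(starts, function(st) {
    st > 1 && st + 5 <= n && ch[st - 1] %in% c("A", "U") &&
      ch[st + 5] %in% c("A", "U")
  }, TRUE))
  score <- params$pentamer_point * np +
    params$doublet_bonus_near * near +
    params$doublet_bonus_far * far +
    params$au_block_bonus * flanked
  structure(list(score = score, n_pentamers = np,
                 n_near_doublets = as.integer(near),
                 n_far_doublets = as.integer(far),
                 n_au_flanked = as.integer(flanked), scored = TRUE),
            class = "AREScoreResult")
}

#' @export
print.AREScoreResult <- function(x, ...) {
  if (!x$scored) cat("AREScoreResult: not scored (UTR too short)\n")
  else cat(sprintf(
    "AREScoreResult: score %.2f (%d pentamers, %d/%d near/far doublets, %d AU-flanked)\n",
    x$score, x$n_pentamers, x$n_near_doublets, x$n_far_doublets,
    x$n_au_flanked))
  invisible(x)
}

#' ARE scores per gene
#'
#' Scores the 3'UTR of every coding transcript longer than
#' `params$min_utr_len` nt and keeps, per gene, the highest-scoring
#' isoform (ties broken by lexicographically smallest transcript id).
#' Genes with no qualifying 3'UTR are absent from the result.
#'
#' @param models list of `TranscriptModel` (all isoforms).
#' @param genome a `DNAStringSet`.
#' @param params an [are_params()].
#' @return data.frame (`gene_id`, `transcript_id`, `score`, `n_pentamers`,
#'   `n_near_doublets`, `n_far_doublets`, `n_au_flanked`).
#' @export
gene_are_scores <- function(models, genome, params = are_params()) {
  rows <- lapply(models, function(tm) {
    if (is.null(tm$cds_span)) return(NULL)
    seg <- utr_cds_segments(tm)
    if (seg["utr3"] <= params$min_utr_len) return(NULL)
    mrna <- mrna_sequence(tm, genome)
    utr3 <- substr(mrna, seg["utr5"] + seg["cds"] + 1L, mrna_length(tm))
    r <- are_score(utr3, params)
    if (!r$scored) return(NULL)
    data.frame(gene_id = tm$gene_id, transcript_id = tm$transcript_id,
               score = r$score, n_pentamers = r$n_pentamers,
               n_near_doublets = r$n_near_doublets,
               n_far_doublets = r$n_far_doublets,
               n_au_flanked = r$n_au_flanked, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) return(data.frame(gene_id = character(),
                                     transcript_id = character(),
                                     score = numeric()))
  df <- df[order(df$gene_id, -df$score, df$transcript_id), ]
  df <- df[!duplicated(df$gene_id), ]
  rownames(df) <- NULL
  df
}
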
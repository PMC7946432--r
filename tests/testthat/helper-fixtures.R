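# Shared fixtures and independent oracle implementations.

# A deterministic random transcript model for property tests: 1-4 exons on
# either strand, optionally coding.
random_transcript <- function(id = "t1", gene = "g1", coding = TRUE) {
  n_ex <- sample(1:4, 1)
  widths <- sample(30:200, n_ex, replace = TRUE)
  gaps <- if (n_ex > 1) sample(20:150, n_ex - 1, replace = TRUE) else integer()
  starts <- cumsum(c(sample(0:500, 1), widths[-n_ex] + gaps))
  exons <- cbind(starts, starts + widths)
  strand <- sample(c("+", "-"), 1)
  tm0 <- editscope::transcript_model(id, gene, "chrT", strand, exons)
  L <- editscope::mrna_length(tm0)
  cds_span <- NULL
  if (coding && L >= 30) {
    # CDS occupies a central mRNA interval, mapped to its genomic span
    a <- sample(0:(L %/% 3), 1)
    b <- sample((2 * L %/% 3):(L - 1), 1)
    g <- editscope::mrna_to_genomic(tm0, c(a, b))
    cds_span <- c(min(g), max(g) + 1L)
  }
  editscope::transcript_model(id, gene, "chrT", strand, exons, cds_span)
}

# A toy genome big enough for any random_transcript.
toy_genome <- function(len = 3000, contig = "chrT", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""))
  names(g) <- contig
  g
}

# One SiteCount row.
site_row <- function(contig = "chr1", pos0 = 100L, ref = "A", strand = "+",
                     nA = 0L, nC = 0L, nG = 0L, nT = 0L, sample_id = "s") {
  data.frame(contig = contig, pos0 = as.integer(pos0), ref = ref,
             strand = strand, nA = nA, nC = nC, nG = nG, nT = nT,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

# Brute-force edit-caller reference: an explicit row-by-row loop, written
# independently of call_edits() internals.
brute_call_edits <- function(exp, ctrl, cfg) {
  out <- NULL
  for (i in seq_len(nrow(exp))) {
    r <- exp[i, ]
    sense_a <- (r$ref == "A" && r$strand %in% c("+", ".")) ||
      (r$ref == "T" && r$strand == "-")
    if (!sense_a) next
    cov <- r$nA + r$nC + r$nG + r$nT
    edited <- if (r$strand == "-") r$nC else r$nG
    if (cov < cfg$min_coverage) next
    if (cov == 0 || edited / cov < cfg$min_edit_frac) next
    j <- which(ctrl$contig == r$contig & ctrl$pos0 == r$pos0 &
                 ctrl$strand == r$strand)
    if (length(j) == 0) next
    c1 <- ctrl[j[1], ]
    ccov <- c1$nA + c1$nC + c1$nG + c1$nT
    cedited <- if (c1$strand == "-") c1$nC else c1$nG
    if (ccov < cfg$ctrl_min_coverage) next
    if (ccov > 0 && cedited / ccov > cfg$ctrl_max_alt_frac) next
    out <- rbind(out, data.frame(
      contig = r$contig, pos0 = r$pos0, strand = r$strand,
      edit_fraction = edited / cov, coverage = cov,
      stringsAsFactors = FALSE))
  }
  out
}

# Brute-force ARE scorer: character-by-character scan, no substring
# vectorization, written independently of are_score().
brute_are_score <- function(seq, params = editscope::are_params()) {
  s <- toupper(chartr("tT", "uU", seq))
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  if (n <= params$min_utr_len) return(NA_real_)
  pent <- c("A", "U", "U", "U", "A")
  starts <- integer()
  if (n >= 5) {
    for (i in 1:(n - 4)) {
      hit <- TRUE
      for (k in 0:4) if (ch[i + k] != pent[k + 1]) { hit <- FALSE; break }
      if (hit) starts <- c(starts, i)
    }
  }
  score <- params$pentamer_point * length(starts)
  if (length(starts) >= 2) {
    for (j in 2:length(starts)) {
      d <- starts[j] - starts[j - 1]
      if (d <= 10) score <- score + params$doublet_bonus_near
      else if (d <= 20) score <- score + params$doublet_bonus_far
    }
  }
  for (st in starts) {
    if (st > 1 && st + 5 <= n &&
        ch[st - 1] %in% c("A", "U") && ch[st + 5] %in% c("A", "U"))
      score <- score + params$au_block_bonus
  }
  score
}

random_rna <- function(n, au_rich = FALSE) {
  prob <- if (au_rich) c(0.35, 0.15, 0.15, 0.35) else rep(0.25, 4)
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE, prob = prob),
        collapse = "")
}

dinuc_counts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  table(paste0(ch[-length(ch)], ch[-1]))
}

edit_keys <- function(df) paste(df$contig, df$pos0, df$strand, sep = ":")
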
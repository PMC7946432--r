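test_that("edit windows are truncated at transcript ends and spliced", {
  genome <- toy_genome(2000, seed = 31)
  tm <- transcript_model("t", "g", "chrT", "+", cbind(0L, 1000L))
  idx <- build_gene_index(list(tm))
  ann <- annotate_edits(data.frame(contig = "chrT", pos0 = c(150L, 20L),
                                   strand = "+"), idx)
  w <- extract_edit_windows(ann, idx, genome, flank = 100)
  expect_equal(nchar(w$seq), c(201L, 121L))
  expect_equal(w$win_start, c(50L, 0L))
  # center base of the full window is the edited base
  center <- substr(w$seq[1], 101, 101)
  expect_equal(center,
               chartr("T", "U", substr(as.character(genome[[1]]), 151, 151)))
  expect_false(grepl("T", w$seq[1], fixed = TRUE))
})

test_that("windows across exon junctions equal the manually spliced sequence", {
  genome <- toy_genome(2000, seed = 32)
  ex <- cbind(c(100L, 400L), c(200L, 500L))
  tm <- transcript_model("t", "g", "chrT", "+", ex)
  idx <- build_gene_index(list(tm))
  gs <- as.character(genome[[1]])
  manual <- paste0(substr(gs, 101, 200), substr(gs, 401, 500))
  # edit at mRNA position 95 (5 nt before the junction), flank 20
  ann <- annotate_edits(data.frame(contig = "chrT",
                                   pos0 = mrna_to_genomic(tm, 95L),
                                   strand = "+"), idx)
  w <- extract_edit_windows(ann, idx, genome, flank = 20)
  expect_equal(w$seq, chartr("T", "U", substr(manual, 76, 116)))
  # same check on the minus strand
  tmm <- transcript_model("tm", "gm", "chrT", "-", ex)
  idxm <- build_gene_index(list(tmm))
  manual_m <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(manual)))
  annm <- annotate_edits(data.frame(contig = "chrT",
                                    pos0 = mrna_to_genomic(tmm, 95L),
                                    strand = "-"), idxm)
  wm <- extract_edit_windows(annm, idxm, genome, flank = 20)
  expect_equal(wm$seq, chartr("T", "U", substr(manual_m, 76, 116)))
  # non-exonic edits are skipped with a warning
  expect_warning(
    none <- extract_edit_windows(
      annotate_edits(data.frame(contig = "chrT", pos0 = 300L, strand = "+"),
                     idx), idx, genome),
    "skipped")
  expect_equal(nrow(none), 0)
})

test_that("dinucleotide shuffle preserves doublet composition and endpoints", {
  set.seed(41)
  for (i in 1:30) {
    s <- random_rna(sample(20:120, 1))
    sh <- editscope:::dinuc_shuffle(s)
    expect_equal(nchar(sh), nchar(s))
    expect_equal(dinuc_counts(sh), dinuc_counts(s))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
    expect_equal(substr(sh, nchar(sh), nchar(sh)),
                 substr(s, nchar(s), nchar(s)))
  }
  # shuffles do vary (not the identity permutation)
  s <- random_rna(100)
  expect_true(any(replicate(10, editscope:::dinuc_shuffle(s)) != s))
})

test_that("a planted octamer is the top-ranked k-mer", {
  set.seed(51)
  for (seed in 1:3) {
    windows <- data.frame(seq = vapply(1:50, function(i) {
      s <- random_rna(201)
      substr(s, 97, 104) <- "UAUAUAUA"
      s
    }, ""))
    enr <- kmer_enrichment(windows, k = 8, n_shuffles = 50, seed = seed)
    expect_equal(enr$kmer[1], "UAUAUAUA")
    expect_gte(enr$observed[1], 50)
    expect_lte(enr$p[1], 1 / 51 + 1e-9)
  }
})

test_that("uniform windows yield no runaway enrichment", {
  set.seed(61)
  tops <- replicate(5, {
    windows <- data.frame(seq = vapply(1:40, function(i) random_rna(150), ""))
    kmer_enrichment(windows, k = 8, n_shuffles = 40, seed = 99)$z[1]
  })
  expect_true(all(tops < 15))   # planted signal above scores z > 40
})

test_that("k-mer enrichment validates its inputs", {
  w <- data.frame(seq = replicate(10, random_rna(50)))
  expect_error(kmer_enrichment(w, n_shuffles = 0), "null model")
  expect_error(kmer_enrichment(data.frame(seq = c("ACGU", "ACGU")), k = 8),
               "shorter")
  expect_error(kmer_enrichment(w[1:3, , drop = FALSE], k = 8), "at least 5")
})

test_that("ARE scoring reproduces the worked examples", {
  r <- are_score("GGGAUUUAGGG")
  expect_equal(r$score, 1.0)
  expect_equal(r$n_pentamers, 1L)
  expect_equal(r$n_au_flanked, 0L)
  # at or below the minimum UTR length: the not-scored sentinel
  expect_false(are_score("CCCCCC")$scored)
  expect_true(is.na(are_score("CCCCCC")$score))
  expect_equal(are_score("CCCCCCCCCCCC")$score, 0)
  # overlapping pentamers + near doublet, scored with a permissive length
  # floor so the 9-mer qualifies; frozen against the brute-force oracle
  p5 <- are_params(min_utr_len = 5)
  r2 <- are_score("AUUUAUUUA", p5)
  expect_equal(r2$n_pentamers, 2L)
  expect_equal(r2$n_near_doublets, 1L)
  expect_equal(r2$score, 3.5)
  expect_equal(brute_are_score("AUUUAUUUA", p5), 3.5)
  expect_error(are_score("AXGU"), "alphabet")
})

test_that("ARE scoring matches the brute-force oracle and is T/U invariant", {
  set.seed(71)
  for (i in 1:1000) {
    s <- random_rna(sample(11:120, 1), au_rich = i %% 2 == 0)
    expect_equal(are_score(s)$score, brute_are_score(s))
    dna <- chartr("U", "T", s)
    expect_equal(are_score(dna)$score, are_score(s)$score)
  }
})

test_that("a disjoint non-flanked pentamer adds exactly one pentamer point", {
  set.seed(81)
  for (i in 1:50) {
    base <- random_rna(60)
    ext <- paste0(base, paste(rep("G", 25), collapse = ""), "GAUUUAG")
    expect_equal(are_score(ext)$score, are_score(base)$score + 1,
                 tolerance = 1e-12)
  }
})

test_that("per-gene ARE scores keep the best isoform above the length floor", {
  genome <- toy_genome(4000, seed = 91)
  gs <- as.character(genome[[1]])
  # place deterministic UTR content: isoform A utr3 has 1 pentamer,
  # isoform B has a clustered pair (higher score)
  mk_iso <- function(id, start, utr3_seq) {
    L3 <- nchar(utr3_seq)
    ex <- cbind(start, start + 60L + L3)
    substr(gs, start + 61, start + 60 + L3) <<- chartr("U", "T", utr3_seq)
    transcript_model(id, "g1", "chrT", "+", ex,
                     cds_span = c(start + 10L, start + 60L))
  }
  tA <- mk_iso("tA", 100L, "GGGAUUUAGGGGGGGG")
  tB <- mk_iso("tB", 600L, "GGAUUUAGAUUUAGGG")
  genome2 <- Biostrings::DNAStringSet(gs); names(genome2) <- "chrT"
  sc <- gene_are_scores(list(tA, tB), genome2)
  expect_equal(nrow(sc), 1)
  expect_equal(sc$transcript_id, "tB")
  expect_equal(sc$score, max(brute_are_score("GGGAUUUAGGGGGGGG"),
                             brute_are_score("GGAUUUAGAUUUAGGG")))
  # a gene whose only 3'UTR is 8 nt is absent
  short <- transcript_model("tS", "g2", "chrT", "+", cbind(2000L, 2070L),
                            cds_span = c(2010L, 2062L))
  sc2 <- gene_are_scores(list(tA, tB, short), genome2)
  expect_false("g2" %in% sc2$gene_id)
})

test_that("per-gene scores equal the brute-force max over random isoforms", {
  set.seed(95)
  genome <- toy_genome(30000, seed = 95)
  gs <- as.character(genome[[1]])
  models <- list()
  truth <- list()
  pos <- 100L
  for (g in 1:20) {
    gid <- sprintf("g%02d", g)
    best <- -Inf
    for (iso in 1:sample(1:3, 1)) {
      u3 <- sample(12:60, 1)
      L <- 60L + u3
      ex <- cbind(pos, pos + L)
      tid <- sprintf("%s.t%d", gid, iso)
      models[[tid]] <- transcript_model(tid, gid, "chrT", "+", ex,
                                        cds_span = c(pos + 10L, pos + 60L))
      utr_seq <- substr(gs, pos + 61, pos + L)
      best <- max(best, brute_are_score(utr_seq))
      pos <- pos + L + 50L
    }
    truth[[gid]] <- best
  }
  sc <- gene_are_scores(unname(models), genome)
  for (gid in sc$gene_id)
    expect_equal(sc$score[sc$gene_id == gid], truth[[gid]])
})
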
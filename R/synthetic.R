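# Seeded synthetic data: genomes, annotations, edit-bearing pileups and
# count matrices with planted ground truth.
#
# Random-number protocol (documented so draws can be replayed by an
# independent oracle): all streams use R's default Mersenne-Twister via
# set.seed().  simulate_reference() seeds once with cfg$seed and draws, per
# gene in order: strand, segment lengths, intron count/breakpoints/lengths,
# intergenic gap, then (after all gene structures) the contig sequence, then
# per target gene the motif position and the edit positions/fractions.
# simulate_tribe_pileups() seeds with cfg$seed + j for sample index j
# (experiment replicates first, control last) and draws, per gene in model
# order: coverage (all sense-A positions, genomic order), edit counts,
# then error counts for the three non-reference bases in alphabetical order.
# simulate_counts() seeds once and draws gene means, then the exonic matrix
# column by column, then the intronic matrix column by column.

#' Configuration for the synthetic reference and pileup simulator
#'
#' Defaults emulate the design of a two-replicate brain TRIBE experiment:
#' duplicate fusion-protein samples plus one control, 3'UTR-biased edit
#' placement (5'UTR/CDS/3'UTR weights from the observed 4/26.7/69.5 percent
#' regional split), AU-rich "UAUAUAUA" motifs planted in most target
#' 3'UTRs, negative-binomial coverage (mean 100, size 10) and a per-base
#' sequencing error rate of 2e-4 (Illumina reads of mean quality ~Q37).
#'
#' @param n_genes number of genes.
#' @param utr5_range,cds_range,utr3_range length ranges (nt) for the three
#'   mRNA segments.
#' @param intron_prob per-junction probability used to draw 0-2 introns.
#' @param intron_range intron length range (nt).
#' @param n_target_genes number of genes receiving planted edits.
#' @param edits_per_target planted edit sites per target gene.
#' @param edit_frac_range range of true editing fractions, in (0, 1].
#' @param region_weights unnormalized weights for planting edits in the
#'   5'UTR, CDS and 3'UTR (named numeric of length 3).
#' @param coverage_mean,coverage_size negative-binomial coverage parameters
#'   (reads per site).
#' @param error_rate per-base sequencing error probability.
#' @param motif_planting_rate fraction of target 3'UTRs receiving an exact
#'   "UAUAUAUA" element.
#' @param n_replicates number of experiment replicates (a control is always
#'   added).
#' @param seed integer seed fixing every stream.
#' @return a validated list of class `SimConfig`.
#' @export
sim_config <- function(n_genes = 60,
                       utr5_range = c(50, 150),
                       cds_range = c(300, 900),
                       utr3_range = c(150, 500),
                       intron_prob = 0.6,
                       intron_range = c(61, 200),
                       n_target_genes = 12,
                       edits_per_target = 3,
                       edit_frac_range = c(0.25, 0.8),
                       region_weights = c(utr5 = 4, cds = 26.7, utr3 = 69.5),
                       coverage_mean = 100,
                       coverage_size = 10,
                       error_rate = 2e-4,
                       motif_planting_rate = 0.8,
                       n_replicates = 2,
                       seed = 1) {
  cfg <- as.list(environment())
  if (error_rate < 0 || error_rate > 1 ||
      motif_planting_rate < 0 || motif_planting_rate > 1)
    stopf("rates must lie in [0, 1]")
  if (edit_frac_range[1] <= 0 || edit_frac_range[2] > 1)
    stopf("edit fractions must lie in (0, 1]")
  if (utr3_range[1] < nchar(ARE_MOTIF))
    stopf("utr3 range shorter than the planted motif (%d nt)",
          nchar(ARE_MOTIF))
  if (n_target_genes > n_genes) stopf("more target genes than genes")
  if (coverage_mean <= 0 || coverage_size <= 0) stopf("invalid coverage")
  structure(cfg, class = "SimConfig")
}

# The AU-rich element planted in target 3'UTRs (DNA alphabet, sense strand).
ARE_MOTIF <- "TATATATA"

runif_int <- function(n, range) {
  as.integer(floor(runif(n, range[1], range[2] + 1)))
}

#' Simulate a reference genome, annotation and planted truth
#'
#' Generates a single-contig genome carrying `n_genes` gene models (5'UTR,
#' CDS, 3'UTR; 0-2 introns) on random strands, plants an exact "UAUAUAUA"
#' element in a configurable fraction of target 3'UTRs, and plants
#' `edits_per_target` editable sense-strand adenosines per target gene at
#' region positions drawn by `region_weights`.  Deterministic under
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `genome` (`DNAStringSet`), `models` (list of
#'   `TranscriptModel`) and `truth` (planted edits, target genes, motif
#'   positions, per-gene knockdown log2 effects).
#' @export
simulate_reference <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  contig <- "chrS1"
  models <- vector("list", cfg$n_genes)
  cursor <- 200L
  gene_meta <- vector("list", cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    gid <- sprintf("g%03d", i)
    strand <- sample(c("+", "-"), 1)
    u5 <- runif_int(1, cfg$utr5_range)
    cds <- runif_int(1, cfg$cds_range)
    u3 <- runif_int(1, cfg$utr3_range)
    L <- u5 + cds + u3
    n_int <- rbinom(1, 2, cfg$intron_prob)
    brk <- sort(sample(seq_len(L - 1L), n_int))
    ilen <- runif_int(n_int, cfg$intron_range)
    # exon mRNA segments between breakpoints; genomic layout inserts introns
    seg <- cbind(c(0L, brk), c(brk, L))
    gstart <- cursor
    ex <- matrix(0L, nrow(seg), 2)
    off <- gstart
    for (k in seq_len(nrow(seg))) {
      w <- seg[k, 2] - seg[k, 1]
      ex[k, ] <- c(off, off + w)
      off <- off + w + if (k < nrow(seg)) ilen[k] else 0L
    }
    # CDS occupies mRNA [u5, u5 + cds); for '-' genes the mRNA 5' end is the
    # genomic right end, so map through a provisional model
    tm0 <- transcript_model(paste0(gid, ".t1"), gid, contig, strand, ex)
    cstart <- genomic_to_mrna_inverse_span(tm0, u5, u5 + cds - 1L)
    models[[i]] <- transcript_model(paste0(gid, ".t1"), gid, contig, strand,
                                    ex, cds_span = cstart)
    gene_meta[[i]] <- list(gene_id = gid, u5 = u5, cds = cds, u3 = u3)
    cursor <- off + runif_int(1, c(200, 500))
  }
  glen <- cursor + 200L
  seq <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)

  targets <- sort(sample(vapply(gene_meta, `[[`, "", "gene_id"),
                         cfg$n_target_genes))
  motif_df <- NULL
  edit_df <- NULL
  w <- cfg$region_weights / sum(cfg$region_weights)
  for (gid in targets) {
    i <- match(gid, vapply(gene_meta, `[[`, "", "gene_id"))
    tm <- models[[i]]
    meta <- gene_meta[[i]]
    L <- mrna_length(tm)
    motif_pos <- NULL
    if (runif(1) < cfg$motif_planting_rate) {
      # motif start, mRNA coords, fully inside the 3'UTR
      m0 <- meta$u5 + meta$cds
      start <- m0 + runif_int(1, c(0, meta$u3 - nchar(ARE_MOTIF)))
      mpos <- start:(start + nchar(ARE_MOTIF) - 1L)
      gpos <- mrna_to_genomic(tm, mpos)
      base <- strsplit(ARE_MOTIF, "")[[1]]
      if (tm$strand == "-") base <- chartr("ACGT", "TGCA", base)
      seq[gpos + 1L] <- base
      motif_pos <- start
      motif_df <- rbind(motif_df, data.frame(
        gene_id = gid, mrna_start = start, stringsAsFactors = FALSE))
    }
    # planted edits: mRNA positions outside the motif, unique
    forbidden <- if (!is.null(motif_pos))
      motif_pos:(motif_pos + nchar(ARE_MOTIF) - 1L) else integer()
    picked <- integer()
    while (length(picked) < cfg$edits_per_target) {
      reg <- sample(c("utr5", "cds", "utr3"), 1, prob = w)
      mp <- switch(reg,
                   utr5 = runif_int(1, c(0, meta$u5 - 1L)),
                   cds = meta$u5 + runif_int(1, c(0, meta$cds - 1L)),
                   utr3 = meta$u5 + meta$cds + runif_int(1, c(0, meta$u3 - 1L)))
      if (mp %in% picked || mp %in% forbidden) next
      picked <- c(picked, mp)
      f <- runif(1, cfg$edit_frac_range[1], cfg$edit_frac_range[2])
      gp <- mrna_to_genomic(tm, mp)
      seq[gp + 1L] <- if (tm$strand == "-") "T" else "A"
      edit_df <- rbind(edit_df, data.frame(
        contig = tm$contig, pos0 = gp, gene_id = gid, strand = tm$strand,
        mrna_pos = mp,
        region = c(utr5 = "5UTR", cds = "CDS", utr3 = "3UTR")[[reg]],
        true_fraction = f, stringsAsFactors = FALSE))
    }
  }
  genome <- Biostrings::DNAStringSet(paste(seq, collapse = ""))
  names(genome) <- contig
  kd <- setNames(rep(0, cfg$n_genes),
                 vapply(gene_meta, `[[`, "", "gene_id"))
  kd[targets] <- -1
  truth <- list(edits = edit_df, target_genes = targets,
                motifs = motif_df, kd_log2fc = kd)
  list(genome = genome, models = models, truth = truth)
}

# CDS genomic span for an mRNA-coordinate CDS interval [m1, m2] (inclusive).
genomic_to_mrna_inverse_span <- function(tm, m1, m2) {
  g <- mrna_to_genomic(tm, c(m1, m2))
  c(min(g), max(g) + 1L)
}

# ---- pileup simulation -----------------------------------------------------

#' Simulate TRIBE pileup tables
#'
#' For every sense-strand adenosine of every annotated gene, draws
#' negative-binomial coverage and, at planted sites with true fraction `f`,
#' a Binomial(coverage, f) edited-read count; all reads are additionally
#' subject to the per-base error rate (uniform over the three non-reference
#' bases).  The control sample carries no planted edits.  Deterministic
#' under `cfg$seed` (see the package's RNG protocol in this file's header).
#'
#' @param ref output of [simulate_reference()].
#' @param cfg the same [sim_config()].
#' @return named list of per-sample `SiteCount` data.frames (columns
#'   `contig`, `pos0`, `ref`, `strand`, `nA`, `nC`, `nG`, `nT`,
#'   `sample_id`); experiment replicates `R1..Rn`, then `control`.
#' @export
simulate_tribe_pileups <- function(ref, cfg = sim_config()) {
  stopifnot(inherits(cfg, "SimConfig"))
  samples <- c(paste0("R", seq_len(cfg$n_replicates)), "control")
  genome_chars <- strsplit(as.character(ref$genome[[1]]), "")[[1]]
  out <- list()
  for (j in seq_along(samples)) {
    set.seed(cfg$seed + j)
    is_ctrl <- samples[j] == "control"
    tabs <- vector("list", length(ref$models))
    for (gi in seq_along(ref$models)) {
      tm <- ref$models[[gi]]
      ex <- tm$exons
      gpos <- unlist(lapply(seq_len(nrow(ex)),
                            function(i) seq.int(ex[i, 1], ex[i, 2] - 1L)))
      refb <- genome_chars[gpos + 1L]
      want <- if (tm$strand == "-") "T" else "A"
      gpos <- gpos[refb == want]
      n <- length(gpos)
      if (n == 0) next
      f <- rep(0, n)
      if (!is_ctrl && !is.null(ref$truth$edits)) {
        te <- ref$truth$edits[ref$truth$edits$gene_id == tm$gene_id, ]
        f[match(te$pos0, gpos)] <- te$true_fraction
      }
      cov <- rnbinom(n, size = cfg$coverage_size, mu = cfg$coverage_mean)
      nedit <- rbinom(n, cov, f)
      rest <- cov - nedit
      ea <- cfg$error_rate / 3
      e1 <- rbinom(n, rest, ea)
      e2 <- rbinom(n, rest - e1, ea / (1 - ea))
      e3 <- rbinom(n, rest - e1 - e2, ea / (1 - 2 * ea))
      nref <- rest - e1 - e2 - e3
      if (tm$strand == "-") {
        # genomic ref T; sense A->G editing appears as genomic T->C
        nA <- e1; nC <- nedit + e2; nG <- e3; nT <- nref
      } else {
        nA <- nref; nC <- e1; nG <- nedit + e2; nT <- e3
      }
      tabs[[gi]] <- data.frame(
        contig = tm$contig, pos0 = gpos, ref = want, strand = tm$strand,
        nA = nA, nC = nC, nG = nG, nT = nT,
        sample_id = samples[j], stringsAsFactors = FALSE)
    }
    out[[samples[j]]] <- do.call(rbind, tabs)
  }
  out
}

# ---- count-matrix simulation -----------------------------------------------

#' Configuration for the count-matrix simulator
#'
#' Defaults emulate an RNAi-knockdown stability experiment in which the RBP
#' stabilizes its targets: target exonic means are halved under knockdown
#' (log2FC -1) while intronic (nascent) signal is untouched, i.e. the
#' programmed effect is purely posttranscriptional.
#'
#' @param mean_expr median per-gene expected read count (gene means are
#'   drawn log-normal around it).
#' @param sdlog log-normal spread of gene means.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   `0` switches to Poisson counts.
#' @param n_per_cond samples per condition (control / knockdown).
#' @param kd_log2fc log2 fold change applied to target genes' exonic means
#'   under knockdown (negative = destabilized without the RBP).
#' @param intron_log2fc log2 fold change applied to target genes' intronic
#'   means under knockdown (0 = no transcriptional effect).
#' @param intron_rel_mean intronic mean as a fraction of the exonic mean.
#' @param seed integer seed.
#' @return a validated list of class `CountSimConfig`.
#' @export
count_sim_config <- function(mean_expr = 300, sdlog = 1, dispersion = 0.05,
                             n_per_cond = 5, kd_log2fc = -1,
                             intron_log2fc = 0, intron_rel_mean = 0.3,
                             seed = 1) {
  cfg <- as.list(environment())
  if (mean_expr <= 0 || intron_rel_mean <= 0) stopf("means must be positive")
  if (dispersion < 0) stopf("dispersion must be >= 0")
  if (n_per_cond < 1) stopf("need at least one sample per condition")
  structure(cfg, class = "CountSimConfig")
}

rcounts <- function(n, mu, dispersion) {
  if (dispersion == 0) rpois(n, mu) else
    rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Simulate exonic and intronic count matrices
#'
#' Draws negative-binomial counts for control and knockdown conditions.
#' The knockdown effect (`cfg$kd_log2fc`) applies multiplicatively to
#' target genes' exonic means only, unless `cfg$intron_log2fc` is set,
#' in which case intronic means change too (a transcriptional effect).
#' The intronic matrix covers only genes that have introns.
#'
#' @param ref output of [simulate_reference()] (gene models define which
#'   genes have introns).
#' @param truth the `truth` element of [simulate_reference()] (supplies the
#'   target gene set).
#' @param cfg a [count_sim_config()].
#' @return list with `exonic` and `intronic` integer matrices (genes x
#'   samples), `labels` (condition per column), and `gene_means`.
#' @export
simulate_counts <- function(ref, truth, cfg = count_sim_config()) {
  stopifnot(inherits(cfg, "CountSimConfig"))
  set.seed(cfg$seed)
  gids <- vapply(ref$models, `[[`, "", "gene_id")
  ng <- length(gids)
  mu <- rlnorm(ng, meanlog = log(cfg$mean_expr), sdlog = cfg$sdlog)
  names(mu) <- gids
  is_target <- gids %in% truth$target_genes
  n <- cfg$n_per_cond
  labels <- c(rep("control", n), rep("knockdown", n))
  mu_kd <- mu * ifelse(is_target, 2^cfg$kd_log2fc, 1)
  exonic <- matrix(0L, ng, 2 * n, dimnames = list(gids, paste0(
    rep(c("ctrl", "kd"), each = n), rep(seq_len(n), 2))))
  for (s in seq_len(2 * n)) {
    m <- if (labels[s] == "control") mu else mu_kd
    exonic[, s] <- rcounts(ng, m, cfg$dispersion)
  }
  has_intron <- vapply(ref$models, function(t) nrow(t$exons) > 1, TRUE)
  mu_i <- mu[has_intron] * cfg$intron_rel_mean
  mu_i_kd <- mu_i * ifelse(is_target[has_intron], 2^cfg$intron_log2fc, 1)
  ni <- sum(has_intron)
  intronic <- matrix(0L, ni, 2 * n,
                     dimnames = list(gids[has_intron], colnames(exonic)))
  for (s in seq_len(2 * n)) {
    m <- if (labels[s] == "control") mu_i else mu_i_kd
    intronic[, s] <- rcounts(ni, m, cfg$dispersion)
  }
  list(exonic = exonic, intronic = intronic, labels = labels,
       gene_means = mu)
}

#' Write planted truth as JSON
#' @param truth the `truth` element of [simulate_reference()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
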
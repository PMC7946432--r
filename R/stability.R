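# mRNA-stability statistics: median-of-ratios normalization,
# permutation-based differential-expression classes, target-vs-background
# contingency, bootstrap resampling and Fisher's combined probability.

#' Median-of-ratios normalization
#'
#' Per-sample size factor = median, over genes with nonzero counts in every
#' sample, of that sample's count divided by the gene's geometric mean
#' across samples.  The normalized matrix is counts divided by size factors.
#'
#' @param counts integer matrix, genes x samples.
#' @return list with `size_factors` (named per sample) and `normalized`.
#' @export
median_of_ratios <- function(counts) {
  counts <- as.matrix(counts)
  ref_ok <- rowSums(counts == 0) == 0
  if (!any(ref_ok))
    stopf("cannot form reference: no gene has nonzero counts in every sample")
  lg <- log(counts[ref_ok, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(lg, 2, function(col) exp(median(col - geo)))
  normalized <- sweep(counts, 2, sf, "/")
  # by construction each column's median log-ratio to the reference
  # (per-gene geometric mean of the raw counts) is 0
  lratio <- sweep(log(normalized[ref_ok, , drop = FALSE]), 1, geo, "-")
  stopifnot(all(abs(apply(lratio, 2, median)) < 1e-8))
  list(size_factors = sf, normalized = normalized)
}

#' Permutation-based differential-expression classes
#'
#' Normalizes by [median_of_ratios()], computes per-gene log2 fold changes
#' as the difference in mean `log2(normalized + 0.5)` between the second
#' and first condition (factor level order), and assigns a two-sided
#' permutation p-value to each gene: exhaustive over all label arrangements
#' when there are at most 1000, otherwise `n_perm` Monte-Carlo draws under
#' `seed`.  Genes are classed `down` (p below `alpha` and log2FC <
#' `-lfc_null`), `up` (symmetric) or `unchanged`.
#'
#' The permutation p-value is discrete with floor `2 / C(n1+n2, n1)`;
#' with the default `alpha = 0.05` at least five samples per condition are
#' needed before any gene can leave the `unchanged` class.  `p_adjust =
#' "none"` (the default) thresholds raw p-values; `"BH"` applies
#' Benjamini-Hochberg across genes first.
#'
#' @param counts integer matrix, genes x samples.
#' @param labels condition per column (exactly two levels).
#' @param alpha significance threshold on (adjusted) p.
#' @param lfc_null optional absolute log2FC floor for the down/up classes.
#' @param p_adjust `"none"` or `"BH"`.
#' @param n_perm Monte-Carlo permutations when exhaustive enumeration
#'   exceeds 1000 arrangements.
#' @param seed seed for Monte-Carlo permutations.
#' @return data.frame (`gene`, `base_mean`, `log2fc`, `p`, `padj`,
#'   `class`).
#' @export
classify_de <- function(counts, labels, alpha = 0.05, lfc_null = 0,
                        p_adjust = c("none", "BH"), n_perm = 10000,
                        seed = 1) {
  p_adjust <- match.arg(p_adjust)
  counts <- as.matrix(counts)
  labels <- factor(labels)
  if (nlevels(labels) != 2) stopf("labels must have exactly two levels")
  if (length(labels) != ncol(counts))
    stopf("labels length must match the number of samples")
  if (any(table(labels) < 2))
    stopf("no within-condition variance: need >= 2 replicates per condition")
  mor <- median_of_ratios(counts)
  lg <- log2(mor$normalized + 0.5)
  g1 <- which(labels == levels(labels)[1])
  g2 <- which(labels == levels(labels)[2])
  n1 <- length(g1); n2 <- length(g2); nc <- ncol(lg)
  obs <- rowMeans(lg[, g2, drop = FALSE]) - rowMeans(lg[, g1, drop = FALSE])
  nboth <- choose(nc, n1)
  if (nboth <= 1000) {
    combs <- combn(nc, n1)                      # includes the observed split
  } else {
    set.seed(seed)
    combs <- cbind(g1, replicate(n_perm, sample.int(nc, n1)))
  }
  ind <- matrix(0, nc, ncol(combs))
  ind[cbind(as.vector(combs),
            rep(seq_len(ncol(combs)), each = n1))] <- 1
  s1 <- lg %*% ind                              # genes x arrangements sums
  tot <- rowSums(lg)
  stats <- (tot - s1) / n2 - s1 / n1
  p <- rowMeans(abs(stats) >= abs(obs) - 1e-12)
  padj <- if (p_adjust == "BH") stats::p.adjust(p, "BH") else p
  cls <- ifelse(padj < alpha & obs < -lfc_null, "down",
                ifelse(padj < alpha & obs > lfc_null, "up", "unchanged"))
  data.frame(gene = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             base_mean = rowMeans(mor$normalized),
             log2fc = obs, p = p, padj = padj, class = cls,
             stringsAsFactors = FALSE, row.names = NULL)
}

de_class_factor <- function(cls) factor(cls, levels = c("down", "unchanged", "up"))

#' Target-vs-background stability contingency
#'
#' Builds the 3 (down/unchanged/up) x 2 (target/background) contingency
#' table from a [classify_de()] result and tests class-by-group
#' independence with Pearson's chi-square (no continuity correction,
#' df = 2).  Cells with expected count < 5 are flagged.  Target ids absent
#' from the DE table are dropped with a warning.
#'
#' @param de a [classify_de()] result.
#' @param targets character vector of target gene ids.
#' @return list of class `StabilityContingency`: `table`, `statistic`,
#'   `df`, `p`, `low_expected`, `class_fractions` (per group).
#' @export
stability_contingency <- function(de, targets) {
  if (length(targets) == 0) stopf("empty target set")
  missing <- setdiff(targets, de$gene)
  if (length(missing) > 0) {
    warnf("%d target(s) not in the DE table; dropped", length(missing))
    targets <- setdiff(targets, missing)
    if (length(targets) == 0) stopf("no targets left after dropping")
  }
  grp <- factor(ifelse(de$gene %in% targets, "target", "background"),
                levels = c("target", "background"))
  tab <- table(de_class_factor(de$class), grp)
  # classes observed in neither group carry no information and would make
  # the Pearson statistic undefined
  test <- suppressWarnings(chisq.test(tab[rowSums(tab) > 0, , drop = FALSE],
                                      correct = FALSE))
  frac <- sweep(tab, 2, colSums(tab), "/")
  structure(list(table = tab, statistic = unname(test$statistic),
                 df = unname(test$parameter), p = test$p.value,
                 low_expected = any(test$expected < 5),
                 class_fractions = frac),
            class = "StabilityContingency")
}

#' @export
print.StabilityContingency <- function(x, ...) {
  print(x$table)
  cat(sprintf("chi-square %.3f, df %d, p %.3g%s\n", x$statistic, x$df, x$p,
              if (x$low_expected) " (cells with expected < 5)" else ""))
  invisible(x)
}

#' Bootstrap class fractions and combined significance
#'
#' Resamples the target set and the background with replacement `n_boot`
#' times; records per-class fractions per group and a chi-square p-value
#' per resample; reports 2.5/97.5-percentile confidence intervals and the
#' Fisher-combined p over resamples.  Deterministic under `seed`.
#'
#' @param de a [classify_de()] result.
#' @param targets character vector of target gene ids.
#' @param n_boot bootstrap resamples (>= 100).
#' @param seed integer seed.
#' @return list of class `StabilityBootstrap`: `ci` (class x group x
#'   bound array), `point` (observed fractions), `boot_p`, `combined_p`,
#'   `n_boot`, `seed`.
#' @export
bootstrap_class_fractions <- function(de, targets, n_boot = 1000, seed = 1) {
  if (n_boot < 100) stopf("n_boot must be >= 100")
  cls <- de_class_factor(de$class)
  is_t <- de$gene %in% targets
  tcls <- cls[is_t]; bcls <- cls[!is_t]
  if (length(tcls) == 0 || length(bcls) == 0)
    stopf("both target and background classes must be non-empty")
  set.seed(seed)
  lv <- levels(cls)
  fr <- array(NA_real_, c(n_boot, 3, 2),
              dimnames = list(NULL, lv, c("target", "background")))
  boot_p <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    tb <- tcls[sample.int(length(tcls), replace = TRUE)]
    bb <- bcls[sample.int(length(bcls), replace = TRUE)]
    fr[b, , "target"] <- as.numeric(table(tb)) / length(tb)
    fr[b, , "background"] <- as.numeric(table(bb)) / length(bb)
    tab <- cbind(target = table(tb), background = table(bb))
    boot_p[b] <- tryCatch(
      suppressWarnings(chisq.test(tab[rowSums(tab) > 0, , drop = FALSE],
                                  correct = FALSE)$p.value),
      error = function(e) NA_real_)
  }
  ci <- apply(fr, c(2, 3), quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  point <- cbind(target = as.numeric(table(tcls)) / length(tcls),
                 background = as.numeric(table(bcls)) / length(bcls))
  rownames(point) <- lv
  pv <- boot_p[!is.na(boot_p) & boot_p > 0]
  structure(list(ci = ci, point = point, boot_p = boot_p,
                 combined_p = if (length(pv)) fisher_combine(pv) else NA_real_,
                 n_boot = n_boot, seed = seed),
            class = "StabilityBootstrap")
}

#' Fisher's combined probability test
#'
#' `X = -2 * sum(log(p))` referred to a chi-square distribution with `2k`
#' degrees of freedom (exact survival function).
#'
#' @param ps numeric vector of p-values, each in (0, 1].
#' @return the combined p-value.
#' @export
fisher_combine <- function(ps) {
  if (length(ps) == 0) stopf("empty p-value list")
  if (any(!is.finite(ps)) || any(ps <= 0) || any(ps > 1))
    stopf("p-values must lie in (0, 1]")
  X <- -2 * sum(log(ps))
  pchisq(X, df = 2 * length(ps), lower.tail = FALSE)
}

#' ARE score versus expression change
#'
#' Stratified summary linking AU-richness to knockdown response:
#' (a) target vs. all-tested score distributions with a rank-sum p;
#' (b) among targets, down vs. not-down score distributions with a
#' rank-sum p, plus the Spearman correlation between score and
#' `-log2fc`.
#'
#' @param scores a [gene_are_scores()] data.frame.
#' @param de a [classify_de()] result.
#' @param targets character vector of target gene ids (>= 5 must carry
#'   scores).
#' @return list with `target_vs_all` and `down_vs_notdown` (each holding
#'   medians, n and p) and `score_change_rho`.
#' @export
are_vs_change <- function(scores, de, targets) {
  sc <- setNames(scores$score, scores$gene_id)
  tested <- intersect(de$gene, names(sc))
  t_sc <- intersect(intersect(targets, tested), names(sc))
  if (length(t_sc) < 5) stopf("fewer than 5 targets with ARE scores")
  all_scores <- sc[tested]
  target_scores <- sc[t_sc]
  degenerate_all <- length(setdiff(tested, t_sc)) == 0
  if (degenerate_all)
    warnf("targets cover all tested genes; target-vs-transcriptome comparison skipped")
  tva <- if (degenerate_all || sd(all_scores) == 0) {
    list(median_target = median(target_scores),
         median_all = median(all_scores),
         n_target = length(t_sc), n_all = length(tested), p = NA_real_)
  } else {
    w <- suppressWarnings(wilcox.test(target_scores,
                                      sc[setdiff(tested, t_sc)]))
    list(median_target = median(target_scores),
         median_all = median(all_scores),
         n_target = length(t_sc), n_all = length(tested), p = w$p.value)
  }
  dcls <- setNames(de$class, de$gene)[t_sc]
  lfc <- setNames(de$log2fc, de$gene)[t_sc]
  down <- target_scores[dcls == "down"]
  notdown <- target_scores[dcls != "down"]
  dvn <- if (length(down) >= 2 && length(notdown) >= 2 &&
             sd(target_scores) > 0) {
    w <- suppressWarnings(wilcox.test(down, notdown))
    list(median_down = median(down), median_notdown = median(notdown),
         n_down = length(down), n_notdown = length(notdown), p = w$p.value)
  } else {
    list(median_down = if (length(down)) median(down) else NA_real_,
         median_notdown = if (length(notdown)) median(notdown) else NA_real_,
         n_down = length(down), n_notdown = length(notdown), p = NA_real_)
  }
  rho <- if (sd(target_scores) > 0 && sd(lfc) > 0)
    cor(target_scores, -lfc, method = "spearman") else 0
  list(target_vs_all = tva, down_vs_notdown = dvn, score_change_rho = rho)
}
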
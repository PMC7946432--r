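test_that("median-of-ratios reproduces the hand-computed size factors", {
  m <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  mor <- median_of_ratios(m)
  # geometric means sqrt(200), sqrt(800), sqrt(1800); medians 1/sqrt(2), sqrt(2)
  expect_equal(round(unname(mor$size_factors), 4), c(0.7071, 1.4142))
  expect_equal(mor$normalized[, 1], mor$normalized[, 2])
  # identical samples: unit size factors
  m2 <- cbind(c(5, 8, 100), c(5, 8, 100), c(5, 8, 100))
  expect_equal(unname(median_of_ratios(m2)$size_factors), c(1, 1, 1))
  # a gene with a zero leaves the reference but is still normalized
  m3 <- rbind(m, c(0, 7))
  mor3 <- median_of_ratios(m3)
  expect_equal(round(unname(mor3$size_factors), 4), c(0.7071, 1.4142))
  expect_equal(nrow(mor3$normalized), 4)
  expect_equal(mor3$normalized[4, 2], 7 / mor3$size_factors[2],
               ignore_attr = TRUE)
  expect_error(median_of_ratios(rbind(c(0, 1), c(1, 0))), "reference")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(113)
  m <- matrix(rnbinom(600, mu = 150, size = 5), nrow = 100)
  m[m == 0] <- 1
  ours <- median_of_ratios(m)$size_factors
  theirs <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-10)
})

test_that("permutation DE classifies constant genes as unchanged", {
  counts <- matrix(50L, nrow = 3, ncol = 10,
                   dimnames = list(paste0("g", 1:3), NULL))
  labels <- rep(c("control", "knockdown"), each = 5)
  de <- classify_de(counts, labels)
  expect_equal(de$log2fc, rep(0, 3))
  expect_equal(de$class, rep("unchanged", 3))
  expect_error(classify_de(counts[, c(1, 2)], c("a", "b")),
               "within-condition")
  expect_error(classify_de(counts, rep("a", 10)), "two levels")
})

test_that("strong knockdown effects are detected with five replicates", {
  set.seed(117)
  ng <- 400
  targets <- paste0("g", 1:60)
  mu <- rep(500, ng)
  counts <- matrix(0L, ng, 10, dimnames = list(paste0("g", 1:ng), NULL))
  labels <- rep(c("control", "knockdown"), each = 5)
  for (s in 1:10) {
    m <- mu
    if (labels[s] == "knockdown") m[1:60] <- m[1:60] / 2
    counts[, s] <- rnbinom(ng, size = 20, mu = m)
  }
  de <- classify_de(counts, labels)
  expect_gte(mean(de$class[1:60] == "down"), 0.9)
  expect_lte(mean(de$class[61:ng] != "unchanged"), 0.1)
  # BH mode is monotone in p and never less conservative
  deb <- classify_de(counts, labels, p_adjust = "BH")
  expect_true(all(deb$padj >= deb$p - 1e-12))
  expect_true(all(diff(deb$padj[order(deb$p)]) >= -1e-12))
})

test_that("stability contingency equals the hand-computed Pearson statistic", {
  de <- data.frame(
    gene = paste0("g", 1:1000),
    class = c(rep("down", 53), rep("unchanged", 38), rep("up", 9),
              rep("down", 203), rep("unchanged", 515), rep("up", 182)),
    stringsAsFactors = FALSE)
  targets <- paste0("g", 1:100)
  res <- stability_contingency(de, targets)
  # independent Pearson chi-square computation
  tab <- unclass(res$table)
  expect_equal(unname(tab[, "target"]), c(53, 38, 9))
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi <- sum((tab - exp_tab)^2 / exp_tab)
  expect_equal(res$statistic, chi, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p, pchisq(chi, 2, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("degenerate contingencies behave sensibly", {
  de_eq <- data.frame(gene = paste0("g", 1:200),
                      class = rep(c("down", "unchanged"), 100))
  # identical class proportions in both groups -> chi-square 0, p 1
  res <- stability_contingency(de_eq, paste0("g", 1:100))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
  de_x <- data.frame(gene = paste0("g", 1:400),
                     class = c(rep("down", 200), rep("up", 200)))
  expect_lt(stability_contingency(de_x, paste0("g", 1:200))$p, 1e-10)
  expect_error(stability_contingency(de_eq, character()), "empty")
  expect_warning(stability_contingency(de_eq, c("g1", "nope")), "dropped")
})

test_that("bootstrap fractions are seeded and honest about degeneracy", {
  de <- data.frame(gene = paste0("g", 1:300),
                   class = rep("down", 300), stringsAsFactors = FALSE)
  b <- bootstrap_class_fractions(de, paste0("g", 1:50), n_boot = 100,
                                 seed = 5)
  expect_equal(unname(b$ci[, "down", "target"]), c(1, 1))
  expect_equal(unname(b$point["down", "target"]), 1)
  set.seed(9991)
  de2 <- data.frame(gene = paste0("g", 1:500),
                    class = sample(c("down", "unchanged", "up"), 500, TRUE,
                                   prob = c(0.4, 0.5, 0.1)))
  b1 <- bootstrap_class_fractions(de2, paste0("g", 1:80), seed = 7,
                                  n_boot = 200)
  b2 <- bootstrap_class_fractions(de2, paste0("g", 1:80), seed = 7,
                                  n_boot = 200)
  expect_identical(b1$ci, b2$ci)
  expect_identical(b1$combined_p, b2$combined_p)
  # CI centers sit near the point fractions
  for (cl in c("down", "unchanged")) {
    mid <- mean(b1$ci[, cl, "target"])
    expect_lt(abs(mid - b1$point[cl, "target"]), 0.1)
  }
  expect_error(bootstrap_class_fractions(de2, "g1", n_boot = 10), "n_boot")
})

test_that("Fisher combination matches the closed form", {
  # df = 4 closed form: exp(-X/2) * (1 + X/2)
  X <- -2 * sum(log(c(0.05, 0.05)))
  expect_equal(fisher_combine(c(0.05, 0.05)), exp(-X / 2) * (1 + X / 2),
               tolerance = 1e-12)
  expect_lt(abs(fisher_combine(c(0.05, 0.05)) - 0.0175), 1e-3)
  expect_equal(fisher_combine(c(1, 1)), 1)
  expect_equal(fisher_combine(0.0421), 0.0421, tolerance = 1e-12)
  expect_error(fisher_combine(numeric()), "empty")
  expect_error(fisher_combine(c(0.5, 0)), "p-values")
  expect_error(fisher_combine(c(0.5, 1.2)), "p-values")
})

test_that("ARE stratification links high scores to downregulation", {
  set.seed(131)
  ng <- 600
  genes <- paste0("g", 1:ng)
  targets <- genes[1:100]
  # targets with high ARE scores are the destabilized ones
  score <- c(runif(50, 4, 9), runif(50, 0, 1.5), runif(ng - 100, 0, 1.5))
  scores <- data.frame(gene_id = genes, transcript_id = paste0(genes, ".t"),
                       score = score)
  de <- data.frame(gene = genes,
                   class = c(rep("down", 50), rep("unchanged", ng - 50)),
                   log2fc = c(runif(50, -2, -0.5), runif(ng - 50, -0.2, 0.2)))
  res <- are_vs_change(scores, de, targets)
  expect_lt(res$target_vs_all$p, 0.05)
  expect_gt(res$down_vs_notdown$median_down,
            res$down_vs_notdown$median_notdown)
  expect_lt(res$down_vs_notdown$p, 0.05)
  expect_gt(res$score_change_rho, 0.3)
  # constant scores: uninformative comparison, zero correlation
  const <- data.frame(gene_id = genes, transcript_id = paste0(genes, ".t"),
                      score = 1)
  resc <- are_vs_change(const, de, targets)
  expect_true(is.na(resc$down_vs_notdown$p))
  expect_equal(resc$score_change_rho, 0)
  # targets covering every tested gene: degenerate, warned and skipped
  expect_warning(resa <- are_vs_change(scores, de, genes), "skipped")
  expect_true(is.na(resa$target_vs_all$p))
  expect_error(are_vs_change(scores[1:3, ], de, targets), "fewer than 5")
})
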
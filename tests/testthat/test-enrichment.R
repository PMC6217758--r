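make_annot <- function() {
  genes <- data.frame(chrom = "1", start = 10000L, end = 20000L,
                      name = "GENE1", strand = "+", stringsAsFactors = FALSE)
  islands <- data.frame(chrom = "1", start = 50000L, end = 51000L,
                        stringsAsFactors = FALSE)
  list(genes = genes, islands = islands)
}

test_that("island/shore/shelf/open-sea boundaries resolve inclusively", {
  an <- make_annot()
  probes <- data.frame(id = paste0("p", 1:5), chrom = "1",
                       pos = c(50500L, 53000L, 54000L, 55000L, 61000L),
                       stringsAsFactors = FALSE)
  out <- annotate_probes(probes, an$genes, an$islands)
  expect_equal(out$island_relation,
               c("island",      # inside the interval
                 "shore",       # 2,000 bp from the edge, inclusive
                 "shelf",       # 3,000 bp: between 2,000 and 4,000
                 "shelf",       # exactly 4,000 bp, inclusive
                 "open_sea"))   # 10,000 bp away
  # one base beyond the 4,000 bp shelf boundary is open sea
  b <- annotate_probes(data.frame(id = c("x", "y"), chrom = "1",
                                  pos = c(55000L, 55001L)),
                       an$genes, an$islands)
  expect_equal(b$island_relation, c("shelf", "open_sea"))
})

test_that("gene assignment uses body or 1,500 bp upstream of the TSS", {
  an <- make_annot()
  probes <- data.frame(id = paste0("p", 1:5), chrom = "1",
                       pos = c(15000L, 8500L, 8499L, 9900L, 30000L),
                       stringsAsFactors = FALSE)
  out <- annotate_probes(probes, an$genes, an$islands)
  expect_equal(out$gene, c("GENE1", "GENE1", NA, "GENE1", NA))
  expect_equal(out$feature,
               c("Body", "TSS1500", "intergenic", "TSS200", "intergenic"))
})

test_that("upstream follows the annotated strand", {
  genes <- data.frame(chrom = "1", start = 10000L, end = 20000L,
                      name = "NEG", strand = "-", stringsAsFactors = FALSE)
  islands <- data.frame(chrom = "2", start = 1L, end = 2L,
                        stringsAsFactors = FALSE)
  out <- annotate_probes(data.frame(id = c("a", "b"), chrom = "1",
                                    pos = c(21500L, 8500L)),
                         genes, islands)
  # on the minus strand the TSS is the interval end: 21,500 is upstream
  expect_equal(out$gene, c("NEG", NA))
})

test_that("annotation is idempotent and total", {
  an <- make_annot()
  set.seed(80)
  probes <- data.frame(id = paste0("p", 1:50), chrom = "1",
                       pos = sample.int(100000L, 50), stringsAsFactors = FALSE)
  a1 <- annotate_probes(probes, an$genes, an$islands)
  a2 <- annotate_probes(a1, an$genes, an$islands)
  expect_identical(a1$island_relation, a2$island_relation)
  expect_true(all(a1$island_relation %in%
                    c("island", "shore", "shelf", "open_sea")))
  expect_true(all(xor(is.na(a1$gene), a1$feature != "intergenic")))
})

test_that("chi-square distribution test matches the direct formula", {
  same <- rbind(c(30, 70), c(30, 70))
  r <- chisq_distribution_test(same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  tab <- rbind(c(10, 90), c(90, 10))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  oracle <- sum((tab - e)^2 / e)
  r2 <- chisq_distribution_test(tab)
  expect_equal(r2$statistic, oracle, tolerance = 1e-12)
  expect_equal(r2$df, 1)
})

test_that("chi-square p is calibrated under resampling from the margins", {
  set.seed(81)
  cat_p <- c(0.2, 0.3, 0.5)
  background <- rmultinom(1, 5000, cat_p)[, 1]
  ps <- replicate(400, {
    sub <- rmultinom(1, 300, cat_p)[, 1]
    chisq_distribution_test(rbind(sub, background))$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Fisher odds ratio and p match enumeration", {
  r <- fisher_or(rbind(c(5, 5), c(5, 5)))
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p, 1)
  # full hypergeometric enumeration at fixed margins
  tab <- rbind(c(8, 2), c(1, 9))
  pr <- dhyper(0:10, 10, 10, 9)          # a can be 0..9 with these margins
  obs <- dhyper(8, 10, 10, 9)
  oracle <- sum(pr[pr <= obs * (1 + 1e-7)])
  r2 <- fisher_or(tab)
  expect_equal(r2$p, oracle, tolerance = 1e-10)
  expect_equal(r2$odds_ratio, (8 * 9) / (2 * 1))
  # maximally unbalanced: two-sided p is twice the observed table
  r3 <- fisher_or(rbind(c(0, 10), c(10, 0)))
  expect_equal(r3$p, 2 * dhyper(0, 10, 10, 10), tolerance = 1e-12)
})

test_that("Fisher p is invariant under joint row and column swaps", {
  tab <- rbind(c(12, 3), c(7, 20))
  swapped <- tab[2:1, 2:1]
  expect_equal(fisher_or(tab)$p, fisher_or(swapped)$p, tolerance = 1e-12)
  expect_equal(fisher_or(tab)$odds_ratio, fisher_or(swapped)$odds_ratio)
})

test_that("a zero margin is flagged as degenerate", {
  r <- fisher_or(rbind(c(0, 0), c(5, 5)))
  expect_true(is.na(r$odds_ratio))
  expect_equal(r$p, 1)
  expect_true(attr(r, "degenerate"))
})

test_that("the sign test reproduces exact binomial tails", {
  expect_equal(sign_test(1, 2)$p, 1.0)
  expect_equal(sign_test(8, 10)$p, 112 / 1024, tolerance = 1e-12)
  # extreme tail preserved through log space
  r <- sign_test(516, 519)
  expect_equal(signif(r$p, 3), 2.72e-149)
  expect_equal(r$log10_p, log10(r$p), tolerance = 1e-10)
})

test_that("the sign test is symmetric and monotone in imbalance", {
  for (n in c(10, 25, 519)) {
    for (k in c(0, 3, floor(n / 2))) {
      expect_equal(sign_test(k, n)$log10_p, sign_test(n - k, n)$log10_p,
                   tolerance = 1e-12)
    }
  }
  p_seq <- vapply(10:0, function(k) sign_test(k, 20)$p, numeric(1))
  expect_true(all(diff(p_seq) <= 1e-12))
})

test_that("Mann-Whitney matches exact enumeration on small samples", {
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)                  # 2 / choose(6, 3)
  expect_equal(r$method, "exact")
  expect_equal(r$U, 0)
})

test_that("Mann-Whitney handles ties and large shifted samples", {
  r <- mann_whitney(c(1, 1, 2), c(1, 2, 2))
  expect_true(r$p <= 1 && r$p > 0.05)
  set.seed(82)
  big <- mann_whitney(rnorm(200), rnorm(200) + 3)
  expect_lt(big$p, 1e-10)
  expect_equal(big$method, "normal")
  tied <- mann_whitney(rep(1, 5), rep(1, 7))
  expect_equal(tied$p, 1)
  expect_true(attr(tied, "all_tied"))
})

test_that("stratified reporting splits probes by cis/trans status", {
  rec <- data.frame(probe = c("a", "a", "b", "c"),
                    cis = c(TRUE, TRUE, FALSE, TRUE),
                    stringsAsFactors = FALSE)
  probes <- data.frame(id = c("a", "b", "c", "d"), chrom = "1",
                       pos = 1:4, stringsAsFactors = FALSE)
  score <- c(a = 0.9, b = 0.1, c = 0.5, d = 0.3)
  out <- stratify_by_score(rec, probes, score)
  expect_equal(sum(out$n), 4L)
  hi <- out[out$bin == "(0.8,1]", ]
  expect_equal(hi$cis_only, 1)
})
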
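test_that("VCF genotypes become effect-allele dosages with missing propagation", {
  path <- tempfile(fileext = ".vcf")
  write_toy_vcf(path, matrix(c("0/0", "0/1", "1/1",
                               "./.", "0|1", "1/1"), nrow = 2, byrow = TRUE))
  gm <- read_vcf_lite(path)
  expect_equal(unname(gm$dosages[, 1]), c(0, 1, 2))
  expect_equal(unname(gm$dosages[, 2]), c(NA, 1, 2))
  expect_equal(gm$variants$missing_frac, c(0, 1 / 3))
  expect_equal(gm$variants$allele_effect, c("G", "G"))  # ALT counted
})

test_that("duplicate variant IDs in a VCF are an error naming the ID", {
  path <- tempfile(fileext = ".vcf")
  write_toy_vcf(path, matrix(c("0/0", "0/1", "1/1",
                               "0/0", "0/0", "0/1"), nrow = 2, byrow = TRUE),
                ids = c("1:100", "1:100"))
  expect_error(read_vcf_lite(path), "1:100")
})

test_that("multiallelic records are rejected with their record number", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1",
               "1\t200\trs2\tA\tG,T\t.\tPASS\t.\tGT\t0/1"), path)
  expect_error(read_vcf_lite(path), "2")
})

test_that(".ma records carry stat = b/se and reject invalid rows", {
  path <- tempfile(fileext = ".ma")
  writeLines(c("SNP A1 A2 freq b se p n",
               "rs1 A G 0.3 0.12 0.04 0.0027 5000",
               "rs2 A G 0.2 0.05 -1 0.5 5000",
               "rs3 A G 0.2 0.05 0.01 1.5 5000"), path)
  expect_message(rec <- read_ma(path), "2 row")
  expect_equal(nrow(rec), 1)
  expect_equal(rec$stat, 3.0)
  expect_equal(attr(rec, "n_rejected"), 2L)
})

test_that("missing frequencies are imputed from a reference table", {
  path <- tempfile(fileext = ".ma")
  writeLines(c("SNP A1 A2 freq b se p n",
               "rs1 A G NA 0.1 0.05 0.04 1000",
               "rs2 A G 0.25 0.1 0.05 0.04 1000"), path)
  ref <- data.frame(SNP = "rs1", freq = 0.42)
  rec <- read_ma(path, freq_ref = ref)
  expect_equal(rec$freq, c(0.42, 0.25))
})

test_that("an empty .ma file yields an empty record set with a warning", {
  path <- tempfile(fileext = ".ma")
  writeLines(character(), path)
  expect_warning(rec <- read_ma(path), "empty")
  expect_equal(nrow(rec), 0)
})

test_that("write_assoc_table filters strictly and orders deterministically", {
  rec <- data.frame(
    probe = "cg1", probe_chr = "1", probe_pos = 500L,
    snp = c("s3", "s1", "s2", "s5", "s4"), snp_chr = "1",
    snp_pos = c(30L, 10L, 20L, 50L, 40L),
    a1 = "A", a2 = "G", freq = 0.3, b = 0.01, se = 0.001, stat = 10,
    p = c(1e-9, 1e-12, 1e-9, 0.5, 1e-20), n = 100L, cis = TRUE,
    distance = 100L, effect_pp = 1, stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  n <- write_assoc_table(rec, path, threshold = 1e-8)
  expect_equal(n, 4)
  back <- read_assoc_table(path)
  # p ascending; the 1e-9 tie broken by position (s2 before s3)
  expect_equal(back$snp, c("s4", "s1", "s2", "s3"))
  # threshold 1.0 keeps every row
  expect_equal(write_assoc_table(rec, path, threshold = 1), 5)
})

test_that("association tables round-trip bit-identically on the written form", {
  rec <- data.frame(
    probe = c("cg1", "cg2"), probe_chr = "1", probe_pos = c(500L, 900L),
    snp = c("s1", "s2"), snp_chr = "1", snp_pos = c(10L, 20L),
    a1 = "A", a2 = "G", freq = c(1 / 3, 0.25), b = c(0.0123456789, -2e-5),
    se = c(0.001, 3e-6), stat = c(12.3456789, -6.6666667),
    p = c(1.23456789e-30, 2.5e-11), n = 100L, cis = c(TRUE, FALSE),
    distance = c(490L, NA), effect_pp = c(1.23456789, -0.002),
    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_assoc_table(rec, path)
  once <- read_assoc_table(path)
  path2 <- tempfile(fileext = ".tsv")
  write_assoc_table(once, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that(".ma output from the GWAS generator parses losslessly", {
  cfg <- sim_config(n_samples = 100, n_blocks = 2, snps_per_block = 10,
                    n_cpgs = 10, gwas_n = 200, seed = 5)
  gm <- simulate_genotypes(cfg)
  truth <- data.frame(probe = "cg1", causal_snp = gm$variants$id[3],
                      b_true_pp = 5, cis = TRUE, stringsAsFactors = FALSE)
  gw <- simulate_outcome_summary(gm, truth, cfg)
  path <- tempfile(fileext = ".ma")
  write_ma(gw$records, path)
  back <- read_ma(path)
  expect_equal(nrow(back), nrow(gw$records))
  expect_equal(back$b, as.numeric(sprintf("%.5e", gw$records$b)))
  expect_equal(back$snp, gw$records$snp)
})

test_that("sample alignment restricts to the ID intersection and reports drops", {
  gm <- toy_genotypes(matrix(rbinom(40, 2, 0.4), nrow = 10))
  tm <- trait_matrix(matrix(runif(8 * 2), nrow = 8),
                     data.frame(id = c("cg1", "cg2"), chrom = "1",
                                pos = c(100L, 200L), stringsAsFactors = FALSE),
                     sample_ids = gm$sample_ids[2:9])
  al <- align_samples(gm, tm, quiet = TRUE)
  expect_equal(al$genotypes$sample_ids, gm$sample_ids[2:9])
  expect_equal(unname(al$n_dropped["genotypes"]), 2L)
  expect_equal(rownames(al$traits$values), al$genotypes$sample_ids)
})

test_that("container invariants are enforced", {
  expect_error(trait_matrix(matrix(c(0.5, 1.2), ncol = 1),
                            data.frame(id = "cg1", chrom = "1", pos = 1L)),
               "\\[0, 1\\]")
  v <- data.frame(id = c("a", "a"), chrom = "1", pos = c(1L, 2L),
                  allele_effect = "A", allele_other = "G",
                  stringsAsFactors = FALSE)
  expect_error(genotype_matrix(matrix(0, 2, 2), v), "duplicate")
})

test_that("BED intervals convert to 1-based closed coordinates on read", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("1\t999\t2000\tisland1\t0\t+",
               "2\t0\t100\tisland2\t0\t-"), path)
  bed <- read_bed(path)
  expect_equal(bed$start, c(1000L, 1L))
  expect_equal(bed$end, c(2000L, 100L))
  expect_equal(bed$name, c("island1", "island2"))
  expect_equal(bed$strand, c("+", "-"))
})
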
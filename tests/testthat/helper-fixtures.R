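# Fixtures built in code: toy genotype panels, a minimal VCF writer, and
# single-locus replicate builders reused by unit, property and acceptance
# tests.

# deterministic toy panel: explicit dosage columns, one chromosome
toy_genotypes <- function(dosages, pos = NULL, chrom = "1") {
  m <- ncol(dosages)
  if (is.null(pos)) pos <- seq_len(m) * 10000L
  variants <- data.frame(id = paste0("s", seq_len(m)),
                         chrom = rep(chrom, length.out = m), pos = pos,
                         allele_effect = rep("A", m),
                         allele_other = rep("G", m),
                         stringsAsFactors = FALSE)
  genotype_matrix(dosages, variants)
}

write_toy_vcf <- function(path, gts, ids = NULL, chrom = NULL, pos = NULL) {
  # gts: variants x samples character matrix of GT strings
  m <- nrow(gts); ns <- ncol(gts)
  if (is.null(ids)) ids <- paste0("rs", seq_len(m))
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  lines <- c("##fileformat=VCFv4.2",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", paste0("SAMP", seq_len(ns))),
                   collapse = "\t"))
  for (i in seq_len(m)) {
    lines <- c(lines, paste(c(chrom[i], pos[i], ids[i], "A", "G", ".",
                              "PASS", ".", "GT", gts[i, ]), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

# one SMR/HEIDI replicate: single LD block, exposure CpG driven by one
# causal variant, outcome GWAS on an independent cohort driven by the same
# (shared = TRUE) or a linked distinct (shared = FALSE) variant
smr_replicate <- function(seed, shared = TRUE, bxy = 0.5, n_exp = 2000,
                          gwas_n = 10000, b_pp = 5, noise_sd = 0.03,
                          mc_draws = 3000) {
  cfg <- sim_config(n_samples = n_exp, n_blocks = 1, snps_per_block = 20,
                    block_decay_rho = 0.9, gwas_n = gwas_n,
                    gwas_noise_sd = 0.2, bxy = bxy, n_pleiotropic = 1,
                    seed = seed)
  gm <- simulate_genotypes(cfg)
  v <- gm$variants
  cs <- v$id[10]
  set.seed(seed + 50000)
  d <- gm$dosages[, cs]
  y <- pmin(pmax(0.5 + (b_pp / 100) * d + rnorm(n_exp, 0, noise_sd), 0), 1)
  tm <- trait_matrix(matrix(y, ncol = 1),
                     data.frame(id = "cg1", chrom = v$chrom[10],
                                pos = v$pos[10], stringsAsFactors = FALSE),
                     sample_ids = gm$sample_ids)
  sc <- mqtl_scan(gm, tm, NULL, save_threshold = 1 + 1e-9)
  out_cs <- if (shared) cs else v$id[13]
  truth <- data.frame(probe = "cg1", causal_snp = out_cs, b_true_pp = b_pp,
                      cis = TRUE, stringsAsFactors = FALSE)
  gw <- simulate_outcome_summary(gm, truth, cfg)
  iset <- select_instruments(as_ma_records(sc), gw$records, gm,
                             exposure_gate = 1e-10)
  if (is.null(iset)) return(NULL)
  s <- smr_test(iset$top$b_zx, iset$top$se_zx, iset$top$b_zy, iset$top$se_zy)
  h <- heidi_test(iset, mc_draws = mc_draws)
  list(iset = iset, smr = s, heidi = h, scan = sc, gm = gm)
}

# one colocalization replicate: two CpGs over one LD block, sharing a
# causal variant or driven by two distinct near-independent variants
coloc_replicate <- function(seed, shared = TRUE, n = 1000) {
  cfg <- sim_config(n_samples = n, n_blocks = 1, snps_per_block = 30,
                    block_decay_rho = 0.9, seed = seed)
  gm <- simulate_genotypes(cfg)
  v <- gm$variants
  set.seed(seed + 70000)
  cs1 <- v$id[15]
  cs2 <- if (shared) cs1 else v$id[sample(c(3, 27), 1)]
  mk <- function(cs) pmin(pmax(0.5 + 0.04 * gm$dosages[, cs] +
                                 rnorm(n, 0, 0.04), 0), 1)
  tm <- trait_matrix(cbind(mk(cs1), mk(cs2)),
                     data.frame(id = c("cgA", "cgB"),
                                chrom = v$chrom[c(15, 15)],
                                pos = v$pos[c(15, 16)],
                                stringsAsFactors = FALSE),
                     sample_ids = gm$sample_ids)
  sc <- mqtl_scan(gm, tm, NULL, save_threshold = 1 + 1e-9)
  a <- sc[sc$probe == "cgA", ]; b <- sc[sc$probe == "cgB", ]
  sh <- intersect(a$snp, b$snp)
  a <- a[match(sh, a$snp), ]; b <- b[match(sh, b$snp), ]
  coloc_abf(a$b, a$se^2, b$b, b$se^2)
}

# naive linear-space enumeration of the five colocalization hypotheses
coloc_enumerate <- function(l1, l2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  a1 <- exp(l1); a2 <- exp(l2)
  n <- length(a1)
  s0 <- 1
  s1 <- p1 * sum(a1)
  s2 <- p2 * sum(a2)
  s3 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    s3 <- s3 + p1 * p2 * a1[i] * a2[j]
  s4 <- p12 * sum(a1 * a2)
  s <- c(s0, s1, s2, s3, s4)
  s / sum(s)
}
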
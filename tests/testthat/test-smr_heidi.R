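test_that("the Wald-ratio statistic matches its closed form", {
  s <- smr_test(0.5, 0.05, 0.1, 0.02)
  expect_equal(s$b_xy, 0.2)
  expect_equal(s$T_smr, 100 * 25 / 125)           # z = (10, 5) -> T = 20
  expect_equal(s$p_smr, pchisq(20, 1, lower.tail = FALSE))
  expect_equal(s$se_xy, abs(s$b_xy) / sqrt(s$T_smr))
})

test_that("a null outcome gives T = 0, p = 1 and a defined SE", {
  s <- smr_test(0.5, 0.05, 0, 0.02)
  expect_equal(s$T_smr, 0)
  expect_equal(s$p_smr, 1)
  expect_equal(s$b_xy, 0)
  expect_true(is.finite(s$se_xy))
})

test_that("flipping the effect allele leaves the SMR test invariant", {
  s1 <- smr_test(0.5, 0.05, 0.1, 0.02)
  s2 <- smr_test(-0.5, 0.05, -0.1, 0.02)
  expect_equal(s1$b_xy, s2$b_xy)
  expect_equal(s1$T_smr, s2$T_smr)
  expect_equal(s1$p_smr, s2$p_smr)
})

test_that("a zero exposure effect is rejected", {
  expect_error(smr_test(0, 0.05, 0.1, 0.02), "undefined")
})

test_that("under the no-effect null p_smr is uniform", {
  set.seed(60)
  n <- 2000
  b_zx <- rnorm(n, 0.05, 0.005)
  se_zx <- rep(0.05 / 10.5, n)                    # strong instrument, z ~ 10
  se_zy <- rep(0.01, n)
  b_zy <- rnorm(n, 0, se_zy)                      # b_xy = 0
  s <- smr_test(b_zx, se_zx, b_zy, se_zy)
  ks <- suppressWarnings(stats::ks.test(s$p_smr, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("instrument selection obeys its stated rules", {
  rep <- smr_replicate(1, shared = TRUE)
  iset <- rep$iset
  expect_false(is.null(iset))
  # top is the exposure minimum among shared SNPs
  expect_equal(iset$top$p_zx, min(c(iset$top$p_zx, iset$alternates$p_zx)))
  # re-filter the returned set against the rules
  for (i in seq_len(nrow(iset$alternates))) {
    expect_lt(iset$alternates$p_zx[i], 1.57e-3)
    r2 <- ld_r2(rep$gm, iset$alternates$snp[i], iset$top$snp)
    expect_gte(r2, 0.05)
    expect_lte(r2, 0.9)
  }
  expect_lte(nrow(iset$alternates), 20)
  # no alternate pair exceeds the upper LD bound
  alt <- iset$alternates$snp
  if (length(alt) > 1) {
    for (i in 1:(length(alt) - 1)) for (j in (i + 1):length(alt))
      expect_lte(ld_r2(rep$gm, alt[i], alt[j]), 0.9 + 1e-9)
  }
})

test_that("near-duplicates of the top instrument are excluded", {
  set.seed(61)
  base <- rbinom(2000, 2, 0.4)
  flip1 <- function(x) { i <- sample(seq_along(x), 30); x[i] <- 2 - x[i]; x }
  dos <- cbind(base, base, flip1(base), rbinom(2000, 2, 0.4))
  gm <- toy_genotypes(dos)
  expect_gt(ld_r2(gm, "s1", "s2"), 0.95)
  mkrec <- function(p) data.frame(snp = paste0("s", 1:4), a1 = "A", a2 = "G",
                                  b = c(0.05, 0.05, 0.049, 0.001),
                                  se = 0.005, p = p,
                                  stringsAsFactors = FALSE)
  exposure <- mkrec(c(1e-22, 1e-21, 1e-20, 0.5))
  outcome <- mkrec(c(1e-5, 1e-5, 1e-5, 0.5))
  iset <- select_instruments(exposure, outcome, gm, exposure_gate = 1e-10)
  expect_equal(iset$top$snp, "s1")
  expect_false("s2" %in% iset$alternates$snp)     # r2 = 1 with top
})

test_that("alternates identical to the top give exact homogeneity", {
  base <- rbinom(1000, 2, 0.4)
  gm <- toy_genotypes(cbind(base, base, base, base, base))
  rec <- data.frame(snp = paste0("s", 1:5), a1 = "A", a2 = "G",
                    b = 0.05, se = 0.005, p = 1e-22,
                    stringsAsFactors = FALSE)
  out <- data.frame(snp = paste0("s", 1:5), a1 = "A", a2 = "G",
                    b = 0.02, se = 0.004, p = 1e-6,
                    stringsAsFactors = FALSE)
  iset <- select_instruments(rec, out, gm, exposure_gate = 1e-10,
                             r2_lo = 0, r2_hi = 1)
  h <- heidi_test(iset, mc_draws = 1000)
  expect_equal(h$T_heidi, 0)
  expect_equal(h$p_heidi, 1)
})

test_that("too few alternates yields SMR without HEIDI", {
  base <- rbinom(500, 2, 0.4)
  gm <- toy_genotypes(cbind(base, rbinom(500, 2, 0.4)))
  rec <- data.frame(snp = c("s1", "s2"), a1 = "A", a2 = "G",
                    b = c(0.05, 0.001), se = 0.005, p = c(1e-22, 0.6),
                    stringsAsFactors = FALSE)
  out <- rec; out$p <- c(1e-4, 0.5); out$b <- c(0.02, 0)
  iset <- select_instruments(rec, out, gm, exposure_gate = 1e-10)
  h <- heidi_test(iset)
  expect_true(is.na(h$p_heidi))
  s <- smr_test(iset$top$b_zx, iset$top$se_zx, iset$top$b_zy, iset$top$se_zy)
  expect_true(is.finite(s$p_smr))
})

test_that("HEIDI p is invariant to the ordering of alternates", {
  rep <- smr_replicate(2, shared = TRUE)
  iset <- rep$iset
  m <- nrow(iset$alternates)
  skip_if(m < 3)
  set.seed(62)
  perm <- sample(m)
  iset2 <- iset
  iset2$alternates <- iset$alternates[perm, ]
  iset2$R <- iset$R[c(1, perm + 1), c(1, perm + 1)]
  p1 <- heidi_test(iset, method = "eigen")$p_heidi
  p2 <- heidi_test(iset2, method = "eigen")$p_heidi
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("Monte Carlo HEIDI agrees with the quadratic-form evaluation", {
  set.seed(63)
  checked <- 0
  for (s in 1:20) {
    rep <- smr_replicate(s + 200, shared = s %% 2 == 0, mc_draws = 20000)
    if (is.null(rep) || is.na(rep$heidi$p_heidi)) next
    p_mc <- rep$heidi$p_heidi
    p_eig <- heidi_test(rep$iset, method = "eigen")$p_heidi
    mc_se <- sqrt(max(p_eig * (1 - p_eig), 1e-6) / 20000)
    expect_lt(abs(p_mc - p_eig), 3 * mc_se + 2e-3)
    checked <- checked + 1
  }
  expect_gte(checked, 10)
})

test_that("two linked distinct causal variants are flagged as heterogeneous", {
  ps <- vapply(1:20, function(s) {
    r <- smr_replicate(s + 400, shared = FALSE)
    if (is.null(r)) NA_real_ else r$heidi$p_heidi
  }, numeric(1))
  expect_lt(median(ps, na.rm = TRUE), 0.05)
})

test_that("the trait design applies its gates and thresholds", {
  cfg <- sim_config(n_samples = 400, n_blocks = 8, snps_per_block = 20,
                    n_cpgs = 60, n_pleiotropic = 5, gwas_n = 8000, seed = 70)
  st <- simulate_study(cfg)
  sc <- mqtl_scan(st$genotypes, st$methylation, st$covariates,
                  save_threshold = 1 + 1e-9)
  set.seed(71)
  res <- run_smr_design(sc, st$gwas$records, st$genotypes, design = "trait",
                        mc_draws = 2000)
  expect_equal(attr(res, "smr_threshold"),
               0.05 / attr(res, "n_tested"))
  expect_true(all(res$pass_smr == (res$p_smr < attr(res, "smr_threshold"))))
  expect_true(all(res$pleiotropic == (res$pass_smr & res$pass_heidi)))
  # planted pleiotropic loci are enriched among the calls
  called <- res$exposure_id[res$pass_smr]
  expect_gt(mean(st$gwas$pleiotropy$probe %in% called), 0.5)
})

test_that("the expression design tests CpG-gene pairs sharing a variant", {
  cfg <- sim_config(n_samples = 400, n_blocks = 8, snps_per_block = 20,
                    n_cpgs = 60, n_expression = 15, expr_n = 2000,
                    shared_causal_fraction = 0.6, seed = 72)
  st <- simulate_study(cfg)
  sc <- mqtl_scan(st$genotypes, st$methylation, st$covariates,
                  save_threshold = 1 + 1e-9)
  set.seed(73)
  res <- run_smr_design(sc, st$eqtl$records, st$genotypes,
                        design = "expression",
                        exposure_probes = st$methylation$probes,
                        outcome_probes = st$eqtl$probes, mc_draws = 2000)
  expect_gt(attr(res, "n_tested"), 0)
  expect_equal(attr(res, "smr_threshold"), 0.05 / attr(res, "n_tested"))
  # pairs built on a genuinely shared causal variant should dominate calls
  shared_expr <- st$eqtl$truth$probe[st$eqtl$truth$shared_with_cpg]
  if (any(res$pleiotropic))
    expect_gt(mean(res$outcome_id[res$pleiotropic] %in% shared_expr), 0.5)
})
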
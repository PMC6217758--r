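#' Simulation configuration
#'
#' Defaults define the study conditions the pipeline is exercised under:
#' an mQTL cohort of 1,000 samples (the scale of a typical population
#' methylation cohort) typed at LD-block-structured biallelic
#' variants (MAF >= 0.05), beta-scale methylation with planted cis
#' (<= 500 kb) and occasional trans effects whose per-allele magnitudes are
#' drawn around a mean of 3.46 percentage points (SD 3.01), confounded
#' covariates, an independent eQTL cohort, and an independent GWAS cohort
#' providing outcome summary statistics at planted pleiotropic loci.
#'
#' @param n_samples mQTL (exposure) cohort size.
#' @param n_chrom number of chromosomes the blocks are spread over.
#' @param n_blocks number of independent LD blocks.
#' @param snps_per_block variants per block.
#' @param block_decay_rho adjacent-variant haplotype correlation within a
#'   block, in \[0, 1); across blocks variants are independent.
#' @param snp_spacing base pairs between adjacent variants in a block.
#' @param block_gap base pairs between consecutive blocks.
#' @param maf_range effect-allele frequency range, within (0, 0.5\].
#' @param n_cpgs number of methylation probes.
#' @param cis_window cis definition in base pairs (<= 500 kb).
#' @param effect_fraction fraction of CpGs with a planted mQTL.
#' @param effect_mean_pp mean planted per-allele effect, percentage points.
#' @param effect_sd_pp SD of planted effects, percentage points.
#' @param trans_fraction fraction of planted effects whose causal variant
#'   lies on another chromosome.
#' @param noise_sd residual SD of methylation on the beta scale.
#' @param n_expression number of expression probes.
#' @param shared_causal_fraction fraction of expression probes whose eQTL is
#'   the same causal variant as a CpG's mQTL.
#' @param expr_n eQTL cohort size.
#' @param n_pleiotropic number of CpGs with a planted effect on the GWAS trait.
#' @param bxy true outcome effect per unit exposure at pleiotropic loci.
#' @param pleiotropy_min_pp minimum |mQTL effect| (percentage points) a CpG
#'   needs before it can be chosen as a pleiotropic locus, so planted
#'   exposure-outcome effects always sit on a usable instrument.
#' @param gwas_n GWAS cohort size.
#' @param gwas_noise_sd residual SD of the GWAS trait.
#' @param seed integer seed; fully determines every generated dataset via a
#'   fixed stream-splitting scheme (see details).
#'
#' @details Independent substreams are derived as `seed + k` for fixed small
#' offsets k (genotypes 11, covariates 12, methylation 13, expression 14,
#' eQTL cohort 15, GWAS cohort 16), wrapped below 2^31.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 1000, n_chrom = 2, n_blocks = 40,
                       snps_per_block = 50, block_decay_rho = 0.9,
                       snp_spacing = 5000, block_gap = 50000,
                       maf_range = c(0.05, 0.5), n_cpgs = 300,
                       cis_window = 500000, effect_fraction = 0.7,
                       effect_mean_pp = 3.46, effect_sd_pp = 3.01,
                       trans_fraction = 0.08, noise_sd = 0.03,
                       n_expression = 50, shared_causal_fraction = 0.5,
                       expr_n = 5000, n_pleiotropic = 10, bxy = 0.5,
                       pleiotropy_min_pp = 2.5, gwas_n = 20000,
                       gwas_noise_sd = 0.2, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_samples >= 1, n_blocks >= 1, snps_per_block >= 1, n_cpgs >= 1,
            block_decay_rho >= 0, block_decay_rho < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            trans_fraction >= 0, trans_fraction <= 1,
            effect_fraction >= 0, effect_fraction <= 1)
  class(cfg) <- "sim_config"
  cfg
}

# deterministic substream seed below 2^31
.sub_seed <- function(seed, offset) (as.integer(seed) + offset) %% 2147483587L

# layout of variants: per-block chromosome, positions and effect-allele
# frequency; a single frequency per block keeps the copying chain's
# marginals exact, so population LD is analytically known
.block_structure <- function(config) {
  blocks <- vector("list", config$n_blocks)
  chrom_of <- rep(seq_len(config$n_chrom), length.out = config$n_blocks)
  pos_cursor <- rep(1L, config$n_chrom)
  for (b in seq_len(config$n_blocks)) {
    ch <- chrom_of[b]
    start <- pos_cursor[ch]
    pos <- start + (seq_len(config$snps_per_block) - 1L) * config$snp_spacing
    pos_cursor[ch] <- pos[length(pos)] + config$block_gap
    blocks[[b]] <- list(chrom = as.character(ch), pos = pos,
                        freq = runif(1, config$maf_range[1],
                                     config$maf_range[2]),
                        rho = config$block_decay_rho)
  }
  blocks
}

# draw one cohort of dosages from a block structure: haplotype alleles
# follow a copying Markov chain within each block (allele j equals allele
# j-1 with probability rho, else a fresh Bernoulli(freq) draw), so the
# haplotype correlation between variants k apart is exactly rho^k; dosage =
# sum of two independent haplotypes, which inherits the same correlation
.draw_dosages <- function(blocks, n) {
  mats <- lapply(blocks, function(blk) {
    m <- length(blk$pos)
    hap <- function() {
      a <- matrix(0L, n, m)
      a[, 1] <- rbinom(n, 1, blk$freq)
      if (m > 1) {
        for (j in 2:m) {
          copy <- runif(n) < blk$rho
          a[, j] <- ifelse(copy, a[, j - 1], rbinom(n, 1, blk$freq))
        }
      }
      a
    }
    hap() + hap()
  })
  do.call(cbind, mats)
}

#' Simulate LD-block-structured genotypes
#'
#' Haplotypes follow a copying Markov chain within each block: each allele
#' equals its neighbour with probability `block_decay_rho`, otherwise it is
#' a fresh Bernoulli draw at the block's frequency, so the correlation
#' between variants k positions apart is exactly `block_decay_rho^k`.
#' Blocks are mutually independent; dosages are sums of two haplotypes.
#' Each block's effect-allele frequency is drawn uniformly within
#' `maf_range`.
#'
#' @param config a [sim_config()].
#' @return A [genotype_matrix()] carrying the block structure as attribute
#'   `"blocks"` (used to draw independent cohorts with the same LD law).
#' @export
simulate_genotypes <- function(config) {
  if (config$maf_range[1] <= 0)
    stop("monomorphic request: maf_range lower bound must be > 0")
  set.seed(.sub_seed(config$seed, 11L))
  blocks <- .block_structure(config)
  dos <- .draw_dosages(blocks, config$n_samples)
  chrom <- unlist(lapply(blocks, function(b) rep(b$chrom, length(b$pos))))
  pos <- unlist(lapply(blocks, function(b) b$pos))
  freq <- unlist(lapply(blocks, function(b) rep(b$freq, length(b$pos))))
  alle <- matrix(c("A", "G", "C", "T")[sample.int(4, 2 * length(pos),
                                                  replace = TRUE)],
                 ncol = 2)
  same <- alle[, 1] == alle[, 2]
  alle[same, 2] <- c(A = "G", G = "A", C = "T", T = "C")[alle[same, 1]]
  variants <- data.frame(id = paste0(chrom, ":", pos), chrom = chrom,
                         pos = as.integer(pos),
                         allele_effect = alle[, 1], allele_other = alle[, 2],
                         info = 1, stringsAsFactors = FALSE)
  variants$true_freq <- freq
  gm <- genotype_matrix(dos, variants,
                        sample_ids = sprintf("S%04d", seq_len(config$n_samples)))
  attr(gm, "blocks") <- blocks
  gm
}

# independent cohort with the same variant panel and LD law
.draw_cohort <- function(gm, n, seed, prefix) {
  blocks <- attr(gm, "blocks")
  if (is.null(blocks)) stop("genotype matrix carries no block structure")
  set.seed(seed)
  dos <- .draw_dosages(blocks, n)
  rownames(dos) <- sprintf("%s%05d", prefix, seq_len(n))
  colnames(dos) <- gm$variants$id
  dos
}

#' Simulate covariates with planted genotype confounding
#'
#' Age, sex, six cell proportions on a simplex, two binary batch indicators,
#' and the first ten genotype principal components. Cell proportions are
#' deliberately correlated with PC1 so that covariate adjustment in the scan
#' is load-bearing, not decorative.
#'
#' @param gm a [genotype_matrix()] for the same cohort.
#' @param config a [sim_config()].
#' @return data.frame keyed by `sample_id`.
#' @export
simulate_covariates <- function(gm, config) {
  set.seed(.sub_seed(config$seed, 12L))
  n <- length(gm$sample_ids)
  dos <- gm$dosages
  dos[is.na(dos)] <- matrix(colMeans(dos, na.rm = TRUE), nrow(dos),
                            ncol(dos), byrow = TRUE)[is.na(dos)]
  sds <- apply(dos, 2, sd)
  pc <- prcomp(dos[, sds > 0, drop = FALSE], center = TRUE, scale. = TRUE)
  npc <- min(10, ncol(pc$x))
  pcs <- scale(pc$x[, seq_len(npc), drop = FALSE])
  colnames(pcs) <- paste0("PC", seq_len(npc))
  cells <- c("CD8T", "CD4T", "Bcell", "NK", "Mono", "Gran")
  alpha <- c(6, 12, 4, 3, 6, 40)                  # granulocyte-dominant blood
  load <- c(0.3, -0.2, 0.15, 0, -0.1, 0.1)        # confounding with PC1
  w <- matrix(rgamma(n * 6, shape = rep(alpha, each = n)), n, 6)
  w <- w * exp(outer(pcs[, 1], load))
  props <- w / rowSums(w)
  # reference-based composition estimates carry estimation error and do not
  # sum exactly to one; this also keeps the six columns jointly identifiable
  # alongside an intercept
  props <- pmin(pmax(props + matrix(rnorm(n * 6, 0, 0.015), n, 6), 0), 1)
  colnames(props) <- cells
  cov <- data.frame(sample_id = gm$sample_ids,
                    age = round(runif(n, 28, 90)),
                    sex = rbinom(n, 1, 0.5),
                    props,
                    batch1 = rbinom(n, 1, 0.5),
                    batch2 = rbinom(n, 1, 0.5),
                    pcs,
                    stringsAsFactors = FALSE)
  rownames(cov) <- NULL
  cov
}

#' Simulate beta-scale methylation with planted mQTL effects
#'
#' Each CpG with a planted effect has value
#' `clamp01(baseline + (b/100) * dosage + covariate effects + noise)`, with
#' the per-allele effect `b` (percentage points) drawn as
#' `sign * |Normal(effect_mean_pp, effect_sd_pp)|`. The causal variant lies
#' within `cis_window` of the probe except for `trans_fraction` of effects,
#' whose causal variant is placed on another chromosome. Clamping events are
#' counted per probe (attribute `clamped_frac`).
#'
#' @param gm a [genotype_matrix()] spanning more than twice the cis window.
#' @param covariates data.frame from [simulate_covariates()] (or `NULL`).
#' @param config a [sim_config()].
#' @return list with `traits` (a beta-scale [trait_matrix()]) and `truth`
#'   (data.frame: probe, causal_snp, b_true_pp, cis).
#' @export
simulate_methylation <- function(gm, covariates, config) {
  set.seed(.sub_seed(config$seed, 13L))
  n <- length(gm$sample_ids)
  v <- gm$variants
  span <- tapply(v$pos, v$chrom, max)
  if (max(span) <= 2 * config$cis_window && length(span) < 2)
    warning("genotype panel narrower than twice the cis window; ",
            "trans placement unavailable")
  # probe positions sampled uniformly over each chromosome's typed span
  chrom <- sample(names(span), config$n_cpgs, replace = TRUE)
  pos <- as.integer(round(runif(config$n_cpgs, 1, span[chrom])))
  pid <- sprintf("cg%06d", seq_len(config$n_cpgs))
  has_eff <- seq_len(config$n_cpgs) %in%
    sample.int(config$n_cpgs, round(config$effect_fraction * config$n_cpgs))
  truth <- data.frame(probe = pid, causal_snp = NA_character_,
                      b_true_pp = 0, cis = NA, stringsAsFactors = FALSE)
  vals <- matrix(0, n, config$n_cpgs)
  baseline <- runif(config$n_cpgs, 0.2, 0.8)
  covmat <- NULL
  if (!is.null(covariates)) {
    covmat <- scale(as.matrix(covariates[match(gm$sample_ids,
                                               covariates$sample_id),
                                         setdiff(names(covariates),
                                                 "sample_id")]),
                    center = TRUE, scale = FALSE)
  }
  for (j in seq_len(config$n_cpgs)) {
    g <- 0
    if (has_eff[j]) {
      trans <- runif(1) < config$trans_fraction && length(span) > 1
      if (trans) {
        cand <- which(v$chrom != chrom[j])
      } else {
        cand <- which(v$chrom == chrom[j] &
                        abs(v$pos - pos[j]) <= config$cis_window)
      }
      if (length(cand) == 0) cand <- which(v$chrom == chrom[j])
      cs <- cand[sample.int(length(cand), 1)]
      b <- sample(c(-1, 1), 1) *
        abs(rnorm(1, config$effect_mean_pp, config$effect_sd_pp))
      truth$causal_snp[j] <- v$id[cs]
      truth$b_true_pp[j] <- b
      truth$cis[j] <- v$chrom[cs] == chrom[j] &&
        abs(v$pos[cs] - pos[j]) <= config$cis_window
      d <- gm$dosages[, cs]
      d[is.na(d)] <- mean(d, na.rm = TRUE)
      g <- (b / 100) * d
    }
    ce <- 0
    if (!is.null(covmat)) {
      gamma <- c(rnorm(1, 0, 3e-4),              # age, per year
                 rnorm(1, 0, 0.01),              # sex
                 rnorm(6, 0, 0.05),              # cell proportions
                 rnorm(2, 0, 0.005),             # batches
                 rnorm(ncol(covmat) - 10, 0, 0.002))  # genotype PCs
      ce <- drop(covmat %*% gamma)
    }
    vals[, j] <- baseline[j] + g + ce + rnorm(n, 0, config$noise_sd)
  }
  clamped <- colMeans(vals < 0 | vals > 1)
  vals <- pmin(pmax(vals, 0), 1)
  probes <- data.frame(id = pid, chrom = chrom, pos = pos,
                       stringsAsFactors = FALSE)
  tm <- trait_matrix(vals, probes, sample_ids = gm$sample_ids, scale = "beta")
  attr(tm, "clamped_frac") <- clamped
  list(traits = tm, truth = truth)
}

# marginal per-SNP OLS summary statistics of a phenotype on each dosage
# column: the GWAS/eQTL summary generator
.marginal_summary <- function(dos, y, variant_meta, snp_idx = NULL) {
  if (is.null(snp_idx)) snp_idx <- seq_len(ncol(dos))
  D <- dos[, snp_idx, drop = FALSE]
  n <- nrow(D)
  Dc <- scale(D, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  sxx <- colSums(Dc^2)
  ok <- sxx > 0
  b <- rep(NA_real_, length(snp_idx))
  se <- b
  b[ok] <- colSums(Dc[, ok, drop = FALSE] * yc) / sxx[ok]
  syy <- sum(yc^2)
  sse <- pmax(syy - b^2 * sxx, 0)
  se[ok] <- sqrt(sse[ok] / (n - 2) / sxx[ok])
  stat <- b / se
  p <- 2 * pt(-abs(stat), n - 2)
  vm <- variant_meta[snp_idx, , drop = FALSE]
  out <- data.frame(snp = vm$id, a1 = vm$allele_effect, a2 = vm$allele_other,
                    freq = colMeans(D) / 2, b = b, se = se, p = p, n = n,
                    stat = stat, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[!is.na(out$se) & out$se > 0, , drop = FALSE]
}

#' Simulate GWAS outcome summary statistics on an independent cohort
#'
#' Draws a new cohort of `gwas_n` samples from the same LD law as the
#' exposure panel (no shared samples: the two-sample design is enforced by
#' construction), builds the trait as the sum over pleiotropic loci of
#' `b_xy * (b_zx/100) * dosage` plus Gaussian noise, and returns marginal
#' per-SNP association records in `.ma`-compatible columns.
#'
#' @param gm exposure-panel [genotype_matrix()] (carries the LD law).
#' @param truth mQTL truth table from [simulate_methylation()].
#' @param config a [sim_config()]; `n_pleiotropic` cis-effect CpGs are given
#'   outcome effect `bxy`.
#' @return list with `records` (data.frame: snp, a1, a2, freq, b, se, p, n,
#'   stat), `pleiotropy` (data.frame: probe, causal_snp, b_xy) and
#'   `gwas_sample_ids`.
#' @export
simulate_outcome_summary <- function(gm, truth, config) {
  set.seed(.sub_seed(config$seed, 16L))
  cand <- which(!is.na(truth$causal_snp) & truth$cis %in% TRUE &
                  abs(truth$b_true_pp) >= config$pleiotropy_min_pp)
  # at most one pleiotropic locus per LD block, so each planted Wald ratio
  # is identified by its own marginal signal rather than a mixture of
  # correlated neighbours; loci are restricted to CpGs whose mQTL effect is
  # large enough to furnish a discovery-threshold instrument, so every
  # ledger entry is recoverable by the SMR stage it targets
  blocks <- attr(gm, "blocks")
  block_of <- rep(seq_along(blocks),
                  vapply(blocks, function(b) length(b$pos), integer(1)))
  names(block_of) <- gm$variants$id
  cand <- cand[sample.int(length(cand))]
  pick <- integer(); used <- integer()
  for (i in cand) {
    bl <- block_of[[truth$causal_snp[i]]]
    if (bl %in% used) next
    pick <- c(pick, i); used <- c(used, bl)
    if (length(pick) >= config$n_pleiotropic) break
  }
  pick <- sort(pick)
  plei <- data.frame(probe = truth$probe[pick],
                     causal_snp = truth$causal_snp[pick],
                     b_zx_pp = truth$b_true_pp[pick],
                     b_xy = rep(config$bxy, length(pick)),
                     stringsAsFactors = FALSE)
  dos <- .draw_cohort(gm, config$gwas_n, .sub_seed(config$seed, 16L), "G")
  y <- rnorm(config$gwas_n, 0, config$gwas_noise_sd)
  for (i in seq_len(nrow(plei))) {
    d <- dos[, plei$causal_snp[i]]
    y <- y + plei$b_xy[i] * (plei$b_zx_pp[i] / 100) * d
  }
  rec <- .marginal_summary(dos, y, gm$variants)
  list(records = rec, pleiotropy = plei, gwas_sample_ids = rownames(dos))
}

#' Simulate expression traits and eQTL summary statistics
#'
#' Expression probes are placed in cis of the typed panel; a configurable
#' fraction share their causal variant with a CpG's planted mQTL (the
#' ground truth consumed by the expression SMR design). eQTL summary
#' statistics come from an independent cohort of `expr_n` samples, per-SNP
#' marginal OLS within 500 kb of each probe.
#'
#' @param gm exposure-panel [genotype_matrix()].
#' @param truth mQTL truth table from [simulate_methylation()].
#' @param config a [sim_config()].
#' @return list with `records` (eQTL records, extra column `probe`),
#'   `probes` (expression probe table) and `truth` (probe, causal_snp,
#'   b_eqtl, shared_with_cpg).
#' @export
simulate_expression_summary <- function(gm, truth, config) {
  set.seed(.sub_seed(config$seed, 14L))
  v <- gm$variants
  cis_cpgs <- truth[!is.na(truth$causal_snp) & truth$cis %in% TRUE, ,
                    drop = FALSE]
  ne <- config$n_expression
  eid <- sprintf("ILMN_%05d", seq_len(ne))
  shared <- runif(ne) < config$shared_causal_fraction & nrow(cis_cpgs) > 0
  causal <- character(ne); epos <- integer(ne); echr <- character(ne)
  for (j in seq_len(ne)) {
    if (shared[j]) {
      row <- cis_cpgs[sample.int(nrow(cis_cpgs), 1), ]
      causal[j] <- row$causal_snp
    } else {
      causal[j] <- v$id[sample.int(nrow(v), 1)]
    }
    ci <- match(causal[j], v$id)
    echr[j] <- v$chrom[ci]
    epos[j] <- as.integer(pmax(1, v$pos[ci] +
                                 round(runif(1, -50000, 50000))))
  }
  b_e <- rnorm(ne, 0.6, 0.1) * sample(c(-1, 1), ne, replace = TRUE)
  dos <- .draw_cohort(gm, config$expr_n, .sub_seed(config$seed, 15L), "E")
  recs <- vector("list", ne)
  for (j in seq_len(ne)) {
    y <- b_e[j] * dos[, causal[j]] + rnorm(config$expr_n)
    idx <- which(v$chrom == echr[j] & abs(v$pos - epos[j]) <= 500000)
    r <- .marginal_summary(dos, y, v, idx)
    if (nrow(r)) r$probe <- eid[j]
    recs[[j]] <- r
  }
  probes <- data.frame(id = eid, chrom = echr, pos = epos,
                       gene = sprintf("GENE%04d", seq_len(ne)),
                       stringsAsFactors = FALSE)
  list(records = do.call(rbind, recs), probes = probes,
       truth = data.frame(probe = eid, causal_snp = causal, b_eqtl = b_e,
                          shared_with_cpg = shared, stringsAsFactors = FALSE))
}

#' Simulate a complete study with known ground truth
#'
#' Convenience wrapper: genotypes, covariates, methylation, GWAS outcome
#' summary and eQTL summary, all deterministic under `config$seed` with
#' independent substreams, with exposure, eQTL and GWAS cohorts sharing no
#' samples.
#'
#' @param config a [sim_config()].
#' @return list with elements `genotypes`, `covariates`, `methylation`
#'   (trait_matrix), `truth`, `gwas`, `eqtl`, `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  gm <- simulate_genotypes(config)
  cov <- simulate_covariates(gm, config)
  meth <- simulate_methylation(gm, cov, config)
  gwas <- simulate_outcome_summary(gm, meth$truth, config)
  eqtl <- simulate_expression_summary(gm, meth$truth, config)
  stopifnot(length(intersect(gm$sample_ids, gwas$gwas_sample_ids)) == 0)
  list(genotypes = gm, covariates = cov, methylation = meth$traits,
       truth = meth$truth, gwas = gwas, eqtl = eqtl, config = config)
}
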
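#' Two-sample SMR (Wald-ratio) test
#'
#' Single-instrument summary-data Mendelian randomization: with exposure
#' estimate `b_zx` (SE `se_zx`) and outcome estimate `b_zy` (SE `se_zy`) at
#' the same variant and effect allele, the exposure-outcome effect is the
#' Wald ratio `b_xy = b_zy / b_zx` (the 2SLS estimator in summary form).
#' The test statistic is `T = z_zx^2 * z_zy^2 / (z_zx^2 + z_zy^2)`,
#' referred to chi-square with 1 df; `se_xy = |b_xy| / sqrt(T)`.
#'
#' @param b_zx,se_zx instrument effect on the exposure and its SE.
#' @param b_zy,se_zy instrument effect on the outcome and its SE.
#' @return list with `b_xy`, `se_xy`, `T_smr`, `p_smr`.
#' @export
smr_test <- function(b_zx, se_zx, b_zy, se_zy) {
  stopifnot(all(se_zx > 0), all(se_zy > 0))
  if (any(b_zx == 0)) stop("b_zx = 0: Wald ratio undefined")
  z_zx <- b_zx / se_zx
  z_zy <- b_zy / se_zy
  T_smr <- z_zx^2 * z_zy^2 / (z_zx^2 + z_zy^2)
  b_xy <- b_zy / b_zx
  # delta-method SE where T = 0 (b_zy = 0), |b_xy|/sqrt(T) otherwise
  se_delta <- sqrt(se_zy^2 / b_zx^2 + b_zy^2 * se_zx^2 / b_zx^4)
  se_xy <- ifelse(T_smr > 0, abs(b_xy) / sqrt(T_smr), se_delta)
  list(b_xy = b_xy, se_xy = se_xy, T_smr = T_smr,
       p_smr = pchisq(T_smr, df = 1, lower.tail = FALSE))
}

#' Select the top instrument and HEIDI alternates for one exposure
#'
#' Exposure and outcome records are matched by SNP ID and allele-harmonized
#' (outcome effects flipped when the allele pair is swapped; strand
#' ambiguous and mismatched records dropped and counted). The top
#' instrument is the smallest exposure p among SNPs present in both studies
#' (ties by chrom, pos, id); alternates are SNPs with exposure
#' `p < p_gate`, r-squared with the top in \[`r2_lo`, `r2_hi`\], pruned so
#' no two alternates have r-squared > `r2_hi` (keeping the smaller exposure
#' p), and truncated to `max_snps` by exposure significance.
#'
#' @param exposure exposure records: `snp, a1, a2, b, se, p` (scan records
#'   renamed via [as_ma_records()] work directly).
#' @param outcome outcome records in the same columns.
#' @param gm [genotype_matrix()] of the exposure panel, for LD.
#' @param exposure_gate significance the top instrument must reach.
#' @param p_gate exposure significance gate for alternates
#'   (1.57e-3, i.e. z^2 > 10).
#' @param r2_lo,r2_hi LD bounds with the top instrument.
#' @param max_snps,min_snps cap and minimum on the alternate count.
#' @return object of class `instrument_set`: `top` (one-row data.frame with
#'   exposure and outcome statistics), `alternates`, signed LD matrix `R`
#'   over (top, alternates), `min_snps`; or `NULL` when no instrument
#'   passes the exposure gate.
#' @export
select_instruments <- function(exposure, outcome, gm,
                               exposure_gate = 1e-10, p_gate = 1.57e-3,
                               r2_lo = 0.05, r2_hi = 0.9,
                               max_snps = 20, min_snps = 3) {
  h <- harmonize_alleles(exposure, outcome)
  ex <- h$x; oy <- h$y
  if (nrow(ex) == 0) return(NULL)
  pos <- gm$variants$pos[match(ex$snp, gm$variants$id)]
  chm <- gm$variants$chrom[match(ex$snp, gm$variants$id)]
  ord <- order(ex$p, chm, pos, ex$snp)
  ex <- ex[ord, , drop = FALSE]; oy <- oy[ord, , drop = FALSE]
  if (ex$p[1] >= exposure_gate) return(NULL)
  top <- 1L
  cand <- which(ex$p < p_gate & seq_len(nrow(ex)) != top)
  keep <- integer()
  for (j in cand) {
    r2 <- suppressWarnings(ld_r2(gm, ex$snp[j], ex$snp[top]))
    if (is.na(r2) || r2 < r2_lo || r2 > r2_hi) next
    ok <- TRUE
    for (k in keep) {                       # pairwise pruning, smaller p first
      r2k <- suppressWarnings(ld_r2(gm, ex$snp[j], ex$snp[k]))
      if (!is.na(r2k) && r2k > r2_hi) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, j)
    if (length(keep) >= max_snps) break
  }
  ids <- ex$snp[c(top, keep)]
  R <- .ld_cor(gm, ids)
  mk <- function(i) data.frame(snp = ex$snp[i], b_zx = ex$b[i],
                               se_zx = ex$se[i], p_zx = ex$p[i],
                               b_zy = oy$b[i], se_zy = oy$se[i],
                               p_zy = oy$p[i], stringsAsFactors = FALSE)
  structure(list(top = mk(top), alternates = mk(keep), R = R,
                 min_snps = min_snps,
                 params = list(exposure_gate = exposure_gate,
                               p_gate = p_gate, r2_lo = r2_lo,
                               r2_hi = r2_hi, max_snps = max_snps)),
            class = "instrument_set")
}

# first-order covariance of Wald ratios i, j given signed LD r_ij; the
# cross-study covariance terms vanish under the two-sample design
.wald_cov <- function(b_zx_i, se_zx_i, b_zy_i, se_zy_i,
                      b_zx_j, se_zx_j, b_zy_j, se_zy_j, r_ij) {
  r_ij * se_zy_i * se_zy_j / (b_zx_i * b_zx_j) +
    r_ij * b_zy_i * b_zy_j * se_zx_i * se_zx_j / (b_zx_i^2 * b_zx_j^2)
}

#' HEIDI heterogeneity test
#'
#' Tests whether the Wald ratios at LD-linked alternative instruments agree
#' with the ratio at the top instrument. `d_i = b_xy(i) - b_xy(top)`; the
#' covariance of the `d` vector is assembled from first-order Wald-ratio
#' variances and LD-driven cross-covariances (cross-study terms vanish in
#' the two-sample design). The statistic is `T = sum (d_i / SE(d_i))^2`,
#' whose null distribution — a sum of correlated squared standard normals —
#' is evaluated by seeded Monte Carlo (default) or by numerical inversion
#' of the characteristic function of the eigenvalue-weighted chi-square
#' mixture (`method = "eigen"`, the analytic cross-check). A HEIDI p above
#' 0.05 is consistent with a single shared causal variant.
#'
#' @param iset an `instrument_set` from [select_instruments()].
#' @param mc_draws Monte Carlo draws for the null distribution.
#' @param method `"mc"` (default) or `"eigen"`.
#' @return list with `T_heidi`, `p_heidi`, `n_snps` (alternate count); when
#'   fewer than `min_snps` alternates are available, `p_heidi` is `NA`.
#' @export
heidi_test <- function(iset, mc_draws = 50000, method = c("mc", "eigen")) {
  method <- match.arg(method)
  alt <- iset$alternates
  m <- nrow(alt)
  if (m < iset$min_snps)
    return(list(T_heidi = NA_real_, p_heidi = NA_real_, n_snps = m))
  top <- iset$top
  bxy_t <- top$b_zy / top$b_zx
  bxy <- alt$b_zy / alt$b_zx
  d <- bxy - bxy_t
  # covariance over (top, alternates); index 1 = top
  all <- rbind(top[, c("b_zx", "se_zx", "b_zy", "se_zy")],
               alt[, c("b_zx", "se_zx", "b_zy", "se_zy")])
  R <- iset$R
  nm <- m + 1L
  C <- matrix(0, nm, nm)
  for (i in seq_len(nm)) for (j in i:nm) {
    C[i, j] <- C[j, i] <- .wald_cov(
      all$b_zx[i], all$se_zx[i], all$b_zy[i], all$se_zy[i],
      all$b_zx[j], all$se_zx[j], all$b_zy[j], all$se_zy[j], R[i, j])
  }
  ii <- seq_len(m) + 1L
  V <- C[ii, ii, drop = FALSE] - C[ii, 1] -
    rep(C[1, ii], each = m) + C[1, 1]
  V <- (V + t(V)) / 2
  ok <- diag(V) > 1e-30
  if (!any(ok)) return(list(T_heidi = 0, p_heidi = 1, n_snps = m))
  d <- d[ok]; V <- V[ok, ok, drop = FALSE]
  T_heidi <- sum(d^2 / diag(V))
  Rd <- stats::cov2cor(V)
  eg <- eigen(Rd, symmetric = TRUE)
  psd_flag <- FALSE
  if (min(eg$values) < -1e-8) {
    psd_flag <- TRUE
    eg$values <- pmax(eg$values, 0)
  }
  lam <- pmax(eg$values, 0)
  if (method == "eigen") {
    p <- .quadform_upper(T_heidi, lam)
  } else {
    L <- eg$vectors %*% diag(sqrt(lam), length(lam)) # MVN(0, Rd) factor
    Z <- matrix(rnorm(mc_draws * length(lam)), mc_draws) %*% t(L)
    T0 <- rowSums(Z^2)
    p <- (sum(T0 >= T_heidi) + 1) / (mc_draws + 1)
  }
  out <- list(T_heidi = T_heidi, p_heidi = min(1, p), n_snps = m)
  if (psd_flag) attr(out, "psd_projected") <- TRUE
  out
}

# upper tail of a weighted sum of independent chi-square(1) variables by
# numerical inversion of the characteristic function (Imhof's integral)
.quadform_upper <- function(q, lambda) {
  lambda <- lambda[lambda > 1e-12]
  if (length(lambda) == 0) return(1)
  f <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    val <- ifelse(u == 0, 0.5 * sum(lambda) - 0.5 * q,
                  sin(theta) / (u * rho))
    val
  }
  int <- stats::integrate(f, 0, Inf, subdivisions = 2000L,
                          rel.tol = 1e-8, stop.on.error = FALSE)
  min(1, max(0, 0.5 + int$value / pi))
}

#' Convert scan records to .ma-style association columns
#'
#' @param records scan records from [mqtl_scan()].
#' @return data.frame with columns `snp, a1, a2, freq, b, se, p, n, stat`
#'   (plus `probe` when present).
#' @export
as_ma_records <- function(records) {
  out <- data.frame(snp = records$snp, a1 = records$a1, a2 = records$a2,
                    freq = records$freq, b = records$b, se = records$se,
                    p = records$p, n = records$n, stat = records$stat,
                    stringsAsFactors = FALSE)
  if (!is.null(records$probe)) out$probe <- records$probe
  out
}

#' Run a full two-stage SMR + HEIDI design
#'
#' Trait design: each exposure probe with a cis mQTL at the discovery
#' threshold (`exposure_gate`, 1e-10) is tested against one GWAS outcome;
#' the SMR significance threshold is `alpha` Bonferroni-corrected for the
#' number of exposures tested. Expression design: each (CpG, expression
#' probe) pair is tested when the CpG passes the discovery gate, the gene
#' has an eQTL with `p < outcome_gate` (5e-8), and a common variant is
#' tested within `window` of both probes; the threshold is corrected for
#' the number of pairs tested. An association is called pleiotropic when
#' `p_smr` beats the corrected threshold and `p_heidi > 0.05`.
#'
#' @param exposure scan records (with `probe`) for the exposure; cis
#'   records are used for instrument selection when a `cis` column exists.
#' @param outcome for `design = "trait"`, one set of .ma records; for
#'   `"expression"`, eQTL records with a `probe` column.
#' @param gm exposure-panel [genotype_matrix()].
#' @param design `"trait"` or `"expression"`.
#' @param exposure_probes probe table for the exposure (id, chrom, pos);
#'   required for the expression design's shared-window gate.
#' @param outcome_probes probe table for expression outcomes.
#' @param outcome_id label used for the outcome in the trait design.
#' @param exposure_gate,outcome_gate,window,alpha design gates (see above).
#' @param heidi_alpha HEIDI pass level (pass when `p_heidi > heidi_alpha`).
#' @param mc_draws Monte Carlo draws for HEIDI.
#' @param ... passed to [select_instruments()].
#' @return data.frame of SMR results, one row per tested unit, with
#'   attributes `smr_threshold` and `n_tested`.
#' @export
run_smr_design <- function(exposure, outcome, gm,
                           design = c("trait", "expression"),
                           exposure_probes = NULL, outcome_probes = NULL,
                           outcome_id = "trait", exposure_gate = 1e-10,
                           outcome_gate = 5e-8, window = 500000,
                           alpha = 0.05, heidi_alpha = 0.05,
                           mc_draws = 50000, ...) {
  design <- match.arg(design)
  exp_rec <- if (!is.null(exposure$cis)) {
    exposure[exposure$cis %in% TRUE, , drop = FALSE]
  } else exposure
  exp_ma <- as_ma_records(exp_rec)
  by_probe <- split(exp_ma, exp_ma$probe)
  gated <- names(by_probe)[vapply(by_probe, function(r) min(r$p),
                                  numeric(1)) < exposure_gate]
  units <- list()
  if (design == "trait") {
    for (cpg in gated)
      units[[length(units) + 1L]] <- list(exposure_id = cpg,
                                          outcome_id = outcome_id,
                                          exp = by_probe[[cpg]],
                                          out = outcome)
  } else {
    stopifnot(!is.null(exposure_probes), !is.null(outcome_probes))
    out_ma <- outcome
    out_by_probe <- split(out_ma, out_ma$probe)
    e_ok <- names(out_by_probe)[vapply(out_by_probe, function(r) min(r$p),
                                       numeric(1)) < outcome_gate]
    vpos <- gm$variants
    for (cpg in gated) {
      cp <- exposure_probes[exposure_probes$id == cpg, ]
      if (nrow(cp) == 0) next
      for (ep in e_ok) {
        gp <- outcome_probes[outcome_probes$id == ep, ]
        if (nrow(gp) == 0 || gp$chrom != cp$chrom) next
        er <- by_probe[[cpg]]; gr <- out_by_probe[[ep]]
        shared <- intersect(er$snp, gr$snp)
        if (length(shared) == 0) next
        sp <- vpos[match(shared, vpos$id), ]
        inwin <- abs(sp$pos - cp$pos) <= window &
          abs(sp$pos - gp$pos) <= window
        if (!any(inwin)) next
        keepids <- shared[inwin]
        units[[length(units) + 1L]] <-
          list(exposure_id = cpg, outcome_id = ep,
               exp = er[er$snp %in% keepids, , drop = FALSE],
               out = gr[gr$snp %in% keepids, , drop = FALSE])
      }
    }
  }
  n_tested <- length(units)
  thr <- if (n_tested > 0) bonferroni_threshold(alpha, n_tested) else NA_real_
  rows <- lapply(units, function(u) {
    iset <- select_instruments(u$exp, u$out, gm,
                               exposure_gate = exposure_gate, ...)
    if (is.null(iset)) return(NULL)
    s <- smr_test(iset$top$b_zx, iset$top$se_zx,
                  iset$top$b_zy, iset$top$se_zy)
    h <- heidi_test(iset, mc_draws = mc_draws)
    data.frame(exposure_id = u$exposure_id, outcome_id = u$outcome_id,
               top_snp = iset$top$snp, b_xy = s$b_xy, se_xy = s$se_xy,
               p_smr = s$p_smr, p_heidi = h$p_heidi,
               n_heidi_snps = h$n_snps,
               pass_smr = s$p_smr < thr,
               pass_heidi = !is.na(h$p_heidi) & h$p_heidi > heidi_alpha,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(exposure_id = character(), outcome_id = character(),
               top_snp = character(), b_xy = numeric(), se_xy = numeric(),
               p_smr = numeric(), p_heidi = numeric(),
               n_heidi_snps = integer(), pass_smr = logical(),
               pass_heidi = logical(), stringsAsFactors = FALSE)
  res$pleiotropic <- res$pass_smr & res$pass_heidi
  rownames(res) <- NULL
  attr(res, "smr_threshold") <- thr
  attr(res, "n_tested") <- n_tested
  res
}
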
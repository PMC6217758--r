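#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate (e.g. genome-wide significance 5e-8,
#'   or 0.05 for SMR designs).
#' @param n_sites number of tests (sites, probes or pairs).
#' @return `alpha / n_sites`.
#' @export
bonferroni_threshold <- function(alpha, n_sites) {
  stopifnot(n_sites >= 1, alpha > 0)
  alpha / n_sites
}

#' Residualize a matrix on covariates
#'
#' Subtracts the least-squares projection of each column onto
#' \[intercept | covariates\]; with no covariates this is mean-centering.
#'
#' @param x numeric matrix (samples x traits or samples x variants).
#' @param covariates numeric matrix/data.frame of covariates (no intercept
#'   column), or `NULL` for centering only.
#' @return matrix of residuals, same dimensions as `x`.
#' @export
residualize <- function(x, covariates = NULL) {
  x <- as.matrix(x)
  if (is.null(covariates) || ncol(as.matrix(covariates)) == 0)
    return(scale(x, center = TRUE, scale = FALSE))
  Z <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    drop_cols <- colnames(Z)[qz$pivot[(qz$rank + 1):ncol(Z)]]
    stop("covariate design is rank deficient; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  qr.resid(qz, x)
}

# covariate design matrix from a covariate table (drops the key column)
.cov_design <- function(covariates) {
  if (is.null(covariates)) return(NULL)
  as.matrix(covariates[, setdiff(names(covariates), "sample_id"),
                       drop = FALSE])
}

#' Genome-wide covariate-adjusted mQTL scan
#'
#' Additive linear model per (variant, probe) pair: trait on dosage
#' (0/1/2) plus covariates. Implemented as the standard fast scan —
#' both sides residualized on the covariates, then correlation-based t
#' statistics by blocked matrix products — which is algebraically identical
#' to per-pair OLS with t on `n - k - 2` degrees of freedom (k covariates).
#' Only records with `p < save_threshold` (strict) are retained. Variants
#' with missing dosages are handled per pair by casewise deletion, with the
#' covariate projection recomputed on the complete cases.
#'
#' @param gm a [genotype_matrix()].
#' @param tm a [trait_matrix()].
#' @param covariates data.frame with `sample_id` plus numeric covariates,
#'   or `NULL`.
#' @param save_threshold strict p-value cutoff for retaining records.
#' @param cis_window cis definition in base pairs (default 500 kb).
#' @param block_size number of probes per matrix block.
#' @return data.frame of mQTL records with columns `probe, probe_chr,
#'   probe_pos, snp, snp_chr, snp_pos, a1, a2, freq, b, se, stat, p, n,
#'   cis, distance, effect_pp`; attributes `n_tests` and `n_skipped`.
#'   `effect_pp = 100 * b` is the percentage-point change in methylation
#'   per effect-allele copy. `cis` is TRUE iff same chromosome and
#'   `distance <= cis_window`.
#' @export
mqtl_scan <- function(gm, tm, covariates = NULL, save_threshold = 1e-8,
                      cis_window = 500000, block_size = 500) {
  al <- align_samples(gm, tm, covariates, quiet = TRUE)
  gm <- al$genotypes; tm <- al$traits
  X <- .cov_design(al$covariates)
  n <- length(gm$sample_ids)
  k <- if (is.null(X)) 0L else ncol(X)
  df <- n - k - 2L
  if (df < 1) stop("not enough samples for the covariate design")
  v <- gm$variants; pr <- tm$probes
  miss_any <- colSums(is.na(gm$dosages)) > 0
  Yr <- residualize(tm$values, X)
  Gr <- residualize(gm$dosages[, !miss_any, drop = FALSE], X)
  sxx <- colSums(Gr^2)
  syy <- colSums(Yr^2)
  freq_all <- colMeans(gm$dosages, na.rm = TRUE) / 2
  out <- list()
  n_tests <- 0L
  n_skipped <- 0L
  vi_complete <- which(!miss_any)
  emit <- function(vi, pj, b, se, stat, p, nn) {
    keep <- is.finite(p) & p < save_threshold
    if (!any(keep)) return(NULL)
    vi <- vi[keep]; pj <- pj[keep]
    dist <- ifelse(v$chrom[vi] == pr$chrom[pj],
                   abs(v$pos[vi] - pr$pos[pj]), NA_integer_)
    data.frame(probe = pr$id[pj], probe_chr = pr$chrom[pj],
               probe_pos = pr$pos[pj], snp = v$id[vi],
               snp_chr = v$chrom[vi], snp_pos = v$pos[vi],
               a1 = v$allele_effect[vi], a2 = v$allele_other[vi],
               freq = freq_all[vi], b = b[keep], se = se[keep],
               stat = stat[keep], p = p[keep], n = nn[keep],
               cis = !is.na(dist) & dist <= cis_window, distance = dist,
               effect_pp = 100 * b[keep], stringsAsFactors = FALSE)
  }
  # complete-dosage variants: blocked matrix path
  if (length(vi_complete)) {
    ok <- sxx > 0
    blocks <- split(seq_len(ncol(Yr)),
                    ceiling(seq_len(ncol(Yr)) / block_size))
    for (bj in blocks) {
      cp <- crossprod(Gr[, ok, drop = FALSE], Yr[, bj, drop = FALSE])
      b <- cp / sxx[ok]
      sse <- pmax(outer(rep(1, sum(ok)), syy[bj]) - b^2 * sxx[ok], 0)
      se <- sqrt(sse / df / sxx[ok])
      stat <- b / se
      p <- 2 * pt(-abs(stat), df)
      n_tests <- n_tests + length(p)
      idx <- which(p < save_threshold, arr.ind = TRUE)
      if (nrow(idx)) {
        vi <- vi_complete[which(ok)][idx[, 1]]
        pj <- bj[idx[, 2]]
        sel <- cbind(idx[, 1], idx[, 2])
        out[[length(out) + 1L]] <-
          emit(vi, pj, b[sel], se[sel], stat[sel], p[sel],
               rep(n, nrow(idx)))
      }
    }
    n_skipped <- n_skipped + sum(!ok) * ncol(Yr)
  }
  # variants with missing calls: per-variant complete-case path
  for (vi in which(miss_any)) {
    cc <- !is.na(gm$dosages[, vi])
    ncc <- sum(cc)
    if (ncc < k + 3) { n_skipped <- n_skipped + ncol(tm$values); next }
    Xcc <- if (is.null(X)) NULL else X[cc, , drop = FALSE]
    g <- residualize(matrix(gm$dosages[cc, vi], ncol = 1), Xcc)
    y <- residualize(tm$values[cc, , drop = FALSE], Xcc)
    sxx1 <- sum(g^2)
    if (sxx1 <= 0) { n_skipped <- n_skipped + ncol(y); next }
    b <- drop(crossprod(g, y)) / sxx1
    sse <- pmax(colSums(y^2) - b^2 * sxx1, 0)
    dfm <- ncc - k - 2L
    se <- sqrt(sse / dfm / sxx1)
    stat <- b / se
    p <- 2 * pt(-abs(stat), dfm)
    n_tests <- n_tests + length(p)
    res <- emit(rep(vi, length(p)), seq_along(p), b, se, stat, p,
                rep(ncc, length(p)))
    if (!is.null(res)) out[[length(out) + 1L]] <- res
  }
  res <- if (length(out)) do.call(rbind, out) else
    emit(integer(), integer(), numeric(), numeric(), numeric(), numeric(),
         integer())
  if (is.null(res))
    res <- data.frame(probe = character(), probe_chr = character(),
                      probe_pos = integer(), snp = character(),
                      snp_chr = character(), snp_pos = integer(),
                      a1 = character(), a2 = character(), freq = numeric(),
                      b = numeric(), se = numeric(), stat = numeric(),
                      p = numeric(), n = integer(), cis = logical(),
                      distance = integer(), effect_pp = numeric(),
                      stringsAsFactors = FALSE)
  ord <- order(res$probe, res$p, res$snp_chr, res$snp_pos, res$snp)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_tests") <- n_tests
  attr(res, "n_skipped") <- n_skipped
  attr(res, "df") <- df
  res
}

#' Per-pair OLS association (reference implementation)
#'
#' Fits the full linear model trait ~ dosage + covariates for a single
#' (variant, probe) pair via `lm.fit` on complete cases. Used as the
#' independent check of the matrix scan; slow but transparent.
#'
#' @param g dosage vector.
#' @param y trait vector.
#' @param X covariate matrix (no intercept) or `NULL`.
#' @return list with `b`, `se`, `stat`, `p`, `n`.
#' @export
ols_single_pair <- function(g, y, X = NULL) {
  cc <- stats::complete.cases(g, y, if (is.null(X)) rep(0, length(g)) else X)
  g <- g[cc]; y <- y[cc]
  D <- cbind(1, g, if (is.null(X)) NULL else as.matrix(X)[cc, , drop = FALSE])
  fit <- stats::lm.fit(D, y)
  dfres <- length(y) - ncol(D)
  sigma2 <- sum(fit$residuals^2) / dfres
  XtXinv <- chol2inv(chol(crossprod(D)))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  b <- fit$coefficients[["g"]]
  stat <- b / se
  list(b = b, se = se, stat = stat, p = 2 * pt(-abs(stat), dfres),
       n = length(y))
}

#' Summarize an mQTL scan
#'
#' Per-probe and per-variant association counts (median and interquartile
#' range), the cis fraction, and mean absolute percentage-point effects
#' split by cis/trans.
#'
#' @param records scan records from [mqtl_scan()].
#' @return list of summary quantities.
#' @export
summarize_scan <- function(records) {
  per_probe <- table(records$probe)
  per_snp <- table(records$snp)
  iqr3 <- function(x) {
    if (length(x) == 0) return(c(NA, NA, NA))
    unname(quantile(as.numeric(x), c(0.25, 0.5, 0.75)))
  }
  list(n_associations = nrow(records),
       n_probes = length(per_probe),
       n_snps = length(per_snp),
       per_probe_quartiles = iqr3(per_probe),
       per_snp_quartiles = iqr3(per_snp),
       cis_fraction = if (nrow(records)) mean(records$cis) else NA_real_,
       mean_abs_effect_pp_cis = mean(abs(records$effect_pp[records$cis])),
       mean_abs_effect_pp_trans = mean(abs(records$effect_pp[!records$cis])))
}
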
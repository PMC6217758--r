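#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Chi-square goodness of fit (1 df) of observed genotype counts against
#' expectations from the estimated allele frequency; an exact test
#' (conditional on allele counts, summing genotype configurations no more
#' probable than the observed one) is available as an option.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @param method `"chisq"` (default) or `"exact"`.
#' @return p-value. Monomorphic input returns 1 with attribute
#'   `monomorphic = TRUE`.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa, method = c("chisq", "exact")) {
  method <- match.arg(method)
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("no observations")
  nA <- 2 * n_AA + n_Aa
  if (nA == 0 || nA == 2 * n) {
    p <- 1
    attr(p, "monomorphic") <- TRUE
    return(p)
  }
  if (method == "chisq") {
    pA <- nA / (2 * n)
    e <- n * c(pA^2, 2 * pA * (1 - pA), (1 - pA)^2)
    chi2 <- sum((c(n_AA, n_Aa, n_aa) - e)^2 / e)
    return(pchisq(chi2, df = 1, lower.tail = FALSE))
  }
  # exact: enumerate heterozygote counts compatible with the allele counts
  n_minor <- min(nA, 2 * n - nA)
  het <- seq(n_minor %% 2, n_minor, by = 2)
  lp <- lgamma(n + 1) - lgamma((n_minor - het) / 2 + 1) - lgamma(het + 1) -
    lgamma((2 * n - n_minor - het) / 2 + 1) + het * log(2) +
    lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) - lgamma(2 * n + 1)
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  obs <- which(het == n_Aa)
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}

#' Variant-level quality-control filters
#'
#' Applies, in a fixed documented order, the post-imputation exclusions:
#' missingness > `max_missing`, minor-allele frequency < `min_maf`,
#' Hardy-Weinberg p < `hwe_p`, fewer than `min_group` observations in any
#' genotype group, and INFO < `min_info` (skipped when INFO is absent).
#' Each removal is attributed to the first failing filter.
#'
#' @param gm a [genotype_matrix()].
#' @param max_missing maximum missing-call fraction.
#' @param hwe_p HWE exclusion threshold (exclude when p < `hwe_p`).
#' @param min_maf minimum minor-allele frequency (computed from non-missing
#'   calls; exclude when MAF < `min_maf`).
#' @param min_group minimum observations per genotype group (hard calls).
#' @param min_info minimum imputation INFO score.
#' @return list: `genotypes` (filtered matrix) and `report` (data.frame of
#'   class `qc_report`: filter, parameter, tested, removed).
#' @export
filter_variants <- function(gm, max_missing = 0.05, hwe_p = 0.001,
                            min_maf = 0.05, min_group = 5, min_info = 0.8) {
  dos <- gm$dosages
  m <- ncol(dos)
  alive <- rep(TRUE, m)
  removed_by <- character(0)
  report <- data.frame(filter = character(), parameter = character(),
                       tested = integer(), removed = integer(),
                       stringsAsFactors = FALSE)
  apply_filter <- function(name, param, fail) {
    fail <- fail & alive
    report <<- rbind(report, data.frame(
      filter = name, parameter = param, tested = sum(alive),
      removed = sum(fail), stringsAsFactors = FALSE))
    alive <<- alive & !fail
  }
  miss <- colMeans(is.na(dos))
  apply_filter("missingness", paste0("> ", max_missing), miss > max_missing)
  af <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  apply_filter("maf", paste0("< ", min_maf), maf < min_maf)
  hard <- round(dos)
  cnt <- function(k) colSums(hard == k, na.rm = TRUE)
  n0 <- cnt(0); n1 <- cnt(1); n2 <- cnt(2)
  hp <- vapply(seq_len(m), function(j) {
    if (!alive[j]) return(1)
    as.numeric(hwe_test(n2[j], n1[j], n0[j]))
  }, numeric(1))
  apply_filter("hwe", paste0("p < ", hwe_p), hp < hwe_p)
  apply_filter("genotype_group", paste0("min group < ", min_group),
               pmin(n0, n1, n2) < min_group)
  info <- gm$variants$info
  info_fail <- !is.na(info) & info < min_info
  apply_filter("info", paste0("< ", min_info), info_fail)
  if (!any(alive))
    stop("all variants removed by QC; review filter configuration")
  gm$dosages <- dos[, alive, drop = FALSE]
  gm$variants <- gm$variants[alive, , drop = FALSE]
  rownames(gm$variants) <- NULL
  class(report) <- c("qc_report", "data.frame")
  list(genotypes = gm, report = report)
}

#' Probe-level exclusions
#'
#' Removes probes flagged as cross-hybridizing, having a common SNP close to
#' the CpG or single-base extension, located on a sex chromosome, or listed
#' as substandard by the array manufacturer. Probes on chromosomes X/Y are
#' removed even when the `sex_chromosome` flag was not set.
#'
#' @param tm a [trait_matrix()].
#' @return list: `traits` (filtered) and `report` (`qc_report`).
#' @export
filter_probes <- function(tm) {
  p <- tm$probes
  sexchr <- p$sex_chromosome | p$chrom %in% c("X", "Y", "chrX", "chrY", "23", "24")
  flags <- list(cross_hybridizing = p$cross_hybridizing,
                snp_proximal = p$snp_proximal,
                sex_chromosome = sexchr,
                substandard = p$substandard)
  alive <- rep(TRUE, nrow(p))
  report <- data.frame(filter = character(), parameter = character(),
                       tested = integer(), removed = integer(),
                       stringsAsFactors = FALSE)
  for (nm in names(flags)) {
    fail <- flags[[nm]] & alive
    report <- rbind(report, data.frame(filter = nm, parameter = "flag",
                                       tested = sum(alive),
                                       removed = sum(fail),
                                       stringsAsFactors = FALSE))
    alive <- alive & !fail
  }
  tm$values <- tm$values[, alive, drop = FALSE]
  tm$probes <- p[alive, , drop = FALSE]
  rownames(tm$probes) <- NULL
  class(report) <- c("qc_report", "data.frame")
  list(traits = tm, report = report)
}

#' Genotype PCA and ancestry-outlier detection
#'
#' Principal components of the standardized dosage matrix (monomorphic
#' variants dropped, missing dosages mean-imputed). Samples further than
#' `sd_cut` standard deviations from the mean on PC1 or PC2 are flagged as
#' outliers and PCs are recomputed on the remaining samples, matching the
#' two-pass convention of computing covariate PCs after outlier removal.
#'
#' @param gm a [genotype_matrix()].
#' @param n_pcs number of components to return.
#' @param sd_cut outlier cut in SD units on PC1/PC2.
#' @return list: `pcs` (data.frame sample_id + PC1..PCk, recomputed after
#'   removal), `outlier_ids`, `initial_pcs`.
#' @export
genotype_pca_outliers <- function(gm, n_pcs = 10, sd_cut = 2.0) {
  n <- length(gm$sample_ids)
  if (n <= n_pcs) stop("need more samples than requested components")
  std <- function(dos) {
    dos[is.na(dos)] <- matrix(colMeans(dos, na.rm = TRUE), nrow(dos),
                              ncol(dos), byrow = TRUE)[is.na(dos)]
    sds <- apply(dos, 2, sd)
    if (!any(sds > 0)) stop("all variants monomorphic: rank-deficient input")
    scale(dos[, sds > 0, drop = FALSE])
  }
  run_pca <- function(ids) {
    x <- std(gm$dosages[ids, , drop = FALSE])
    pc <- prcomp(x, center = FALSE, scale. = FALSE)
    k <- min(n_pcs, ncol(pc$x))
    out <- data.frame(sample_id = ids, pc$x[, seq_len(k), drop = FALSE],
                      stringsAsFactors = FALSE)
    names(out)[-1] <- paste0("PC", seq_len(k))
    rownames(out) <- NULL
    out
  }
  first <- run_pca(gm$sample_ids)
  flag <- abs(first$PC1 - mean(first$PC1)) > sd_cut * sd(first$PC1) |
    abs(first$PC2 - mean(first$PC2)) > sd_cut * sd(first$PC2)
  outliers <- first$sample_id[flag]
  keep <- setdiff(gm$sample_ids, outliers)
  if (length(keep) <= n_pcs)
    stop("too few samples remain after outlier removal")
  list(pcs = run_pca(keep), outlier_ids = outliers, initial_pcs = first)
}
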
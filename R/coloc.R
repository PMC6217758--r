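#' Wakefield log approximate Bayes factor
#'
#' For a single-SNP association with estimate `b` and variance `varb`,
#' against a `Normal(0, w_sd^2)` effect prior: with `z^2 = b^2/varb` and
#' shrinkage `r = w_sd^2 / (w_sd^2 + varb)`, the log ABF in favour of
#' association is `0.5 * log(1 - r) + 0.5 * r * z^2`.
#'
#' @param b effect estimate(s).
#' @param varb sampling variance(s), `se^2`, all > 0.
#' @param w_sd prior effect SD (0.15 for a standardized quantitative trait).
#' @return vector of log ABFs.
#' @export
log_abf <- function(b, varb, w_sd = 0.15) {
  stopifnot(all(varb > 0), w_sd > 0)
  r <- w_sd^2 / (w_sd^2 + varb)
  z2 <- b^2 / varb
  0.5 * log(1 - r) + 0.5 * r * z2
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, stable
.logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Pairwise Bayesian colocalization from summary statistics
#'
#' Enumerates posterior support for the five hypotheses H0 (no causal
#' variant for either trait), H1/H2 (one trait only), H3 (two distinct
#' causal variants) and H4 (a single shared causal variant), from per-SNP
#' approximate Bayes factors under a single-causal-variant-per-trait
#' assumption, with priors `p1`, `p2` (per-SNP association with each trait)
#' and `p12` (per-SNP shared association). All sums are carried in log
#' space; the H3 cross term `sum_{i != j}` is computed as the log-difference
#' of the full product and the matched-index term.
#'
#' @param b1,varb1 effect estimates and variances for trait 1 over the
#'   shared SNP window (allele-harmonized with trait 2).
#' @param b2,varb2 same for trait 2.
#' @param p1,p2,p12 prior probabilities (defaults 1e-4, 1e-4, 1e-5).
#' @param w_sd prior effect SD passed to [log_abf()].
#' @return object of class `coloc_result`: list with `pp` (named PP0..PP4,
#'   summing to 1), `n_snps`, and logical labels `shared_region`
#'   (PP3 + PP4 > 0.99), `shared_variant` (additionally PP4/PP3 > 1) and
#'   `convincing` (additionally PP4/PP3 > 5).
#' @export
coloc_abf <- function(b1, varb1, b2, varb2, p1 = 1e-4, p2 = 1e-4,
                      p12 = 1e-5, w_sd = 0.15) {
  stopifnot(length(b1) == length(varb1), length(b2) == length(varb2),
            length(b1) == length(b2))
  nsnp <- length(b1)
  if (nsnp < 2) stop("colocalization needs at least 2 SNPs (H3 undefined)")
  l1 <- log_abf(b1, varb1, w_sd)
  l2 <- log_abf(b2, varb2, w_sd)
  s1 <- .logsumexp(l1)
  s2 <- .logsumexp(l2)
  s12 <- .logsumexp(l1 + l2)
  L0 <- 0
  L1 <- log(p1) + s1
  L2 <- log(p2) + s2
  L3 <- log(p1) + log(p2) + .logdiffexp(s1 + s2, s12)
  L4 <- log(p12) + s12
  L <- c(L0, L1, L2, L3, L4)
  pp <- exp(L - .logsumexp(L))
  pp <- pp / sum(pp)
  names(pp) <- paste0("PP", 0:4)
  shared_region <- (pp[["PP3"]] + pp[["PP4"]]) > 0.99
  ratio <- pp[["PP4"]] / pp[["PP3"]]
  structure(list(pp = pp, n_snps = nsnp,
                 shared_region = shared_region,
                 shared_variant = shared_region && ratio > 1,
                 convincing = shared_region && ratio > 5),
            class = "coloc_result")
}

#' @method print coloc_result
#' @export
print.coloc_result <- function(x, ...) {
  cat("coloc:", x$n_snps, "SNPs; PP0..PP4 =",
      paste(sprintf("%.3g", x$pp), collapse = " "), "\n")
  cat("  shared_region:", x$shared_region,
      " shared_variant:", x$shared_variant,
      " convincing:", x$convincing, "\n")
  invisible(x)
}

#' Enumerate CpG pairs eligible for colocalization
#'
#' All unordered pairs of probes on the same chromosome within `max_sep`
#' of each other, restricted to probes with at least one association at the
#' discovery threshold. Each pair's SNP window is the intersection of the
#' two probes' +/- `snp_window` windows.
#'
#' @param probes probe table (columns `id`, `chrom`, `pos`).
#' @param records scan records used to establish eligibility.
#' @param discovery_p eligibility threshold on the probe's best p.
#' @param max_sep maximum probe separation in bp.
#' @param snp_window half-width of each probe's SNP window in bp.
#' @return data.frame: `probe1, probe2, chrom, window_start, window_end`.
#' @export
pair_windows <- function(probes, records, discovery_p = 1e-10,
                         max_sep = 250000, snp_window = 500000) {
  eligible <- unique(records$probe[records$p < discovery_p])
  pr <- probes[probes$id %in% eligible, , drop = FALSE]
  pr <- pr[order(pr$chrom, pr$pos, pr$id), , drop = FALSE]
  out <- list()
  for (ch in unique(pr$chrom)) {
    sub <- pr[pr$chrom == ch, , drop = FALSE]
    if (nrow(sub) < 2) next
    for (i in seq_len(nrow(sub) - 1)) {
      for (j in (i + 1):nrow(sub)) {
        if (abs(sub$pos[j] - sub$pos[i]) > max_sep) next
        ws <- max(sub$pos[i], sub$pos[j]) - snp_window
        we <- min(sub$pos[i], sub$pos[j]) + snp_window
        out[[length(out) + 1L]] <- data.frame(
          probe1 = sub$id[i], probe2 = sub$id[j], chrom = ch,
          window_start = max(1, ws), window_end = we,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(probe1 = character(), probe2 = character(),
                      chrom = character(), window_start = integer(),
                      window_end = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Harmonize two sets of association records to a common effect allele
#'
#' Records are matched by SNP ID; when the allele pair is swapped between
#' studies the second study's effect sign is flipped, and strand-ambiguous
#' pairs (A/T, C/G) are dropped with a count (attribute `n_ambiguous`),
#' as are allele-mismatched records (attribute `n_mismatched`).
#'
#' @param x,y data.frames with columns `snp, a1, a2, b` (plus any others).
#' @return list of the two aligned data.frames, row-matched.
#' @export
harmonize_alleles <- function(x, y) {
  shared <- intersect(x$snp, y$snp)
  x <- x[match(shared, x$snp), , drop = FALSE]
  y <- y[match(shared, y$snp), , drop = FALSE]
  ambiguous <- (toupper(x$a1) == "A" & toupper(x$a2) == "T") |
    (toupper(x$a1) == "T" & toupper(x$a2) == "A") |
    (toupper(x$a1) == "C" & toupper(x$a2) == "G") |
    (toupper(x$a1) == "G" & toupper(x$a2) == "C")
  same <- x$a1 == y$a1 & x$a2 == y$a2
  swap <- x$a1 == y$a2 & x$a2 == y$a1
  keep <- !ambiguous & (same | swap)
  n_mism <- sum(!ambiguous & !(same | swap))
  x2 <- x[keep, , drop = FALSE]
  y2 <- y[keep, , drop = FALSE]
  flip <- swap[keep]
  y2$b[flip] <- -y2$b[flip]
  if (!is.null(y2$stat)) y2$stat[flip] <- -y2$stat[flip]
  if (!is.null(y2$freq)) y2$freq[flip] <- 1 - y2$freq[flip]
  tmp <- y2$a1[flip]; y2$a1[flip] <- y2$a2[flip]; y2$a2[flip] <- tmp
  out <- list(x = x2, y = y2)
  attr(out, "n_ambiguous") <- sum(ambiguous)
  attr(out, "n_mismatched") <- n_mism
  out
}

#' Run colocalization over eligible CpG pairs of a scan
#'
#' For each pair from [pair_windows()], both probes' full association
#' statistics over the shared SNP window are aligned by SNP ID (a single
#' scan shares one allele coding, so no flipping is needed) and passed to
#' [coloc_abf()].
#'
#' @param full_records scan records saved at threshold 1 (all statistics)
#'   for the eligible probes.
#' @param pairs output of [pair_windows()].
#' @param min_snps minimum shared SNPs per pair.
#' @param ... passed to [coloc_abf()].
#' @return data.frame: pair columns, `n_snps`, `PP0..PP4`, labels.
#' @export
coloc_scan_pairs <- function(full_records, pairs, min_snps = 2, ...) {
  split_rec <- split(full_records, full_records$probe)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    r1 <- split_rec[[pairs$probe1[i]]]
    r2 <- split_rec[[pairs$probe2[i]]]
    if (is.null(r1) || is.null(r2)) return(NULL)
    win <- function(r) r[r$snp_chr == pairs$chrom[i] &
                           r$snp_pos >= pairs$window_start[i] &
                           r$snp_pos <= pairs$window_end[i], , drop = FALSE]
    r1 <- win(r1); r2 <- win(r2)
    shared <- intersect(r1$snp, r2$snp)
    if (length(shared) < min_snps) return(NULL)
    r1 <- r1[match(shared, r1$snp), ]
    r2 <- r2[match(shared, r2$snp), ]
    cr <- coloc_abf(r1$b, r1$se^2, r2$b, r2$se^2, ...)
    data.frame(probe1 = pairs$probe1[i], probe2 = pairs$probe2[i],
               chrom = pairs$chrom[i], n_snps = cr$n_snps,
               PP0 = cr$pp[1], PP1 = cr$pp[2], PP2 = cr$pp[3],
               PP3 = cr$pp[4], PP4 = cr$pp[5],
               shared_region = cr$shared_region,
               shared_variant = cr$shared_variant,
               convincing = cr$convincing, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(probe1 = character(), probe2 = character(),
                      chrom = character(), n_snps = integer(),
                      PP0 = numeric(), PP1 = numeric(), PP2 = numeric(),
                      PP3 = numeric(), PP4 = numeric(),
                      shared_region = logical(), shared_variant = logical(),
                      convincing = logical(), stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
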
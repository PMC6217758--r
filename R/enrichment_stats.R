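#' Annotate probes to genes, genic features, and CpG-island context
#'
#' A probe is annotated to a gene when it lies within the gene body or at
#' most 1,500 bp upstream of the transcription start site (upstream is 5'
#' of the TSS on the annotated strand; the 1,500 bp boundary is inclusive).
#' The genic feature is `TSS200` (within 200 bp upstream of the TSS),
#' `TSS1500` (201-1,500 bp upstream), `Body` (inside the gene), or
#' `intergenic`. Island context is `island` (within an island interval),
#' `shore` (up to 2,000 bp from an island edge, inclusive), `shelf`
#' (2,000-4,000 bp, 4,000 inclusive), or `open_sea`. Boundary positions
#' resolve toward the nearer-to-feature class.
#'
#' @param probes data.frame with `id`, `chrom`, `pos`.
#' @param genes data.frame of gene intervals: `chrom, start, end, name,
#'   strand` (1-based closed; see [read_bed()]).
#' @param islands data.frame of CpG-island intervals: `chrom, start, end`.
#' @return `probes` with columns `gene`, `feature`, `island_relation`
#'   replaced/added.
#' @export
annotate_probes <- function(probes, genes, islands) {
  gene <- rep(NA_character_, nrow(probes))
  feature <- rep("intergenic", nrow(probes))
  island_relation <- rep("open_sea", nrow(probes))
  for (i in seq_len(nrow(probes))) {
    pos <- probes$pos[i]; ch <- probes$chrom[i]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g)) {
      inside <- pos >= g$start & pos <= g$end
      minus <- g$strand == "-"
      tss <- ifelse(minus, g$end, g$start)
      updist <- ifelse(minus, pos - tss, tss - pos)   # >0 when upstream
      ups <- updist >= 1 & updist <= 1500
      hit <- which(inside | ups)
      if (length(hit)) {
        # prefer body hits, then nearest TSS
        hit <- hit[order(!inside[hit], abs(pos - tss[hit]))]
        h <- hit[1]
        gene[i] <- if (!is.null(g$name)) g$name[h] else
          paste0(ch, ":", g$start[h], "-", g$end[h])
        feature[i] <- if (inside[h]) "Body" else
          if (updist[h] <= 200) "TSS200" else "TSS1500"
      }
    }
    isl <- islands[islands$chrom == ch, , drop = FALSE]
    if (nrow(isl)) {
      d <- pmax(0, pmax(isl$start - pos, pos - isl$end))
      dm <- min(d)
      island_relation[i] <- if (dm == 0) "island" else
        if (dm <= 2000) "shore" else if (dm <= 4000) "shelf" else "open_sea"
    }
  }
  probes$gene <- gene
  probes$feature <- feature
  probes$island_relation <- island_relation
  probes
}

#' Chi-square test for different annotation distributions
#'
#' Pearson chi-square on a 2 x k contingency table (k - 1 df), comparing the
#' category distribution of a subset of sites against a comparison set.
#'
#' @param tab 2 x k matrix of counts (rows: groups; columns: categories).
#' @return list with `statistic`, `df`, `p`.
#' @export
chisq_distribution_test <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == 2, ncol(tab) >= 2, all(tab >= 0))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stop("expected count of zero; merge categories")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Fisher's exact test with cross-product odds ratio
#'
#' Two-sided exact p by hypergeometric enumeration (tables no more probable
#' than the observed one, at fixed margins); the reported odds-ratio point
#' estimate is the sample cross-product ratio `(a*d)/(b*c)`, not the
#' conditional MLE.
#'
#' @param tab 2 x 2 count matrix.
#' @return list with `odds_ratio`, `p`; a zero margin yields `OR = NA`,
#'   `p = 1` and attribute `degenerate = TRUE`.
#' @export
fisher_or <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    out <- list(odds_ratio = NA_real_, p = 1)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  p <- stats::fisher.test(tab)$p.value
  list(odds_ratio = or, p = min(1, p))
}

#' Exact two-sided sign test
#'
#' Binomial test at rate 1/2: `p = min(1, 2 * min(P(X <= k), P(X >= k)))`,
#' evaluated in log space so that p-values far below the double-precision
#' floor remain representable through their log10.
#'
#' @param k number of successes (e.g. concordant pairs).
#' @param n number of trials.
#' @return list with `p` (linear scale; 0 when below the double floor) and
#'   `log10_p`.
#' @export
sign_test <- function(k, n) {
  stopifnot(k >= 0, n >= k)
  lo <- pbinom(k, n, 0.5, log.p = TRUE)
  hi <- pbinom(k - 1, n, 0.5, lower.tail = FALSE, log.p = TRUE)
  lp <- min(0, log(2) + min(lo, hi))
  list(p = exp(lp), log10_p = lp / log(10))
}

#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration over all group assignments when the smaller sample has
#' at most `exact_max` observations (handles ties by enumerating the actual
#' rank sums); otherwise the normal approximation with tie correction.
#'
#' @param x,y numeric samples.
#' @param exact_max largest minimum-group size for exact enumeration.
#' @return list with `U`, `p`, `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 8) {
  stopifnot(length(x) > 0, length(y) > 0)
  n1 <- length(x); n2 <- length(y)
  all_v <- c(x, y)
  if (length(unique(all_v)) == 1) {
    out <- list(U = n1 * n2 / 2, p = 1, method = "degenerate")
    attr(out, "all_tied") <- TRUE
    return(out)
  }
  rk <- rank(all_v)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (min(n1, n2) <= exact_max && choose(n1 + n2, n1) <= 5e5) {
    combs <- utils::combn(n1 + n2, n1)
    Us <- colSums(matrix(rk[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    tol <- 1e-9
    p <- min(1, 2 * min(mean(Us <= U + tol), mean(Us >= U - tol)))
    return(list(U = U, p = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  ties <- table(all_v)
  nn <- n1 + n2
  sig2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
  z <- (U - mu) / sqrt(sig2)
  list(U = U, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

#' Stratified association report by an external per-probe scalar
#'
#' Groups probes into bins of an external score (e.g. twin heritability)
#' and tabulates, per bin, the fraction of probes with at least one
#' significant association, split by cis only / trans only / both.
#'
#' @param records scan records from [mqtl_scan()].
#' @param probes probe table covering all tested probes.
#' @param score named numeric vector (names = probe IDs).
#' @param breaks passed to [cut()].
#' @return data.frame, one row per bin.
#' @export
stratify_by_score <- function(records, probes, score,
                              breaks = seq(0, 1, 0.2)) {
  cls <- tapply(records$cis, records$probe, function(z)
    if (all(z)) "cis_only" else if (!any(z)) "trans_only" else "both")
  bin <- cut(score[probes$id], breaks, include.lowest = TRUE)
  status <- cls[probes$id]
  status[is.na(status)] <- "none"
  tab <- table(bin, factor(status,
                           levels = c("cis_only", "trans_only", "both", "none")))
  out <- as.data.frame.matrix(prop.table(tab, 1))
  out$bin <- rownames(tab)
  out$n <- as.integer(rowSums(tab))
  rownames(out) <- NULL
  out[, c("bin", "n", "cis_only", "trans_only", "both", "none")]
}
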
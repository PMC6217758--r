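#' Squared dosage correlation between two variants
#'
#' LD r-squared as the squared sample correlation of dosages over
#' complete-case samples, computed in the analysis panel itself.
#'
#' @param gm a [genotype_matrix()].
#' @param v1,v2 variant IDs.
#' @return r-squared in \[0, 1\]; `NA` with a warning when either variant
#'   has zero variance.
#' @export
ld_r2 <- function(gm, v1, v2) {
  d1 <- gm$dosages[, v1]; d2 <- gm$dosages[, v2]
  cc <- !is.na(d1) & !is.na(d2)
  if (sum(cc) < 2) stop("fewer than 2 complete-case samples")
  if (sd(d1[cc]) == 0 || sd(d2[cc]) == 0) {
    warning("zero dosage variance; r2 undefined for (", v1, ", ", v2, ")")
    return(NA_real_)
  }
  cor(d1[cc], d2[cc])^2
}

# signed LD correlation matrix over a set of variant ids
.ld_cor <- function(gm, ids) {
  D <- gm$dosages[, ids, drop = FALSE]
  suppressWarnings(cor(D, use = "pairwise.complete.obs"))
}

#' Greedy LD clumping of one probe's association records
#'
#' PLINK-style clumping: repeatedly take the unassigned variant with the
#' smallest p <= `p1` as index, assign to it every unassigned variant with
#' p <= `p2`, within `window_kb` of the index position, and r-squared >=
#' `r2_cut` with the index; iterate until no index candidate remains.
#' p-value ties are broken by (chrom, pos, id), so output is deterministic.
#'
#' @param records association records for a single probe (columns `snp`,
#'   `snp_chr`, `snp_pos`, `p`).
#' @param gm the [genotype_matrix()] that produced the associations.
#' @param p1 index-variant significance threshold.
#' @param p2 member-variant significance threshold.
#' @param r2_cut minimum r-squared with the index for membership.
#' @param window_kb window half-width around the index, kilobases.
#' @return data.frame of clumps sorted by index p: `index_snp, index_chr,
#'   index_pos, index_p, n_members, members` (comma-joined IDs).
#' @export
clump <- function(records, gm, p1 = 1e-8, p2 = 1e-8, r2_cut = 0.1,
                  window_kb = 250) {
  rec <- records[records$p <= p2, , drop = FALSE]
  rec <- rec[order(rec$p, rec$snp_chr, rec$snp_pos, rec$snp), , drop = FALSE]
  unassigned <- rep(TRUE, nrow(rec))
  out <- list()
  repeat {
    cand <- which(unassigned & rec$p <= p1)
    if (length(cand) == 0) break
    idx <- cand[1]                        # smallest p, ties pre-broken
    unassigned[idx] <- FALSE
    near <- which(unassigned &
                    rec$snp_chr == rec$snp_chr[idx] &
                    abs(rec$snp_pos - rec$snp_pos[idx]) <= window_kb * 1000)
    memb <- integer()
    for (j in near) {
      r2 <- suppressWarnings(ld_r2(gm, rec$snp[j], rec$snp[idx]))
      if (!is.na(r2) && r2 >= r2_cut) memb <- c(memb, j)
    }
    unassigned[memb] <- FALSE
    out[[length(out) + 1L]] <- data.frame(
      index_snp = rec$snp[idx], index_chr = rec$snp_chr[idx],
      index_pos = rec$snp_pos[idx], index_p = rec$p[idx],
      n_members = length(memb),
      members = paste(rec$snp[memb], collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(index_snp = character(), index_chr = character(),
                      index_pos = integer(), index_p = numeric(),
                      n_members = integer(), members = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$index_p, res$index_chr, res$index_pos, res$index_snp), ,
      drop = FALSE]
}

#' Clump every probe's records in a scan
#'
#' @param records scan records (with `probe` column) from [mqtl_scan()].
#' @param gm a [genotype_matrix()].
#' @param ... passed to [clump()].
#' @return data.frame with a `probe` column prepended to [clump()] output.
#' @export
ld_clump <- function(records, gm, ...) {
  split_rec <- split(records, records$probe)
  out <- lapply(names(split_rec), function(cpg) {
    cl <- clump(split_rec[[cpg]], gm, ...)
    if (nrow(cl)) cbind(probe = cpg, cl, stringsAsFactors = FALSE) else NULL
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0)
    return(data.frame(probe = character(), index_snp = character(),
                      index_chr = character(), index_pos = integer(),
                      index_p = numeric(), n_members = integer(),
                      members = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
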
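#' @importFrom stats pchisq pt pnorm qnorm rnorm rbinom runif sd cor median
#'   quantile prcomp rgamma setNames dbinom pbinom
#' @importFrom utils read.table write.table head combn
NULL

# scientific notation, 6 significant digits: fixed output format so that
# write -> read round-trips are bit-identical on the written representation
fmt_sci <- function(x) ifelse(is.na(x), "NA", sprintf("%.5e", x))

#' Construct a genotype matrix
#'
#' Container for additive allele dosages (samples x variants) plus variant
#' metadata. Dosages count copies of the effect allele and lie in \[0, 2\]
#' (hard calls are 0/1/2; imputed dosages may be fractional). Missing calls
#' are stored as `NA` and handled downstream by casewise deletion.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns.
#' @param variants data.frame with columns `id`, `chrom`, `pos`,
#'   `allele_effect`, `allele_other`, and optionally `maf` and `info`.
#' @param sample_ids character vector of sample identifiers.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants, sample_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  stopifnot(is.data.frame(variants),
            all(c("id", "chrom", "pos", "allele_effect", "allele_other") %in%
                  names(variants)))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosages)))
  if (nrow(variants) != ncol(dosages))
    stop("variant table has ", nrow(variants), " rows but dosage matrix has ",
         ncol(dosages), " columns")
  if (length(sample_ids) != nrow(dosages))
    stop("sample_ids length does not match dosage rows")
  if (anyDuplicated(variants$id))
    stop("duplicate variant IDs: ",
         paste(unique(variants$id[duplicated(variants$id)]), collapse = ", "))
  if (any(variants$pos < 1)) stop("variant positions must be >= 1")
  bad <- variants$allele_effect == variants$allele_other
  if (any(bad)) stop("effect and other allele identical for: ",
                     paste(variants$id[bad], collapse = ", "))
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variants$id
  if (is.null(variants$maf)) {
    af <- colMeans(dosages, na.rm = TRUE) / 2
    variants$maf <- pmin(af, 1 - af)
  }
  if (is.null(variants$info)) variants$info <- NA_real_
  variants$missing_frac <- colMeans(is.na(dosages))
  structure(list(dosages = dosages, variants = variants,
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @method print genotype_matrix
#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      nrow(x$variants), "variants\n")
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  cat("  MAF range: [", sprintf("%.3f", min(x$variants$maf)), ",",
      sprintf("%.3f", max(x$variants$maf)), "]\n")
  invisible(x)
}

#' Construct a molecular trait matrix
#'
#' Holds methylation beta values (all in \[0,1\]) or expression values,
#' samples x probes, with probe metadata carrying position, gene/island
#' annotation and exclusion flags.
#'
#' @param values numeric matrix, samples in rows, probes in columns.
#' @param probes data.frame with at least `id`, `chrom`, `pos`; optional
#'   `gene`, `feature`, `island_relation` and logical flag columns
#'   `cross_hybridizing`, `snp_proximal`, `sex_chromosome`, `substandard`.
#' @param sample_ids character vector of sample identifiers.
#' @param scale `"beta"` (methylation proportions) or `"expression"`.
#' @return An object of class `trait_matrix`.
#' @export
trait_matrix <- function(values, probes, sample_ids = rownames(values),
                         scale = c("beta", "expression")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  stopifnot(is.data.frame(probes), all(c("id", "chrom", "pos") %in% names(probes)))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (nrow(probes) != ncol(values))
    stop("probe table rows do not match value columns")
  if (length(sample_ids) != nrow(values))
    stop("sample_ids length does not match value rows")
  if (scale == "beta") {
    rng <- range(values, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1)
      stop("beta-scale values must lie in [0, 1]; observed range [",
           rng[1], ", ", rng[2], "]")
  }
  for (fl in c("cross_hybridizing", "snp_proximal", "sex_chromosome",
               "substandard")) {
    if (is.null(probes[[fl]])) probes[[fl]] <- FALSE
  }
  rownames(values) <- sample_ids
  colnames(values) <- probes$id
  structure(list(values = values, probes = probes, sample_ids = sample_ids,
                 scale = scale),
            class = "trait_matrix")
}

#' @method print trait_matrix
#' @export
print.trait_matrix <- function(x, ...) {
  cat("trait_matrix (", x$scale, "): ", length(x$sample_ids), " samples x ",
      nrow(x$probes), " probes\n", sep = "")
  invisible(x)
}

#' Restrict genotype, trait and covariate data to shared samples
#'
#' All joint operations use the intersection of sample IDs (exact string
#' match); the number of samples dropped from each input is reported.
#'
#' @param gm a [genotype_matrix()].
#' @param tm a [trait_matrix()].
#' @param covariates data.frame with a `sample_id` column, or `NULL`.
#' @param quiet suppress the dropped-sample message.
#' @return list with elements `genotypes`, `traits`, `covariates`,
#'   `n_dropped` (named vector).
#' @export
align_samples <- function(gm, tm, covariates = NULL, quiet = FALSE) {
  ids <- intersect(gm$sample_ids, tm$sample_ids)
  if (!is.null(covariates)) ids <- intersect(ids, covariates$sample_id)
  if (length(ids) == 0) stop("no samples shared between inputs")
  dropped <- c(genotypes = length(gm$sample_ids) - length(ids),
               traits = length(tm$sample_ids) - length(ids),
               covariates = if (is.null(covariates)) 0L else
                 nrow(covariates) - length(ids))
  if (!quiet && sum(dropped) > 0)
    message("align_samples: dropped ", paste(dropped, collapse = "/"),
            " samples (genotypes/traits/covariates)")
  gm$dosages <- gm$dosages[ids, , drop = FALSE]
  gm$sample_ids <- ids
  tm$values <- tm$values[ids, , drop = FALSE]
  tm$sample_ids <- ids
  if (!is.null(covariates)) {
    covariates <- covariates[match(ids, covariates$sample_id), , drop = FALSE]
    if (anyNA(covariates)) stop("covariates contain missing values after alignment")
  }
  list(genotypes = gm, traits = tm, covariates = covariates,
       n_dropped = dropped)
}

#' Read a biallelic VCF into a genotype matrix
#'
#' Minimal VCF import for the QTL pipeline: biallelic SNP/indel records with
#' GT or DS FORMAT fields. Dosages count copies of the ALT allele (the
#' effect allele). Multiallelic records are rejected with their record
#' numbers; duplicate variant IDs are an error, matching the convention of
#' naming variants by location and excluding duplicates.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param prefer_ds use the DS field when present instead of counting GT alleles.
#' @return A [genotype_matrix()].
#' @export
read_vcf_lite <- function(path, prefer_ds = FALSE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE) | is.na(fix$ALT) | is.na(fix$REF)
  if (any(multi))
    stop("multiallelic or malformed records at record number(s): ",
         paste(which(multi), collapse = ", "))
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  if (anyDuplicated(ids))
    stop("duplicate variant IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  has_ds <- prefer_ds && any(grepl("DS", fix$FORMAT %||% "", fixed = TRUE))
  if (has_ds) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    dos <- t(ds)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    cnt <- function(g) {
      g <- gsub("|", "/", g, fixed = TRUE)
      ifelse(is.na(g) | grepl("\\.", g),
             NA_real_,
             vapply(strsplit(g, "/", fixed = TRUE),
                    function(a) sum(a == "1"), numeric(1)))
    }
    dos <- apply(gt, 1, cnt)
    if (is.null(dim(dos))) dos <- matrix(dos, nrow = ncol(gt), ncol = nrow(gt))
  }
  samples <- colnames(vcf@gt)[-1]
  variants <- data.frame(id = ids, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         allele_effect = fix$ALT, allele_other = fix$REF,
                         stringsAsFactors = FALSE)
  genotype_matrix(dos, variants, sample_ids = samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read GCTA-COJO style summary statistics (.ma)
#'
#' Whitespace-delimited columns `SNP A1 A2 freq b se p n` with a header.
#' A1 is the effect allele. Rows with non-positive standard errors or
#' p-values outside (0, 1] are rejected and counted. When the frequency
#' column is absent or missing, values are filled from `freq_ref`.
#'
#' @param path file path.
#' @param freq_ref optional data.frame with columns `SNP` (or `snp`) and
#'   `freq` used to impute missing allele frequencies.
#' @return data.frame with columns `snp, a1, a2, freq, b, se, p, n, stat`
#'   (stat = b/se); attribute `n_rejected` counts dropped rows.
#' @export
read_ma <- function(path, freq_ref = NULL) {
  empty <- data.frame(snp = character(), a1 = character(), a2 = character(),
                      freq = numeric(), b = numeric(), se = numeric(),
                      p = numeric(), n = numeric(), stat = numeric(),
                      stringsAsFactors = FALSE)
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character())
  if (length(first) == 0 || !nzchar(trimws(first[1]))) {
    warning("empty .ma file: ", path)
    attr(empty, "n_rejected") <- 0L
    return(empty)
  }
  x <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  names(x) <- tolower(names(x))
  need <- c("snp", "a1", "a2", "b", "se", "p", "n")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop(".ma file missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(x$freq)) x$freq <- NA_real_
  if (anyNA(x$freq) && !is.null(freq_ref)) {
    names(freq_ref) <- tolower(names(freq_ref))
    idx <- match(x$snp, freq_ref$snp)
    fill <- is.na(x$freq) & !is.na(idx)
    x$freq[fill] <- freq_ref$freq[idx[fill]]
  }
  bad <- !is.finite(x$se) | x$se <= 0 | !is.finite(x$p) | x$p <= 0 | x$p > 1
  if (any(bad))
    message("read_ma: rejected ", sum(bad), " row(s) with invalid se or p")
  x <- x[!bad, , drop = FALSE]
  x$stat <- x$b / x$se
  out <- x[, c("snp", "a1", "a2", "freq", "b", "se", "p", "n", "stat")]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Write summary statistics in .ma format
#'
#' @param records data.frame with columns `snp, a1, a2, freq, b, se, p, n`.
#' @param path output path.
#' @export
write_ma <- function(records, path) {
  out <- data.frame(SNP = records$snp, A1 = records$a1, A2 = records$a2,
                    freq = fmt_sci(records$freq), b = fmt_sci(records$b),
                    se = fmt_sci(records$se), p = fmt_sci(records$p),
                    n = records$n)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an association table, keeping rows below a p-value threshold
#'
#' Only rows with `p < threshold` (strict) are saved, mirroring a scan that
#' retains results more significant than a pre-defined threshold. Row order
#' is deterministic: by probe, then p, with p-ties broken by
#' (chrom, pos, variant id). Numeric columns are written in scientific
#' notation with 6 significant digits so round-trips are exact on the
#' written representation.
#'
#' @param records scan record data.frame (see [mqtl_scan()]).
#' @param path output TSV path.
#' @param threshold strict upper bound on p.
#' @return invisibly, the number of rows written.
#' @export
write_assoc_table <- function(records, path, threshold = 1) {
  keep <- records[records$p < threshold, , drop = FALSE]
  ord <- order(keep$probe, keep$p, keep$snp_chr, keep$snp_pos, keep$snp)
  keep <- keep[ord, , drop = FALSE]
  out <- keep
  for (cl in intersect(c("freq", "b", "se", "stat", "p", "effect_pp"), names(out)))
    out[[cl]] <- fmt_sci(out[[cl]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(nrow(keep))
}

#' Read an association table written by [write_assoc_table()]
#'
#' @param path TSV path.
#' @return data.frame of scan records.
#' @export
read_assoc_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if ("cis" %in% names(x)) x$cis <- as.logical(x$cis)
  x
}

#' Read a BED interval file
#'
#' BED is 0-based half-open on disk; intervals are converted to 1-based
#' closed coordinates on read (the convention used throughout this package).
#'
#' @param path BED file path.
#' @return data.frame with columns `chrom, start, end` and, when present,
#'   `name, score, strand`.
#' @export
read_bed <- function(path) {
  gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
  df <- data.frame(chrom = as.character(gr$seqnames),
                   start = gr$start, end = gr$end,
                   stringsAsFactors = FALSE)
  if (!is.null(gr$name)) df$name <- gr$name
  if (!is.null(gr$score)) df$score <- gr$score
  df$strand <- as.character(gr$strand)
  df
}
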
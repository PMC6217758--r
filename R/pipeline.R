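#' Load a pipeline configuration from a YAML file
#'
#' Keys override [sim_config()] simulation fields and the analysis
#' thresholds of [run_pipeline()]; every threshold used in the analysis has
#' a named key whose default matches the published convention (1e-8 save
#' threshold, genome-wide alpha 5e-8, 1e-10 discovery threshold, 500 kb cis
#' window, 250 kb pairing window, clump parameters 1e-8/1e-8/0.1/250 kb,
#' HEIDI pass level 0.05).
#'
#' @param path YAML file of `key: value` pairs; must include `seed`.
#' @return list with `sim` (a [sim_config()]) and `analysis` (thresholds).
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) stop("config must set a seed")
  sim_keys <- names(formals(sim_config))
  sim <- do.call(sim_config, raw[intersect(names(raw), sim_keys)])
  analysis <- list(save_threshold = 1e-8, alpha_gw = 5e-8,
                   discovery_p = 1e-10, cis_window = 500000,
                   pair_max_sep = 250000, clump_p1 = 1e-8, clump_p2 = 1e-8,
                   clump_r2 = 0.1, clump_kb = 250, smr_alpha = 0.05,
                   heidi_alpha = 0.05, eqtl_gate = 5e-8)
  for (k in intersect(names(raw), names(analysis))) analysis[[k]] <- raw[[k]]
  list(sim = sim, analysis = analysis)
}

#' Run the full pipeline on a simulated study
#'
#' simulate -> QC -> scan -> clump -> coloc -> SMR (trait and expression
#' designs), writing each stage's table under `out_dir` and returning a run
#' manifest with the seed, thresholds actually used, per-stage record
#' counts and output file hashes. Deterministic under the seed.
#'
#' @param sim a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param analysis analysis thresholds (see [load_pipeline_config()]);
#'   missing entries take their defaults.
#' @param mc_draws HEIDI Monte Carlo draws.
#' @return the manifest, invisibly also written as `manifest.yaml`.
#' @export
run_pipeline <- function(sim = sim_config(), out_dir = tempfile("mqtlrun"),
                         analysis = list(), mc_draws = 20000) {
  defaults <- list(save_threshold = 1e-8, alpha_gw = 5e-8,
                   discovery_p = 1e-10, cis_window = 500000,
                   pair_max_sep = 250000, clump_p1 = 1e-8, clump_p2 = 1e-8,
                   clump_r2 = 0.1, clump_kb = 250, smr_alpha = 0.05,
                   heidi_alpha = 0.05, eqtl_gate = 5e-8)
  for (k in names(defaults))
    if (is.null(analysis[[k]])) analysis[[k]] <- defaults[[k]]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- simulate_study(sim)

  qc_v <- filter_variants(study$genotypes)
  qc_p <- filter_probes(study$methylation)
  utils::write.table(qc_v$report, file.path(out_dir, "qc_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  scan <- mqtl_scan(qc_v$genotypes, qc_p$traits, study$covariates,
                    save_threshold = analysis$save_threshold,
                    cis_window = analysis$cis_window)
  write_assoc_table(scan, file.path(out_dir, "scan.tsv"),
                    threshold = analysis$save_threshold)
  bonf <- bonferroni_threshold(analysis$alpha_gw, nrow(qc_p$traits$probes))

  clumps <- ld_clump(scan, qc_v$genotypes, p1 = analysis$clump_p1,
                     p2 = analysis$clump_p2, r2_cut = analysis$clump_r2,
                     window_kb = analysis$clump_kb)
  utils::write.table(clumps, file.path(out_dir, "clumps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # coloc and HEIDI need all statistics in the windows, not only those below
  # the save threshold: rerun the scan unthresholded for the probes that
  # reach the discovery threshold
  elig <- unique(scan$probe[scan$p < analysis$discovery_p])
  coloc_res <- data.frame()
  full <- scan
  if (length(elig) >= 1) {
    keep <- qc_p$traits$probes$id %in% elig
    tm_sub <- trait_matrix(qc_p$traits$values[, keep, drop = FALSE],
                           qc_p$traits$probes[keep, , drop = FALSE],
                           sample_ids = qc_p$traits$sample_ids,
                           scale = qc_p$traits$scale)
    full <- mqtl_scan(qc_v$genotypes, tm_sub, study$covariates,
                      save_threshold = 1 + 1e-9,
                      cis_window = analysis$cis_window)
    pairs <- pair_windows(tm_sub$probes, scan,
                          discovery_p = analysis$discovery_p,
                          max_sep = analysis$pair_max_sep,
                          snp_window = analysis$cis_window)
    if (nrow(pairs))
      coloc_res <- coloc_scan_pairs(full, pairs)
  }
  utils::write.table(coloc_res, file.path(out_dir, "coloc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  set.seed(.sub_seed(sim$seed, 21L))
  smr_trait <- run_smr_design(full, study$gwas$records, qc_v$genotypes,
                              design = "trait",
                              exposure_gate = analysis$discovery_p,
                              alpha = analysis$smr_alpha,
                              heidi_alpha = analysis$heidi_alpha,
                              mc_draws = mc_draws)
  utils::write.table(smr_trait, file.path(out_dir, "smr_trait.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  set.seed(.sub_seed(sim$seed, 22L))
  smr_expr <- run_smr_design(full, study$eqtl$records, qc_v$genotypes,
                             design = "expression",
                             exposure_probes = qc_p$traits$probes,
                             outcome_probes = study$eqtl$probes,
                             exposure_gate = analysis$discovery_p,
                             outcome_gate = analysis$eqtl_gate,
                             window = analysis$cis_window,
                             alpha = analysis$smr_alpha,
                             heidi_alpha = analysis$heidi_alpha,
                             mc_draws = mc_draws)
  utils::write.table(smr_expr, file.path(out_dir, "smr_expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  files <- c("qc_variants.tsv", "scan.tsv", "clumps.tsv", "coloc.tsv",
             "smr_trait.tsv", "smr_expression.tsv")
  hashes <- tools::md5sum(file.path(out_dir, files))
  names(hashes) <- files
  manifest <- list(
    seed = sim$seed,
    thresholds = c(analysis,
                   bonferroni = bonf,
                   smr_trait_threshold = attr(smr_trait, "smr_threshold"),
                   smr_expression_threshold = attr(smr_expr, "smr_threshold")),
    counts = list(
      variants_tested = nrow(qc_v$genotypes$variants),
      probes_tested = nrow(qc_p$traits$probes),
      scan_tests = attr(scan, "n_tests"),
      scan_records_saved = nrow(scan),
      clumps = nrow(clumps),
      coloc_pairs = nrow(coloc_res),
      smr_trait_tested = attr(smr_trait, "n_tested"),
      smr_trait_pleiotropic = sum(smr_trait$pleiotropic),
      smr_expression_tested = attr(smr_expr, "n_tested"),
      smr_expression_pleiotropic = sum(smr_expr$pleiotropic)),
    hashes = as.list(hashes),
    out_dir = out_dir)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  manifest$tables <- list(scan = scan, clumps = clumps, coloc = coloc_res,
                          smr_trait = smr_trait, smr_expression = smr_expr)
  invisible(manifest)
}
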
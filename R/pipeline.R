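# Run configuration, the end-to-end pipeline, and the command-line entry
# point.

#' Pipeline run configuration
#'
#' Collects every printed constant of the analysis in one place, together
#' with the synthetic-data generator settings.  Thresholds default to the
#' published values; the simulation block accepts any [sim_config()]
#' argument.
#'
#' @param bin_size Track bin width in bp (default 10).
#' @param similarity_window Window for sample similarity in bp (default
#'   1000); must be a multiple of `bin_size`.
#' @param stop_flank Stop-codon window flank in bp (default 200).
#' @param tpm_floor Expression floor for gene-level m6A calls (default 1).
#' @param mirna_rpm_min miRNA expression floor in RPM (default 10).
#' @param te_fpkm_min mRNA FPKM floor for translation efficiency (default
#'   10).
#' @param entropy_max,constant_tpm_min Constant-gene rule (default 0.5 /
#'   10).
#' @param completeness_min Repeat completeness threshold (default 0.9).
#' @param naive_threshold,naive_min_bins,naive_merge_gap Naive peak caller
#'   settings for synthetic end-to-end runs; the default threshold of 2
#'   log2 units demands at least four-fold IP enrichment, which keeps peak
#'   counts from fragmenting when signal hovers near the cutoff.
#' @param strand_aware Reserved flag for strand-aware annotation (default
#'   off; the upstream protocol's strandedness is not asserted).
#' @param seed Run seed.
#' @param simulation Named list of [sim_config()] overrides.
#' @return An object of class `RunConfig`.
#' @export
run_config <- function(bin_size = 10, similarity_window = 1000,
                       stop_flank = 200, tpm_floor = 1, mirna_rpm_min = 10,
                       te_fpkm_min = 10, entropy_max = 0.5,
                       constant_tpm_min = 10, completeness_min = 0.9,
                       naive_threshold = 2, naive_min_bins = 3,
                       naive_merge_gap = 1, strand_aware = FALSE, seed = 1,
                       simulation = list()) {
  .assert(similarity_window %% bin_size == 0,
          "bin_size must divide similarity_window")
  thr <- c(bin_size, similarity_window, stop_flank, tpm_floor,
           mirna_rpm_min, te_fpkm_min, entropy_max, constant_tpm_min,
           completeness_min, naive_threshold)
  .assert(all(thr > 0), "all thresholds must be positive")
  structure(list(bin_size = bin_size, similarity_window = similarity_window,
                 stop_flank = stop_flank, tpm_floor = tpm_floor,
                 mirna_rpm_min = mirna_rpm_min, te_fpkm_min = te_fpkm_min,
                 entropy_max = entropy_max,
                 constant_tpm_min = constant_tpm_min,
                 completeness_min = completeness_min,
                 naive_threshold = naive_threshold,
                 naive_min_bins = naive_min_bins,
                 naive_merge_gap = naive_merge_gap,
                 strand_aware = strand_aware, seed = seed,
                 simulation = simulation),
            class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys are [run_config()] arguments (the
#'   `simulation` block holds [sim_config()] overrides).
#' @return A `RunConfig`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> signal -> annotate -> genes -> classify -> compare
#' -> mirna -> te -> retro -> report from one configuration, writing TSV
#' outputs and a log (with a configuration echo and the seed) into
#' `outdir`.
#'
#' @param config A `RunConfig` (or path to a YAML file).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "pipeline.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logln <- function(...) writeLines(sprintf(...), log_con)
  logln("oetm6a pipeline run, seed = %d", config$seed)
  logln("config: %s", paste(utils::capture.output(utils::str(
    config[setdiff(names(config), "simulation")])), collapse = " "))

  scfg <- do.call(sim_config, c(list(seed = config$seed,
                                     bin_size = config$bin_size),
                                config$simulation))

  ## simulate
  sim <- simulate_annotation(scfg)
  exp <- simulate_stage_experiment(scfg, sim)
  cond <- simulate_condition_experiment(scfg, sim)
  write_gene_models(sim$bundle, file.path(outdir, "annotation.gtf"))
  write_expression(exp$expression, file.path(outdir, "expression_tpm.tsv"))
  .write_tsv(sim$homology, file.path(outdir, "homology.tsv"))
  logln("simulate: %d genes, %d repeat fragments",
        nrow(sim$bundle$genes), nrow(sim$repeats))

  stages <- scfg$stages
  ## signal: similarity of all Input tracks
  inputs <- list()
  for (s in stages) for (r in names(exp$tracks[[s]])) {
    inputs[[paste0(s, "_", r)]] <- exp$tracks[[s]][[r]]$input
  }
  simres <- sample_similarity(inputs, window = config$similarity_window)
  .write_tsv(data.frame(sample = rownames(simres$r), simres$r,
                        check.names = FALSE),
             file.path(outdir, "similarity_pearson.tsv"))
  rep_r <- vapply(stages, function(s) {
    simres$r[paste0(s, "_rep1_Input"), paste0(s, "_rep2_Input")]
  }, numeric(1))
  logln("signal: replicate Pearson r per stage: %s",
        paste(sprintf("%s=%.3f", stages, rep_r), collapse = ", "))

  ## annotate: peak features, enrichment, metagene (per stage, replicate 1)
  annot <- list(); enr <- list(); meta <- list()
  for (s in stages) {
    pk <- exp$peaks[[s]]$rep1
    if (is.null(pk)) next
    a <- assign_peak_features(pk, sim$bundle, stop_flank = config$stop_flank)
    annot[[s]] <- a
    enr[[s]] <- cbind(stage = s,
                      feature_enrichment(a, sim$bundle,
                                         stop_flank = config$stop_flank))
    tx_expr <- exp$tx_expression[, paste0(s, "_rep1")]
    meta[[s]] <- metagene_profile(pk, sim$bundle, tx_expr)
  }
  .write_tsv(do.call(rbind, enr), file.path(outdir, "feature_enrichment.tsv"))
  logln("annotate: %d stages annotated", length(annot))

  ## genes: per-stage m6A calls
  calls <- list()
  for (s in stages) {
    calls[[s]] <- call_m6a_genes(exp$peaks[[s]], sim$bundle,
                                 expr = exp$stage_tpm[, s],
                                 tpm_floor = config$tpm_floor)
  }
  call_tab <- do.call(rbind, lapply(stages, function(s) {
    cbind(stage = s, calls[[s]])
  }))
  .write_tsv(call_tab, file.path(outdir, "m6a_gene_calls.tsv"))
  logln("genes: m6A+ per stage: %s",
        paste(vapply(stages, function(s) sprintf("%s=%d", s,
          sum(calls[[s]]$status == "m6A+")), character(1)), collapse = ", "))

  ## classify
  norm <- normalize_expression(exp$expression)
  cls <- classify_maternal_zga(norm)
  .write_tsv(cls, file.path(outdir, "stage_classification.tsv"))
  logln("classify: %s", paste(names(table(cls$label)), table(cls$label),
                              sep = "=", collapse = ", "))

  ## compare: human-mouse homolog categories at the ZGA-comparable stage
  homolog <- classify_homolog_expression(exp$expression, exp$mouse,
                                         sim$homology,
                                         stage_pairs = c("8C" = "2C"))
  .write_tsv(homolog, file.path(outdir, "homolog_categories.tsv"))

  ## mirna
  mir <- mirna_rpm(exp$mirna$counts, exp$mirna$samples, exp$mirna$families)
  coding <- sim$bundle$genes$gene_id[sim$bundle$genes$biotype ==
                                       "protein_coding"]
  mir_stage <- intersect(colnames(mir$stage_rpm), stages)[1]
  mirres <- mirna_targeting(calls[[mir_stage]], sim$target_map, mir,
                            mir_stage, rpm_min = config$mirna_rpm_min,
                            coding_genes = coding)
  .write_tsv(mirres$genes, file.path(outdir, "mirna_targeting.tsv"))
  logln("mirna[%s]: fisher p = %.3g, wilcoxon(weighted) p = %.3g",
        mir_stage, mirres$fisher$p_value, mirres$wilcoxon_weighted$p_value)

  ## te
  te <- translation_efficiency(exp$ribo, exp$mrna,
                               fpkm_min = config$te_fpkm_min,
                               coding_genes = coding)
  .write_tsv(te, file.path(outdir, "translation_efficiency.tsv"))
  te_stage <- intersect(unique(te$stage), stages)[1]
  const_m6a <- cls$gene_id[cls$constant &
                             cls$gene_id %in%
                               calls[[te_stage]]$gene_id[
                                 calls[[te_stage]]$status == "m6A+"]]
  te_reg <- te_by_peak_region(te, te_stage, annot[[te_stage]], const_m6a)
  if (!is.null(te_reg$summary)) {
    .write_tsv(te_reg$summary, file.path(outdir, "te_by_region.tsv"))
  }

  ## retro
  loci <- filter_repeat_loci(sim$repeats, sim$consensus, sim$bundle,
                             min_completeness = config$completeness_min)
  retro_summ <- list(); scored_by_stage <- list()
  for (s in stages) {
    tr <- exp$tracks[[s]]
    scored <- score_repeat_loci(loci,
                                lapply(tr, `[[`, "input"),
                                lapply(tr, `[[`, "signal"))
    scored_by_stage[[s]] <- scored
    retro_summ[[s]] <- cbind(stage = s, subfamily_summary(scored))
  }
  .write_tsv(do.call(rbind, retro_summ),
             file.path(outdir, "retro_subfamily_summary.tsv"))

  ## retro condition comparison via the naive caller
  naive <- function(trk) call_peaks_naive(trk$rep1$signal,
                                          threshold = config$naive_threshold,
                                          min_bins = config$naive_min_bins,
                                          merge_gap = config$naive_merge_gap)
  cond_scored <- lapply(cond$tracks, function(tr) {
    score_repeat_loci(loci, lapply(tr, `[[`, "input"),
                      lapply(tr, `[[`, "signal"))
  })
  cmpres <- condition_peak_comparison(naive(cond$tracks$Ctrl),
                                      naive(cond$tracks$treated), loci,
                                      cond_scored$Ctrl,
                                      cond_scored$treated)
  logln("retro: %d loci retained; Ctrl peaks on repeats = %d, treated = %d (reduction %.1f%%)",
        nrow(loci), cmpres$n_ctrl, cmpres$n_treated,
        cmpres$reduction_percent)
  if (!is.null(cmpres$subfamily_tests)) {
    .write_tsv(cmpres$subfamily_tests,
               file.path(outdir, "retro_condition_tests.tsv"))
  }

  ## report
  report <- data.frame(
    metric = c("n_genes", "n_m6a_genes_truth", "min_replicate_r",
               paste0("m6a_plus_", stages), "n_repeat_loci",
               "retro_peak_reduction_pct"),
    value = c(nrow(sim$bundle$genes), length(sim$truth$m6a_genes),
              min(rep_r),
              vapply(stages, function(s) sum(calls[[s]]$status == "m6A+"),
                     numeric(1)),
              nrow(loci), cmpres$reduction_percent))
  .write_tsv(report, file.path(outdir, "report.tsv"))
  logln("report written")

  invisible(list(sim = sim, experiment = exp, condition = cond,
                 similarity = simres, annotations = annot,
                 enrichment = enr, metagene = meta, calls = calls,
                 classification = cls, homolog = homolog, mirna = mirres,
                 te = te, te_by_region = te_reg, loci = loci,
                 retro = scored_by_stage, condition_comparison = cmpres,
                 report = report))
}

#' Command-line entry point
#'
#' `oetm6a_cli(c("run", "--config", "cfg.yaml", "--out", "results"))`
#' executes the full pipeline; the `simulate` subcommand writes only the
#' synthetic inputs.  Available subcommands: `simulate`, `run` (aliases:
#' `signal`, `annotate`, `genes`, `classify`, `compare`, `mirna`, `te`,
#' `retro`, `report`, which all require the preceding stages and therefore
#' execute the pipeline through their stage).
#'
#' @param args Character vector of command-line arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Invisibly, the pipeline result (or `NULL` for `simulate`).
#' @export
oetm6a_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  .assert(length(args) >= 1, paste(
    "usage: oetm6a_cli(c('<subcommand>', '--config', '<yaml>',",
    "'--out', '<dir>'))"))
  sub <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i)) args[i[1] + 1] else default
  }
  outdir <- opt("--out", "oetm6a_out")
  cfg_path <- opt("--config")
  config <- if (is.null(cfg_path)) run_config() else read_run_config(cfg_path)
  seed <- opt("--seed")
  if (!is.null(seed)) config$seed <- as.integer(seed)

  known <- c("simulate", "run", "signal", "annotate", "genes", "classify",
             "compare", "mirna", "te", "retro", "report")
  .assert(sub %in% known, "unknown subcommand '%s' (one of: %s)", sub,
          paste(known, collapse = ", "))
  if (sub == "simulate") {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    scfg <- do.call(sim_config, c(list(seed = config$seed,
                                       bin_size = config$bin_size),
                                  config$simulation))
    sim <- simulate_annotation(scfg)
    write_gene_models(sim$bundle, file.path(outdir, "annotation.gtf"))
    Biostrings::writeXStringSet(sim$bundle$sequence,
                                file.path(outdir, "genome.fa"))
    .write_tsv(data.frame(chrom = names(sim$bundle$chrom_sizes),
                          size = unname(sim$bundle$chrom_sizes)),
               file.path(outdir, "chrom.sizes"))
    .write_tsv(sim$repeats, file.path(outdir, "repeats.tsv"))
    .write_tsv(data.frame(subfamily = names(sim$consensus),
                          length = unname(sim$consensus)),
               file.path(outdir, "repeat_consensus.tsv"))
    .write_tsv(sim$homology, file.path(outdir, "homology.tsv"))
    .write_tsv(sim$target_map, file.path(outdir, "mirna_targets.tsv"))
    .log_msg("simulate: inputs written to %s", outdir)
    return(invisible(NULL))
  }
  invisible(run_pipeline(config, outdir))
}
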
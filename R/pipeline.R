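#' Pipeline configuration
#'
#' Bundles the module parameters for an end-to-end synthetic run with the
#' pipeline's standard defaults: 2 nt arm flank, expression filter at mean
#' log2 >= 5, arm-DE significance at FDR 0.01, 10,000 bootstrap replicates,
#' tested cohorts > 50 samples, TargetScan filters at conservation >= 90 and
#' context < -0.3555, and 5% percentile intervals.
#'
#' @param seed Master integer seed; stage seeds are derived from it.
#' @param sim A [sim_config()] for the synthetic cohorts (its own `seed`
#'   field is overridden by the derived stage seeds).
#' @param hotspot A [hotspot_config()].
#' @param resampling A [resampling_config()].
#' @param n_perm Permutation count for the gene-set stage.
#' @param de_fdr Arm-DE significance threshold.
#' @param out_dir Optional directory for TSV/JSON outputs; `NULL` skips
#'   writing.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(seed = 1L, sim = sim_config(),
                            hotspot = hotspot_config(),
                            resampling = resampling_config(),
                            n_perm = 10000L, de_fdr = 0.01, out_dir = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  structure(list(seed = as.integer(seed), sim = sim, hotspot = hotspot,
                 resampling = resampling, n_perm = as.integer(n_perm),
                 de_fdr = de_fdr, out_dir = out_dir),
            class = "run_config")
}

# derive a stage seed from the master seed, kept within 32-bit range
.stage_seed <- function(seed, stage) (as.integer(seed) * 101L + stage) %% 2000000000L

#' Run the synthetic end-to-end pipeline
#'
#' Orchestrates simulate -> classify -> enrich -> normalize/curate -> m53 ->
#' arm differential expression -> strand shift -> gene sets on seeded
#' synthetic cohorts, optionally writing machine-readable outputs. The run
#' is deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list with elements `classification`, `enrichment`,
#'   `m53`, `diffexp`, `strand_shift`, `genesets`, `truth`, and `summary`
#'   (a flat list of headline numbers).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))

  # -- mutation landscape: simulate, classify, test enrichment
  mut_cfg <- config$sim
  mut_cfg$seed <- .stage_seed(config$seed, 1L)
  mut_cfg$enriched_types <- if (length(config$sim$enriched_types) > 0)
    config$sim$enriched_types else "TT01"
  mut <- simulate_mutation_table(mut_cfg, config$hotspot)
  meta_flags <- mut$metadata
  calls <- classify_cohort(mut$mutations, mut$cna, meta_flags, config$hotspot)
  res_cfg <- config$resampling
  res_cfg$seed <- .stage_seed(config$seed, 2L)
  enrichment <- bootstrap_enrichment(calls, mut$metadata, res_cfg)

  # -- arm counts: simulate, normalize, curate, score
  cnt_cfg <- config$sim
  cnt_cfg$seed <- .stage_seed(config$seed, 3L)
  cohort <- simulate_cohort(cnt_cfg)
  norm <- normalize_counts(cohort$counts)
  mset <- curate_mirna_set(norm,
                           cohort$truth$loci$mirna_id[cohort$truth$loci$conserved])
  scores <- rank_within_cohort(m53_cohort(norm, mset, cohort$metadata))
  scores$genotype <- cohort$metadata$genotype[
    match(scores$sample_id, cohort$metadata$sample_id)]

  # -- arm-level differential expression: biallelic mutants vs wild type
  mutants <- cohort$metadata$sample_id[
    cohort$metadata$genotype == "HOTSPOT_BIALLELIC"]
  wt <- cohort$metadata$sample_id[cohort$metadata$genotype == "WT"]
  diffexp <- NULL
  shift <- NULL
  if (length(mutants) >= 2L && length(wt) >= 2L) {
    diffexp <- arm_diff_expression(cohort$counts, mutants, wt)
    shift <- strand_shift_test(diffexp)
  }

  # -- target gene sets on simulated gene statistics
  gs <- simulate_gene_statistics(seed = .stage_seed(config$seed, 4L))
  genesets <- geneset_permutation_test(gs$statistics, gs$sets,
                                       n_perm = config$n_perm,
                                       seed = .stage_seed(config$seed, 5L))

  summary <- list(
    seed = config$seed,
    version = as.character(utils::packageVersion("armshift")),
    n_samples = nrow(cohort$metadata),
    n_hotspot_calls = sum(calls$status %in% c("HOTSPOT", "HOTSPOT_BIALLELIC")),
    top_enriched_type = enrichment$tumor_type[which.min(enrichment$p_raw)],
    min_p_bonferroni = min(enrichment$p_bonferroni),
    mean_m53_wt = mean(scores$m53[scores$genotype == "WT"], na.rm = TRUE),
    mean_m53_biallelic = mean(scores$m53[scores$genotype == "HOTSPOT_BIALLELIC"],
                              na.rm = TRUE),
    n_arms_significant = if (!is.null(diffexp))
      sum(diffexp$fdr < config$de_fdr) else NA_integer_,
    strand_shift_p = if (!is.null(shift)) shift$p_value else NA_real_,
    top_gene_set = genesets$set_name[1L]
  )

  bundle <- list(classification = calls, enrichment = enrichment,
                 m53 = scores, diffexp = diffexp, strand_shift = shift,
                 genesets = genesets,
                 truth = list(mutation = mut$truth, cohort = cohort$truth,
                              genesets = gs$truth),
                 summary = summary)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) write.table(
      df, file.path(config$out_dir, name), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wr(calls, "classification.tsv")
    wr(enrichment, "enrichment.tsv")
    wr(scores, "m53_scores.tsv")
    if (!is.null(diffexp)) wr(diffexp, "arm_diffexp.tsv")
    wr(genesets, "genesets.tsv")
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(bundle)
}
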
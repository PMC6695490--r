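#' Synthetic-cohort configuration
#'
#' Parameters of the seeded generators that emulate the statistical
#' structure of tumor miRNA-seq cohorts with DICER1 genotype effects:
#' tissue-specific lognormal locus expression, per-locus 5p/3p duplex
#' asymmetry, negative-binomial over-dispersion with lognormal library
#' sizes, a multiplicative 5p-processing deficiency tied to genotype, and
#' mutation tables with background passengers, hypermutated samples, and
#' tumor-type-restricted hotspot planting.
#'
#' The deficiency factor delta multiplies expected 5p-arm counts only
#' (3p arms are untouched): hotspot carriers without a second hit get an
#' intermediate `delta_hotspot`, biallelic carriers the stronger
#' `delta_biallelic`, so the expected m53 gap of a genotype group versus
#' wild type is `log2(delta)`.
#'
#' @param n_loci Number of miRNA loci (hairpins), each with a 5p and 3p arm.
#' @param n_tumor_types,samples_per_type Cohort layout; tumor types act as
#'   pseudo-tissues with their own baseline expression profile.
#' @param expr_meanlog,expr_sdlog Lognormal baseline expression per locus
#'   per tissue.
#' @param frac5p_shape1,frac5p_shape2 Beta parameters for the per-locus 5p
#'   fraction of hairpin output.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mean + mean^2 * dispersion).
#' @param lib_meanlog,lib_sdlog Lognormal per-sample library-size factor.
#' @param genotype_freqs Baseline per-type genotype probabilities, named
#'   `WT, VUS, HOTSPOT, HOTSPOT_BIALLELIC`.
#' @param delta_hotspot,delta_biallelic 5p deficiency factors in `(0, 1]`.
#' @param enriched_types Tumor types (by name or index) whose hotspot and
#'   biallelic frequencies are multiplied by `enrichment_multiplier`.
#' @param enrichment_multiplier Hotspot enrichment factor for planted types.
#' @param hypermutated_rate Per-sample hypermutation probability.
#' @param passenger_rate Mean background passenger mutations per sample
#'   (non-DICER1 genes).
#' @param hypermut_passenger_multiplier Passenger multiplier in
#'   hypermutated samples.
#' @param conserved_fraction Fraction of loci flagged broadly conserved.
#' @param compensate If `TRUE`, each sample's expected counts are rescaled
#'   to its pre-deficiency total, emulating the uptake of lost 5p reads by
#'   3p reads under depth normalization. Off by default: the primary defect
#'   modeled is 5p depletion, not 3p gain.
#' @param seed Optional integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_loci = 60L, n_tumor_types = 4L,
                       samples_per_type = 60L,
                       expr_meanlog = log(200), expr_sdlog = 1.0,
                       frac5p_shape1 = 2, frac5p_shape2 = 2,
                       nb_dispersion = 0.15,
                       lib_meanlog = 0, lib_sdlog = 0.3,
                       genotype_freqs = c(WT = 0.86, VUS = 0.06,
                                          HOTSPOT = 0.04,
                                          HOTSPOT_BIALLELIC = 0.04),
                       delta_hotspot = 0.75, delta_biallelic = 0.5,
                       enriched_types = character(0),
                       enrichment_multiplier = 10,
                       hypermutated_rate = 0.05,
                       passenger_rate = 2,
                       hypermut_passenger_multiplier = 20,
                       conserved_fraction = 0.3,
                       compensate = FALSE,
                       seed = NULL) {
  cfg <- list(n_loci = as.integer(n_loci),
              n_tumor_types = as.integer(n_tumor_types),
              samples_per_type = as.integer(samples_per_type),
              expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
              frac5p_shape1 = frac5p_shape1, frac5p_shape2 = frac5p_shape2,
              nb_dispersion = nb_dispersion,
              lib_meanlog = lib_meanlog, lib_sdlog = lib_sdlog,
              genotype_freqs = genotype_freqs,
              delta_hotspot = delta_hotspot,
              delta_biallelic = delta_biallelic,
              enriched_types = enriched_types,
              enrichment_multiplier = enrichment_multiplier,
              hypermutated_rate = hypermutated_rate,
              passenger_rate = passenger_rate,
              hypermut_passenger_multiplier = hypermut_passenger_multiplier,
              conserved_fraction = conserved_fraction,
              compensate = isTRUE(compensate),
              seed = seed)
  with(cfg, {
    stopifnot(n_loci >= 2L, n_tumor_types >= 1L, samples_per_type >= 1L,
              expr_sdlog >= 0, frac5p_shape1 > 0, frac5p_shape2 > 0,
              nb_dispersion > 0, lib_sdlog >= 0,
              setequal(names(genotype_freqs),
                       c("WT", "VUS", "HOTSPOT", "HOTSPOT_BIALLELIC")),
              all(genotype_freqs >= 0), sum(genotype_freqs) > 0,
              delta_hotspot > 0, delta_hotspot <= 1,
              delta_biallelic > 0, delta_biallelic <= 1,
              enrichment_multiplier >= 1,
              hypermutated_rate >= 0, hypermutated_rate <= 1,
              passenger_rate >= 0, hypermut_passenger_multiplier >= 1,
              conserved_fraction >= 0, conserved_fraction <= 1)
  })
  structure(cfg, class = "sim_config")
}

.genotype_levels <- c("WT", "VUS", "HOTSPOT", "HOTSPOT_BIALLELIC")

# internal: per-type genotype probabilities with enrichment planting
.type_genotype_probs <- function(config, type_name, type_index) {
  p <- config$genotype_freqs[.genotype_levels]
  planted <- type_name %in% config$enriched_types ||
    type_index %in% config$enriched_types
  if (planted) {
    p[c("HOTSPOT", "HOTSPOT_BIALLELIC")] <-
      p[c("HOTSPOT", "HOTSPOT_BIALLELIC")] * config$enrichment_multiplier
  }
  list(probs = p / sum(p), planted = planted)
}

# internal: shared sample/genotype layout for both generators
.simulate_samples <- function(config) {
  types <- sprintf("TT%02d", seq_len(config$n_tumor_types))
  rows <- lapply(seq_along(types), function(t) {
    gp <- .type_genotype_probs(config, types[t], t)
    n <- config$samples_per_type
    data.frame(
      sample_id = sprintf("%s_S%03d", types[t], seq_len(n)),
      tumor_type = types[t],
      genotype = sample(.genotype_levels, n, replace = TRUE, prob = gp$probs),
      hypermutated = stats::runif(n) < config$hypermutated_rate,
      planted_enriched = gp$planted,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate an arm-count cohort with a planted 5p deficiency
#'
#' Draws a cohort of tumor samples with tissue-specific locus expression and
#' genotype-dependent 5p-arm deficiency. Expected counts are
#' `lib_s * expr[locus, tissue] * frac5p * delta_s` for 5p arms and
#' `lib_s * expr[locus, tissue] * (1 - frac5p)` for 3p arms; counts are
#' negative binomial with the configured dispersion. The same seed yields
#' identical output.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (arm count matrix), `metadata` (`sample_id,
#'   tumor_type, genotype, hypermutated`), and `truth` (list with `samples`
#'   incl. per-sample delta, `loci` incl. per-locus 5p fraction and
#'   conserved flag, and `enriched_types`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  loci <- sprintf("mir-%03d", seq_len(config$n_loci))
  frac5p <- stats::rbeta(config$n_loci, config$frac5p_shape1,
                         config$frac5p_shape2)
  conserved <- seq_len(config$n_loci) %in%
    sample.int(config$n_loci, round(config$conserved_fraction * config$n_loci))
  samples <- .simulate_samples(config)
  types <- unique(samples$tumor_type)
  expr <- matrix(stats::rlnorm(config$n_loci * length(types),
                               config$expr_meanlog, config$expr_sdlog),
                 nrow = config$n_loci, ncol = length(types),
                 dimnames = list(loci, types))
  delta <- c(WT = 1, VUS = 1, HOTSPOT = config$delta_hotspot,
             HOTSPOT_BIALLELIC = config$delta_biallelic)[samples$genotype]
  lib <- stats::rlnorm(nrow(samples), config$lib_meanlog, config$lib_sdlog)

  arm_ids <- c(rbind(paste0(loci, "|5p"), paste0(loci, "|3p")))
  counts <- matrix(0L, nrow = length(arm_ids), ncol = nrow(samples),
                   dimnames = list(arm_ids, samples$sample_id))
  size <- 1 / config$nb_dispersion
  for (j in seq_len(nrow(samples))) {
    base <- expr[, samples$tumor_type[j]]
    mu5 <- lib[j] * base * frac5p * delta[j]
    mu3 <- lib[j] * base * (1 - frac5p)
    if (config$compensate) {
      # put lost 5p mass back via global rescaling to pre-deficiency depth
      full <- sum(lib[j] * base)
      scale <- full / sum(mu5 + mu3)
      mu5 <- mu5 * scale
      mu3 <- mu3 * scale
    }
    counts[paste0(loci, "|5p"), j] <- stats::rnbinom(config$n_loci,
                                                     mu = mu5, size = size)
    counts[paste0(loci, "|3p"), j] <- stats::rnbinom(config$n_loci,
                                                     mu = mu3, size = size)
  }
  truth <- list(
    samples = data.frame(sample_id = samples$sample_id,
                         genotype = samples$genotype,
                         delta = unname(delta), stringsAsFactors = FALSE),
    loci = data.frame(mirna_id = loci, frac5p = frac5p, conserved = conserved,
                      stringsAsFactors = FALSE),
    enriched_types = unique(samples$tumor_type[samples$planted_enriched])
  )
  list(counts = validate_arm_counts(counts),
       metadata = samples[, c("sample_id", "tumor_type", "genotype",
                              "hypermutated")],
       truth = truth)
}

# amino acids for random substitutions (no ambiguity codes)
.aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# internal: one random non-hotspot DICER1 missense
.random_vus <- function(config_positions) {
  repeat {
    pos <- sample(300:1900, 1L)
    if (!as.character(pos) %in% names(config_positions)) break
  }
  aa <- sample(.aa, 2L)
  sprintf("%s%d%s", aa[1L], pos, aa[2L])
}

#' Simulate a somatic mutation table with planted genotypes
#'
#' Emits MAF-like mutation records, GISTIC-style copy-number calls, sample
#' metadata, and ground truth. Hotspot samples carry one hotspot missense;
#' biallelic samples additionally carry a second hit drawn among a
#' truncating mutation, a deep deletion, a heterozygous loss, or a distinct
#' second hotspot allele; VUS samples carry a non-hotspot DICER1 missense.
#' Background passenger mutations (non-truncating, non-DICER1 genes) are
#' added per sample, multiplied in hypermutated samples, so the planted
#' DICER1 genotype stays exactly recoverable by classification. The truth
#' genotype is the label expected with copy-loss evidence enabled; samples
#' whose only second hit is HETLOSS classify as `HOTSPOT` when copy-loss
#' evidence is disabled.
#'
#' @param config A [sim_config()].
#' @param hotspot_cfg The [hotspot_config()] whose residues are planted.
#' @param second_hit_probs Probabilities of each biallelic second-hit
#'   mechanism, named `truncating, deep_deletion, hetloss, second_hotspot`.
#' @return List with `mutations`, `cna`, `metadata`, `truth` (`samples` with
#'   genotype and `second_hit` mechanism, plus `enriched_types`).
#' @export
simulate_mutation_table <- function(config = sim_config(),
                                    hotspot_cfg = hotspot_config(),
                                    second_hit_probs = c(truncating = 0.5,
                                                         deep_deletion = 0.2,
                                                         hetloss = 0.15,
                                                         second_hotspot = 0.15)) {
  stopifnot(inherits(config, "sim_config"),
            setequal(names(second_hit_probs),
                     c("truncating", "deep_deletion", "hetloss",
                       "second_hotspot")))
  if (!is.null(config$seed)) set.seed(config$seed)
  samples <- .simulate_samples(config)
  pos_map <- hotspot_cfg$hotspot_positions
  hot_positions <- as.integer(names(pos_map))

  muts <- list()
  cna <- list()
  second_hit <- rep(NA_character_, nrow(samples))
  add_mut <- function(s, tt, change, vclass, gene = hotspot_cfg$gene) {
    muts[[length(muts) + 1L]] <<- data.frame(
      sample_id = s, gene = gene, protein_change = change,
      variant_class = vclass, tumor_type = tt, stringsAsFactors = FALSE)
  }
  hotspot_allele <- function() {
    i <- sample(length(hot_positions), 1L)
    alt <- sample(setdiff(.aa, pos_map[i]), 1L)
    sprintf("%s%d%s", pos_map[i], hot_positions[i], alt)
  }
  for (j in seq_len(nrow(samples))) {
    s <- samples$sample_id[j]; tt <- samples$tumor_type[j]
    g <- samples$genotype[j]
    if (g == "VUS") add_mut(s, tt, .random_vus(pos_map), "missense")
    if (g %in% c("HOTSPOT", "HOTSPOT_BIALLELIC")) {
      allele1 <- hotspot_allele()
      add_mut(s, tt, allele1, "missense")
    }
    if (g == "HOTSPOT_BIALLELIC") {
      mech <- sample(names(second_hit_probs), 1L, prob = second_hit_probs)
      second_hit[j] <- mech
      if (mech == "truncating") {
        kind <- sample(c("nonsense", "frameshift_indel", "splice_site"), 1L)
        pos <- sample(300:1900, 1L)
        change <- switch(kind,
          nonsense = sprintf("%s%d*", sample(.aa, 1L), pos),
          frameshift_indel = sprintf("%s%dRfs*%d", sample(.aa, 1L), pos,
                                     sample(3:30, 1L)),
          splice_site = sprintf("X%d_splice", pos))
        add_mut(s, tt, change, kind)
      } else if (mech == "deep_deletion") {
        cna[[length(cna) + 1L]] <- data.frame(
          sample_id = s, gene = hotspot_cfg$gene, call = -2L,
          stringsAsFactors = FALSE)
      } else if (mech == "hetloss") {
        cna[[length(cna) + 1L]] <- data.frame(
          sample_id = s, gene = hotspot_cfg$gene, call = -1L,
          stringsAsFactors = FALSE)
      } else { # distinct second hotspot allele at the same or another residue
        repeat {
          allele2 <- hotspot_allele()
          if (allele2 != allele1) break
        }
        add_mut(s, tt, allele2, "missense")
      }
    }
    # background passengers in other genes: never truncating DICER1
    lambda <- config$passenger_rate *
      if (samples$hypermutated[j]) config$hypermut_passenger_multiplier else 1
    n_pass <- stats::rpois(1L, lambda)
    if (n_pass > 0L) {
      for (k in seq_len(n_pass)) {
        aa <- sample(.aa, 2L)
        add_mut(s, tt,
                sprintf("%s%d%s", aa[1L], sample(10:900, 1L), aa[2L]),
                sample(c("missense", "silent"), 1L, prob = c(0.7, 0.3)),
                gene = sprintf("GENE%04d", sample.int(5000L, 1L)))
      }
    }
  }
  mutations <- if (length(muts) > 0L) do.call(rbind, muts) else
    data.frame(sample_id = character(0), gene = character(0),
               protein_change = character(0), variant_class = character(0),
               tumor_type = character(0), stringsAsFactors = FALSE)
  cna <- if (length(cna) > 0L) do.call(rbind, cna) else
    data.frame(sample_id = character(0), gene = character(0),
               call = integer(0), stringsAsFactors = FALSE)
  truth <- list(
    samples = data.frame(sample_id = samples$sample_id,
                         tumor_type = samples$tumor_type,
                         genotype = samples$genotype,
                         hypermutated = samples$hypermutated,
                         second_hit = second_hit, stringsAsFactors = FALSE),
    enriched_types = unique(samples$tumor_type[samples$planted_enriched])
  )
  list(mutations = mutations, cna = cna,
       metadata = samples[, c("sample_id", "tumor_type", "hypermutated")],
       truth = truth)
}

#' Simulate gene-level statistics with planted target sets
#'
#' Background gene statistics (e.g. log fold changes) are Normal(0, sigma);
#' genes of the planted sets are shifted upward by `effect`, emulating
#' derepression of the targets of a 5p-depleted miRNA family. Sets are
#' disjoint so the planted signal is unambiguous.
#'
#' @param n_genes Universe size.
#' @param n_sets Number of family target sets (disjoint, equal size).
#' @param set_size Genes per set.
#' @param n_planted Number of sets receiving the shift (the first ones).
#' @param effect Upward shift added to planted-set genes.
#' @param sigma Background standard deviation.
#' @param seed Optional integer seed.
#' @return List with `statistics` (named numeric, gene -> statistic), `sets`
#'   (named list), and `truth` (`planted` set names, `effect`).
#' @export
simulate_gene_statistics <- function(n_genes = 2000L, n_sets = 8L,
                                     set_size = 50L, n_planted = 1L,
                                     effect = 1, sigma = 1, seed = NULL) {
  stopifnot(n_sets * set_size <= n_genes, n_planted <= n_sets, sigma > 0)
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("GENE%05d", seq_len(n_genes))
  statistics <- setNames(stats::rnorm(n_genes, 0, sigma), genes)
  member_pool <- sample(genes, n_sets * set_size)
  sets <- split(member_pool, rep(seq_len(n_sets), each = set_size))
  names(sets) <- sprintf("miR-family-%02d_targets", seq_len(n_sets))
  planted <- names(sets)[seq_len(n_planted)]
  for (nm in planted) statistics[sets[[nm]]] <-
    statistics[sets[[nm]]] + effect
  list(statistics = statistics, sets = sets,
       truth = list(planted = planted, effect = effect))
}
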
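#' Resampling-test configuration
#'
#' @param n_replicates Number of bootstrap replicates (default 10,000).
#' @param min_cohort_size Tumor types are tested only when their eligible
#'   sample count is strictly greater than this (default 50): smaller
#'   cohorts are too narrow for a stable null.
#' @param include_hypermutated Whether hypermutated samples enter the
#'   eligible pool and the per-type observed counts. The conservative first
#'   pass excludes them; a second pass including them is also standard.
#' @param alpha_ci Two-sided percentile-interval level for depletion calls.
#' @param min_null_mean Minimum mean of the null hotspot count for the null
#'   to be treated as approximately normal; below it no depletion is called.
#' @param seed Optional integer seed making the replicate draws reproducible.
#' @return A `resampling_config` list.
#' @export
resampling_config <- function(n_replicates = 10000L, min_cohort_size = 50L,
                              include_hypermutated = FALSE, alpha_ci = 0.05,
                              min_null_mean = 5, seed = NULL) {
  stopifnot(n_replicates >= 1L, min_cohort_size >= 1L,
            alpha_ci > 0, alpha_ci < 1)
  structure(list(n_replicates = as.integer(n_replicates),
                 min_cohort_size = as.integer(min_cohort_size),
                 include_hypermutated = isTRUE(include_hypermutated),
                 alpha_ci = alpha_ci, min_null_mean = min_null_mean,
                 seed = seed),
            class = "resampling_config")
}

#' Exact tail probability of the bootstrap null
#'
#' Under with-replacement resampling of `n` samples from a pool with hotspot
#' rate `rate`, the null count is Binomial(`n`, `rate`); this returns the
#' exact strict upper tail `P(X > observed)`. Used as the analytic oracle
#' for [bootstrap_enrichment()].
#'
#' @param n Cohort size resampled per replicate.
#' @param rate Pool hotspot rate in `[0, 1]`.
#' @param observed Observed hotspot count.
#' @return `P(X > observed)`.
#' @export
exact_binomial_tail <- function(n, rate, observed) {
  stopifnot(rate >= 0, rate <= 1, observed >= 0, observed <= n)
  stats::pbinom(observed, size = n, prob = rate, lower.tail = FALSE)
}

#' Percentile-interval depletion call
#'
#' Computes the `alpha/2` and `1 - alpha/2` percentile bounds of the null
#' count distribution and calls a tumor type depleted when its observed
#' count falls below the lower bound. Because a percentile interval is only
#' reliable when the resampling null is approximately normal, the call is
#' additionally gated on the null mean reaching `min_null_mean`.
#'
#' @param null_counts Bootstrap null counts.
#' @param observed Observed hotspot count.
#' @param alpha_ci Two-sided interval level.
#' @param min_null_mean Normality guard on the null mean.
#' @return List `ci_low, ci_high, depleted, normality_ok`.
#' @export
depletion_call <- function(null_counts, observed, alpha_ci = 0.05,
                           min_null_mean = 5) {
  stopifnot(length(null_counts) > 0L)
  qs <- unname(stats::quantile(null_counts,
                               probs = c(alpha_ci / 2, 1 - alpha_ci / 2)))
  normality_ok <- mean(null_counts) >= min_null_mean
  list(ci_low = qs[1L], ci_high = qs[2L],
       depleted = normality_ok && observed < qs[1L],
       normality_ok = normality_ok)
}

#' Bootstrap test for tumor-type enrichment of hotspot genotypes
#'
#' For every tumor type whose eligible sample count exceeds
#' `config$min_cohort_size`, draws that many samples with replacement from
#' the pooled eligible samples of all tested types, per replicate, and
#' counts how many draws are hotspot carriers. The raw enrichment p-value is
#' the fraction of replicates whose count strictly exceeds the observed
#' count; the add-one companion `(r + 1) / (B + 1)` is always reported so
#' degenerate `p = 0` outputs stay interpretable. P-values are
#' Bonferroni-corrected across tested types, and percentile-interval
#' depletion calls are attached.
#'
#' @param genotype_calls Data frame from [classify_cohort()] (columns
#'   `sample_id, status, hypermutated`; a sample is a hotspot carrier when
#'   its status is `HOTSPOT` or `HOTSPOT_BIALLELIC`).
#' @param metadata Data frame with `sample_id` and `tumor_type` for every
#'   call.
#' @param config A [resampling_config()].
#' @return Data frame with one row per tested tumor type: `tumor_type,
#'   n_samples, observed_hotspots, null_mean, p_raw, p_raw_plus_one,
#'   p_bonferroni, ci_low, ci_high, depleted, normality_ok`.
#' @export
bootstrap_enrichment <- function(genotype_calls, metadata,
                                 config = resampling_config()) {
  calls <- genotype_calls
  calls$tumor_type <- metadata$tumor_type[match(calls$sample_id,
                                                metadata$sample_id)]
  if (anyNA(calls$tumor_type)) stop("metadata must cover every sample")
  if (!config$include_hypermutated)
    calls <- calls[!calls$hypermutated, , drop = FALSE]
  calls$hot <- calls$status %in% c("HOTSPOT", "HOTSPOT_BIALLELIC")

  sizes <- table(calls$tumor_type)
  tested <- names(sizes)[sizes > config$min_cohort_size]
  if (length(tested) == 0L) stop("no tumor type exceeds min_cohort_size")
  pool <- calls$hot[calls$tumor_type %in% tested]
  if (length(pool) < 2L) stop("eligible pool has fewer than 2 samples")

  if (!is.null(config$seed)) set.seed(config$seed)
  B <- config$n_replicates
  rows <- lapply(tested, function(tt) {
    n_t <- as.integer(sizes[[tt]])
    observed <- sum(calls$hot[calls$tumor_type == tt])
    draws <- sample.int(length(pool), n_t * B, replace = TRUE)
    m <- colSums(matrix(pool[draws], nrow = n_t, ncol = B))
    p_raw <- sum(m > observed) / B
    dep <- depletion_call(m, observed, config$alpha_ci, config$min_null_mean)
    data.frame(tumor_type = tt, n_samples = n_t,
               observed_hotspots = observed, null_mean = mean(m),
               p_raw = p_raw,
               p_raw_plus_one = (sum(m > observed) + 1) / (B + 1),
               ci_low = dep$ci_low, ci_high = dep$ci_high,
               depleted = dep$depleted, normality_ok = dep$normality_ok,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_raw * nrow(out))
  out[, c("tumor_type", "n_samples", "observed_hotspots", "null_mean",
          "p_raw", "p_raw_plus_one", "p_bonferroni", "ci_low", "ci_high",
          "depleted", "normality_ok")]
}
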
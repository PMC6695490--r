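#' Filter miRNA target predictions
#'
#' Keeps predictions whose site conservation is at least `min_conservation`
#' percent and whose context score is strictly below `context_cutoff`
#' (context scores are more negative for stronger predicted repression; the
#' default cutoff selects roughly the strongest 5% of sites). Ties exactly
#' at the cutoff are excluded.
#'
#' @param predictions Data frame with columns `gene, mirna, conservation,
#'   context_score` (conservation as a percentage in `[0, 100]`).
#' @param min_conservation Conservation floor (inclusive).
#' @param context_cutoff Context-score ceiling (exclusive).
#' @return The filtered data frame.
#' @export
filter_predictions <- function(predictions, min_conservation = 90,
                               context_cutoff = -0.3555) {
  stopifnot(all(c("gene", "mirna", "conservation", "context_score") %in%
                  names(predictions)))
  if (nrow(predictions) > 0L &&
      (any(predictions$conservation < 0) || any(predictions$conservation > 100)))
    stop("conservation must be a percentage in [0, 100]")
  keep <- predictions$conservation >= min_conservation &
    predictions$context_score < context_cutoff
  predictions[keep, , drop = FALSE]
}

#' Aggregate filtered predictions into family target sets
#'
#' Members of one miRNA family share a seed and hence targets; predictions
#' for all family members are pooled and deduplicated into one gene set per
#' family. Sets smaller than `min_set_size` are dropped with a warning.
#'
#' @param filtered Output of [filter_predictions()].
#' @param family_map Named character vector mapping miRNA ids to family
#'   labels; miRNAs absent from the map are skipped with a warning.
#' @param min_set_size Minimum retained set size.
#' @return Named list of unique gene vectors, one per family.
#' @export
build_family_sets <- function(filtered, family_map, min_set_size = 5L) {
  if (nrow(filtered) == 0L) return(setNames(list(), character(0)))
  fam <- family_map[filtered$mirna]
  if (anyNA(fam)) {
    warning("dropping ", sum(is.na(fam)),
            " prediction(s) for miRNAs without a family mapping", call. = FALSE)
    filtered <- filtered[!is.na(fam), , drop = FALSE]
    fam <- fam[!is.na(fam)]
  }
  sets <- lapply(split(filtered$gene, fam), function(g) unique(g))
  small <- vapply(sets, length, integer(1)) < min_set_size
  if (any(small)) {
    warning("dropping ", sum(small), " set(s) below min_set_size: ",
            paste(names(sets)[small], collapse = ", "), call. = FALSE)
    sets <- sets[!small]
  }
  sets
}

#' Competitive permutation test for gene-set enrichment
#'
#' For each set, the observed statistic is the mean gene-level statistic
#' (e.g. log fold change) over the set's genes present in the universe; the
#' null is the mean over `n_perm` random draws of the same number of genes
#' from the universe. The one-sided upward p-value uses the add-one
#' estimator `p_up = (#{null >= observed} + 1) / (n_perm + 1)`; FDR is
#' BH-adjusted across sets.
#'
#' @param gene_statistics Named numeric vector: gene -> statistic. The gene
#'   universe is the set of names.
#' @param sets Named list of gene vectors; sets with fewer than 2 genes in
#'   the universe are skipped with a warning.
#' @param n_perm Number of permutation draws.
#' @param seed Optional integer seed.
#' @return Data frame `set_name, size, mean_statistic, p_up, fdr, direction`,
#'   sorted by `p_up`.
#' @export
geneset_permutation_test <- function(gene_statistics, sets, n_perm = 10000L,
                                     seed = NULL) {
  stopifnot(!is.null(names(gene_statistics)), length(gene_statistics) > 1L)
  if (!is.null(seed)) set.seed(seed)
  universe <- names(gene_statistics)
  stats_vec <- unname(gene_statistics)
  rows <- list()
  for (nm in names(sets)) {
    members <- intersect(sets[[nm]], universe)
    if (length(members) < 2L) {
      warning("skipping set '", nm, "': fewer than 2 genes in universe",
              call. = FALSE)
      next
    }
    k <- length(members)
    obs <- mean(gene_statistics[members])
    # random same-size gene sets: draws without replacement within a draw
    null_means <- vapply(seq_len(n_perm), function(i)
      mean(stats_vec[sample.int(length(stats_vec), k)]), numeric(1))
    p_up <- (sum(null_means >= obs) + 1) / (n_perm + 1)
    rows[[nm]] <- data.frame(
      set_name = nm, size = k, mean_statistic = obs, p_up = p_up,
      direction = sign(obs - mean(stats_vec)), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(set_name = character(0), size = integer(0),
                      mean_statistic = numeric(0), p_up = numeric(0),
                      fdr = numeric(0), direction = numeric(0)))
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p_up)
  out <- out[order(out$p_up), c("set_name", "size", "mean_statistic",
                                "p_up", "fdr", "direction")]
  rownames(out) <- NULL
  out
}

#' Write / read gene sets in GMT format
#'
#' One set per line: name, description (the set name again), then member
#' genes, tab-separated.
#'
#' @param sets Named list of gene vectors.
#' @param path File path.
#' @return The path (writer) or a named list of gene vectors (reader).
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(parts, function(x) x[-(1:2)]),
           vapply(parts, `[[`, character(1), 1L))
}
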
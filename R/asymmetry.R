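#' Per-sample m53 arm-asymmetry score
#'
#' For one sample, `m5` is the median normalized expression over the 5p arms
#' of the curated miRNA set, `m3` the median over the 3p arms, and
#' `m53 = log2(m5 / m3)`. Medians are taken over linear-scale normalized
#' values with no pseudocount (even-length medians are the midpoint mean),
#' so the score is exactly invariant to per-sample rescaling. A zero median
#' on either arm leaves the score undefined and raises an error naming the
#' sample rather than silently imputing.
#'
#' @param normalized Normalized arm matrix (rows `"mirnaID|arm"`).
#' @param mirna_set A [curate_mirna_set()] result, or a character vector of
#'   locus ids; every member must have both arms in the matrix.
#' @param sample Sample (column) identifier.
#' @return List with `sample_id`, `m5`, `m3`, `m53`.
#' @export
m53_score <- function(normalized, mirna_set, sample) {
  ids <- if (is.data.frame(mirna_set)) mirna_set$mirna_id else mirna_set
  stopifnot(length(ids) > 0L)
  rows5 <- paste0(ids, "|5p")
  rows3 <- paste0(ids, "|3p")
  missing <- setdiff(c(rows5, rows3), rownames(normalized))
  if (length(missing) > 0L)
    stop("arms missing from matrix: ", paste(missing, collapse = ", "))
  m5 <- median(normalized[rows5, sample])
  m3 <- median(normalized[rows3, sample])
  if (m5 <= 0 || m3 <= 0)
    stop("m53 undefined for sample '", sample,
         "': zero median ", if (m5 <= 0) "5p" else "3p", " expression")
  list(sample_id = sample, m5 = m5, m3 = m3, m53 = log2(m5 / m3))
}

#' m53 scores for a cohort
#'
#' Computes [m53_score()] for every sample, joining tumor-type labels from
#' the metadata. Samples whose score is undefined (zero arm median) are kept
#' in the output with `NA` score and `defined = FALSE` rather than dropped.
#'
#' @param normalized Normalized arm matrix.
#' @param mirna_set Curated miRNA set.
#' @param metadata Data frame with `sample_id` and `tumor_type` covering all
#'   columns of `normalized`.
#' @return Data frame `sample_id, tumor_type, m5, m3, m53, defined`.
#' @export
m53_cohort <- function(normalized, mirna_set, metadata) {
  samples <- colnames(normalized)
  stopifnot(all(samples %in% metadata$sample_id))
  rows <- lapply(samples, function(s) {
    sc <- tryCatch(m53_score(normalized, mirna_set, s), error = function(e) NULL)
    if (is.null(sc))
      data.frame(sample_id = s, m5 = NA_real_, m3 = NA_real_, m53 = NA_real_,
                 defined = FALSE, stringsAsFactors = FALSE)
    else
      data.frame(sample_id = s, m5 = sc$m5, m3 = sc$m3, m53 = sc$m53,
                 defined = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$tumor_type <- metadata$tumor_type[match(out$sample_id, metadata$sample_id)]
  out[, c("sample_id", "tumor_type", "m5", "m3", "m53", "defined")]
}

#' Rank m53 scores within each tumor cohort
#'
#' Dense ascending ranks of `m53` within tumor type (rank 1 = lowest score;
#' ties share a rank). The per-type minimum is flagged, matching the
#' observation that biallelic hotspot cases typically sit at the bottom of
#' their cohort.
#'
#' @param scores Output of [m53_cohort()]; undefined scores rank `NA`.
#' @return `scores` with added `rank` and `is_min` columns.
#' @export
rank_within_cohort <- function(scores) {
  scores$rank <- NA_integer_
  scores$is_min <- NA
  for (tt in unique(scores$tumor_type)) {
    idx <- which(scores$tumor_type == tt & scores$defined)
    if (length(idx) == 0L) next
    vals <- scores$m53[idx]
    lev <- sort(unique(vals))
    scores$rank[idx] <- match(vals, lev)          # dense ranks
    scores$is_min[idx] <- scores$rank[idx] == 1L
  }
  scores
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up: for sorted p-values, `adj_(i) = min_(j >= i)
#' p_(j) * n / j`, capped at 1, returned in the original order. Implemented
#' directly so its algebra is visible to the property tests.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(p_values)
  o <- order(p_values)
  sorted <- p_values[o]
  adj <- pmin(1, rev(cummin(rev(sorted * n / seq_len(n)))))
  out <- numeric(n)
  out[o] <- adj
  out
}

#' Arm-level differential expression between two sample groups
#'
#' Counts are normalized jointly over both groups (median-of-ratios), then
#' each arm is tested with Welch's two-sample t-test on
#' `log2(normalized + 1)`. The reported fold change is
#' `log2((mean_A + 1) / (mean_B + 1))` of normalized means. Arms with zero
#' variance in both groups get `p = 1`. P-values are BH-adjusted; the
#' conventional significance call in this pipeline is FDR < 0.01.
#'
#' @param counts Raw arm count matrix covering both groups.
#' @param groupA_ids,groupB_ids Sample identifiers (each of length >= 2).
#' @return Data frame `arm_id, arm, log2_fold_change, p_value, fdr` (one row
#'   per arm).
#' @export
arm_diff_expression <- function(counts, groupA_ids, groupB_ids) {
  stopifnot(length(groupA_ids) >= 2L, length(groupB_ids) >= 2L,
            all(c(groupA_ids, groupB_ids) %in% colnames(counts)))
  norm <- normalize_counts(counts[, c(groupA_ids, groupB_ids), drop = FALSE])
  lg <- log2(norm + 1)
  a <- lg[, groupA_ids, drop = FALSE]
  b <- lg[, groupB_ids, drop = FALSE]
  res <- lapply(seq_len(nrow(lg)), function(i) {
    va <- a[i, ]; vb <- b[i, ]
    lfc <- log2((mean(norm[i, groupA_ids]) + 1) / (mean(norm[i, groupB_ids]) + 1))
    p <- if (stats::var(va) == 0 && stats::var(vb) == 0) {
      1
    } else {
      tryCatch(stats::t.test(va, vb)$p.value, error = function(e) 1)
    }
    c(lfc = lfc, p = p)
  })
  res <- do.call(rbind, res)
  parts <- .split_arm_id(rownames(counts))
  data.frame(arm_id = rownames(counts), arm = parts$arm,
             log2_fold_change = res[, "lfc"], p_value = res[, "p"],
             fdr = bh_adjust(res[, "p"]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Strand-shift test: do 5p arms move differently from 3p arms?
#'
#' Two-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction) comparing the log fold changes of 5p arms against those of 3p
#' arms from an [arm_diff_expression()] result. A negative direction means
#' 5p arms are shifted down relative to 3p arms, the signature of impaired
#' 5p-arm processing.
#'
#' @param de_results Output of [arm_diff_expression()].
#' @return List with `statistic` (rank-sum W), `p_value`, and `direction`
#'   (sign of `median(5p logFC) - median(3p logFC)`).
#' @export
strand_shift_test <- function(de_results) {
  lfc5 <- de_results$log2_fold_change[de_results$arm == "5p"]
  lfc3 <- de_results$log2_fold_change[de_results$arm == "3p"]
  if (length(lfc5) < 2L || length(lfc3) < 2L)
    stop("need at least two arms per strand class")
  if (length(unique(c(lfc5, lfc3))) == 1L) {
    # every value tied: no evidence of shift in either direction
    return(list(statistic = length(lfc5) * length(lfc3) / 2, p_value = 1,
                direction = 0))
  }
  wt <- suppressWarnings(stats::wilcox.test(lfc5, lfc3, exact = FALSE,
                                            correct = TRUE))
  p <- wt$p.value
  if (is.na(p)) p <- 1
  list(statistic = unname(wt$statistic), p_value = p,
       direction = sign(median(lfc5) - median(lfc3)))
}
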
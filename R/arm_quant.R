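#' Extend arm intervals by a symmetric flank
#'
#' Mature-arm read counting uses annotation intervals widened by a small
#' flank on either side (default 2 nt, i.e. 4 extra nt per arm) so reads
#' with templated end heterogeneity are still captured. Coordinates are the
#' internal 0-based half-open convention; starts are clipped at 0.
#'
#' @param annotations Arm annotation data frame (see [read_mirna_gff()]).
#' @param flank Non-negative flank width in nucleotides.
#' @return The annotations with widened `start`/`end`.
#' @export
extend_arm_intervals <- function(annotations, flank = 2L) {
  stopifnot(flank >= 0)
  annotations$start <- pmax(0L, annotations$start - as.integer(flank))
  annotations$end <- annotations$end + as.integer(flank)
  annotations
}

#' Toy overlap counter assigning reads to miRNA arms
#'
#' A deliberately simple stand-in for a full-featured read counter, used for
#' small demonstrations and tests: a read increments an arm when it overlaps
#' it by at least 1 bp on the same chromosome (strand-agnostic); a read
#' overlapping several arms goes to the arm with the largest overlap, with
#' ties broken in favor of the 5p arm (then annotation order).
#'
#' @param read_intervals Data frame with columns
#'   `chrom, start, end, strand, sample` (0-based half-open).
#' @param annotations Arm annotations, typically after
#'   [extend_arm_intervals()].
#' @return An arm count matrix (all annotated arms x all samples seen).
#' @export
count_reads_to_arms <- function(read_intervals, annotations) {
  arm_ids <- paste0(annotations$mirna_id, "|", annotations$arm)
  samples <- unique(as.character(read_intervals$sample))
  counts <- matrix(0L, nrow = length(arm_ids), ncol = length(samples),
                   dimnames = list(arm_ids, samples))
  for (i in seq_len(nrow(read_intervals))) {
    r <- read_intervals[i, ]
    ov <- ifelse(annotations$chrom == r$chrom,
                 pmin(annotations$end, r$end) - pmax(annotations$start, r$start),
                 0L)
    ov[ov < 0L] <- 0L
    if (all(ov == 0L)) next
    best <- which(ov == max(ov))
    if (length(best) > 1L) {
      is5 <- annotations$arm[best] == "5p"
      best <- if (any(is5)) best[is5][1L] else best[1L]
    }
    s <- as.character(r$sample)
    counts[best, s] <- counts[best, s] + 1L
  }
  validate_arm_counts(counts)
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed as the median, over arms whose counts
#' are positive in every sample, of the ratio of each sample's count to the
#' arm's geometric mean across samples. Factors are rescaled to geometric
#' mean 1 for identifiability; normalization divides each sample's column by
#' its factor.
#'
#' @param counts Arm count matrix (arms x samples).
#' @return Positive numeric vector of per-sample size factors (geometric
#'   mean 1), named by sample.
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts), ncol(counts) >= 1L)
  allpos <- rowSums(counts <= 0) == 0L
  if (!any(allpos))
    stop("no arm has positive counts in every sample; ",
         "median-of-ratios is undefined (consider a pseudo-reference fallback)")
  lc <- log(counts[allpos, , drop = FALSE])
  ref <- rowMeans(lc)                    # log geometric mean per arm
  sf <- exp(apply(lc - ref, 2L, median))
  sf <- sf / exp(mean(log(sf)))          # geometric mean 1
  setNames(sf, colnames(counts))
}

#' Normalize counts by size factors
#'
#' @param counts Arm count matrix.
#' @param sf Size factors from [size_factors()] (computed when missing).
#' @return Numeric matrix `counts[, j] / sf[j]`, with the factors attached
#'   as attribute `size_factors`.
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  stopifnot(all(sf > 0), length(sf) == ncol(counts))
  norm <- sweep(counts, 2L, sf, "/")
  attr(norm, "size_factors") <- sf
  norm
}

#' Collapse loci with identical mature products
#'
#' Several miRNA genes produce byte-identical 5p and 3p mature species
#' (e.g. the three mir-124 loci); for arm-level analysis these are treated
#' as a single locus whose counts are the sum over group members.
#'
#' @param counts Arm count matrix with `"mirnaID|arm"` rownames.
#' @param collapse_groups Named character vector mapping `mirna_id` to a
#'   group label; loci absent from the map are kept as-is. Group members
#'   must have identical arm structure (same set of annotated arms).
#' @return Collapsed count matrix with group labels as locus identifiers.
#' @export
collapse_identical_loci <- function(counts, collapse_groups = NULL) {
  if (is.null(collapse_groups) || length(collapse_groups) == 0L) return(counts)
  parts <- .split_arm_id(rownames(counts))
  grp <- collapse_groups[parts$mirna_id]
  grp[is.na(grp)] <- parts$mirna_id[is.na(grp)]
  # discordant arm structure within a group is an annotation error
  for (g in unique(grp[parts$mirna_id %in% names(collapse_groups)])) {
    members <- unique(parts$mirna_id[grp == g])
    armsets <- lapply(members, function(m) sort(parts$arm[parts$mirna_id == m]))
    if (length(unique(armsets)) > 1L)
      stop("collapse group '", g, "' members have discordant arm structure")
  }
  new_id <- paste0(grp, "|", parts$arm)
  out <- rowsum(counts, group = new_id, reorder = FALSE)
  storage.mode(out) <- "integer"
  validate_arm_counts(out)
}

#' Curate the analysis miRNA set
#'
#' A locus enters the analysis set if it is broadly expressed (mean over
#' samples of `log2(locus expression + 1)` at least `min_mean_log2`, where
#' locus expression is the sum of the locus's normalized 5p and 3p values)
#' or broadly conserved (member of `conserved_ids` with both arms present in
#' the matrix). The union is returned with per-member provenance.
#'
#' @param normalized Normalized arm matrix (both arms of each candidate
#'   locus must be rows).
#' @param conserved_ids Character vector of broadly conserved locus ids.
#' @param min_mean_log2 Expression threshold on the mean log2 scale
#'   (inclusive).
#' @return Data frame of class `MirnaSet` with columns `mirna_id` and
#'   `provenance` (`"expressed"`, `"conserved"`, or `"both"`).
#' @export
curate_mirna_set <- function(normalized, conserved_ids = character(0),
                             min_mean_log2 = 5) {
  parts <- .split_arm_id(rownames(normalized))
  loci <- unique(parts$mirna_id)
  both <- vapply(loci, function(m)
    all(c("5p", "3p") %in% parts$arm[parts$mirna_id == m]), logical(1))
  loci <- loci[both]
  if (length(loci) == 0L) stop("no locus has both arms in the matrix")
  mean_log2 <- vapply(loci, function(m) {
    expr <- normalized[paste0(m, "|5p"), ] + normalized[paste0(m, "|3p"), ]
    mean(log2(expr + 1))
  }, numeric(1))
  expressed <- loci[mean_log2 >= min_mean_log2]
  conserved <- intersect(conserved_ids, loci)
  members <- union(expressed, conserved)
  if (length(members) == 0L)
    stop("curated miRNA set is empty; downstream medians would be undefined")
  provenance <- ifelse(members %in% expressed & members %in% conserved, "both",
                       ifelse(members %in% expressed, "expressed", "conserved"))
  structure(data.frame(mirna_id = members, provenance = provenance,
                       stringsAsFactors = FALSE),
            class = c("MirnaSet", "data.frame"))
}
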
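#' Hotspot classification configuration
#'
#' Defines the gene and residue set used to call hotspot alleles, and how
#' hypermutated samples are flagged. The default residues are the DICER1
#' RNase IIIb metal-ion-binding catalytic residues (E1705, D1709, D1810,
#' E1813), the adjacent recurrent G1809, and the RNase IIIa interface residue
#' S1344 whose recurrent substitution phenocopies RNase IIIb hotspots.
#'
#' @param gene Gene symbol to which classification is restricted.
#' @param hotspot_positions Named character vector: names are residue numbers,
#'   values the expected reference amino acid (one letter).
#' @param hypermutation_rule `"metadata_flag"` (use the `hypermutated` column
#'   of the sample metadata) or `"mutation_count"` (flag samples whose
#'   nonsilent mutation burden exceeds `hypermutation_threshold`).
#' @param hypermutation_threshold Nonsilent mutations per sample above which
#'   a sample is flagged under the count rule.
#' @param use_copy_loss Whether heterozygous copy-number loss (GISTIC -1,
#'   "HETLOSS") is eligible second-hit evidence. Enable for TCGA-like data;
#'   disable for targeted panels underpowered to call copy loss. Deep
#'   deletions (-2) are always eligible.
#' @return A `hotspot_config` list.
#' @export
hotspot_config <- function(gene = "DICER1",
                           hotspot_positions = c(`1705` = "E", `1709` = "D",
                                                 `1809` = "G", `1810` = "D",
                                                 `1813` = "E", `1344` = "S"),
                           hypermutation_rule = c("metadata_flag", "mutation_count"),
                           hypermutation_threshold = 1000L,
                           use_copy_loss = TRUE) {
  hypermutation_rule <- match.arg(hypermutation_rule)
  pos <- as.integer(names(hotspot_positions))
  stopifnot(all(pos > 0L), all(nchar(hotspot_positions) == 1L),
            hypermutation_threshold >= 1L)
  structure(list(gene = gene,
                 hotspot_positions = setNames(unname(hotspot_positions),
                                              as.character(pos)),
                 hypermutation_rule = hypermutation_rule,
                 hypermutation_threshold = as.integer(hypermutation_threshold),
                 use_copy_loss = isTRUE(use_copy_loss)),
            class = "hotspot_config")
}

#' Parse an HGVSp-short protein change
#'
#' Recognizes missense (`S1344L`), nonsense (`E1705*`), frameshift
#' (`K1140Rfs*5`), and splice (`X1843_splice`) notations. Anything else
#' yields `kind = "other"` with `position = NA`.
#'
#' @param hgvsp Protein-change string (a leading `"p."` prefix is tolerated).
#' @return List with `ref_aa`, `position`, `kind` (one of `missense`,
#'   `nonsense`, `frameshift`, `splice`, `other`), and `alt_aa`.
#' @export
parse_protein_change <- function(hgvsp) {
  stopifnot(is.character(hgvsp), length(hgvsp) == 1L, nzchar(hgvsp))
  s <- sub("^p\\.", "", hgvsp)
  out <- list(ref_aa = NA_character_, position = NA_integer_,
              kind = "other", alt_aa = NA_character_)
  if (grepl("^X?([0-9]+)_splice$", s) || grepl("^[A-Z][0-9]+_splice$", s)) {
    out$position <- as.integer(gsub("[^0-9]", "", sub("_splice$", "", s)))
    out$kind <- "splice"
  } else if (grepl("^[A-Z][0-9]+[A-Za-z]*fs", s)) {
    out$ref_aa <- substr(s, 1L, 1L)
    out$position <- as.integer(sub("^[A-Z]([0-9]+).*$", "\\1", s))
    out$kind <- "frameshift"
  } else if (grepl("^[A-Z][0-9]+\\*$", s)) {
    out$ref_aa <- substr(s, 1L, 1L)
    out$position <- as.integer(sub("^[A-Z]([0-9]+)\\*$", "\\1", s))
    out$kind <- "nonsense"
    out$alt_aa <- "*"
  } else if (grepl("^[A-Z][0-9]+[A-Z]$", s)) {
    out$ref_aa <- substr(s, 1L, 1L)
    out$position <- as.integer(sub("^[A-Z]([0-9]+)[A-Z]$", "\\1", s))
    out$alt_aa <- substr(s, nchar(s), nchar(s))
    out$kind <- if (out$alt_aa == out$ref_aa) "other" else "missense"
  }
  out
}

#' Is a mutation record a hotspot allele?
#'
#' True iff the record lies in the configured gene and is a nonsynonymous
#' substitution (missense) at a configured residue whose reference amino
#' acid matches the configured one. A substitution at a configured residue
#' number with a discordant reference amino acid (e.g. a transcript
#' mismatch) triggers a warning and is not a hotspot.
#'
#' @param record One-row data frame or list with fields `gene`,
#'   `protein_change`, `variant_class`.
#' @param config A [hotspot_config()].
#' @return Logical scalar.
#' @export
is_hotspot <- function(record, config = hotspot_config()) {
  if (!identical(as.character(record$gene), config$gene)) return(FALSE)
  p <- parse_protein_change(as.character(record$protein_change))
  if (p$kind != "missense" || is.na(p$position)) return(FALSE)
  want <- config$hotspot_positions[as.character(p$position)]
  if (is.na(want)) return(FALSE)
  if (!identical(unname(want), p$ref_aa)) {
    warning("reference amino acid mismatch at configured residue ",
            p$position, " (expected ", want, ", saw ", p$ref_aa,
            "); not counted as hotspot", call. = FALSE)
    return(FALSE)
  }
  TRUE
}

#' Is a mutation record truncating?
#'
#' Truncating classes are nonsense, frameshift indels, and splice-site
#' alterations. (Deep deletions are copy-number evidence, handled in
#' [classify_sample()].)
#'
#' @inheritParams is_hotspot
#' @return Logical scalar.
#' @export
is_truncating <- function(record) {
  as.character(record$variant_class) %in%
    c("nonsense", "frameshift_indel", "splice_site")
}

#' Flag a sample as hypermutated
#'
#' @param sample_id Sample to flag.
#' @param mutation_table Data frame of mutation records (all genes).
#' @param metadata Data frame with `sample_id` and, under the metadata rule,
#'   a logical `hypermutated` column.
#' @param config A [hotspot_config()].
#' @return Logical scalar.
#' @export
flag_hypermutated <- function(sample_id, mutation_table, metadata,
                              config = hotspot_config()) {
  in_meta <- !is.null(metadata) && sample_id %in% metadata$sample_id
  in_table <- !is.null(mutation_table) && sample_id %in% mutation_table$sample_id
  if (!in_meta && !in_table)
    stop("sample '", sample_id, "' absent from both mutation table and metadata")
  if (config$hypermutation_rule == "metadata_flag") {
    if (!in_meta || is.null(metadata$hypermutated))
      stop("metadata with a 'hypermutated' column required for sample '",
           sample_id, "' under the metadata_flag rule")
    return(isTRUE(metadata$hypermutated[match(sample_id, metadata$sample_id)]))
  }
  if (!in_table) return(FALSE)
  rows <- mutation_table[mutation_table$sample_id == sample_id, , drop = FALSE]
  nonsilent <- sum(rows$variant_class != "silent")
  nonsilent > config$hypermutation_threshold
}

#' Classify one sample's DICER1 genotype
#'
#' Applies the genotype rules: no alterations in the configured gene -> `WT`;
#' only non-hotspot alterations -> `VUS`; at least one hotspot allele ->
#' `HOTSPOT`; a hotspot allele plus at least one second hit ->
#' `HOTSPOT_BIALLELIC`. Second hits are truncating mutations, a distinct
#' second hotspot allele (identical protein changes count once, guarding
#' against caller duplication), deep deletions (GISTIC -2, always), and
#' heterozygous loss (GISTIC -1, only when `config$use_copy_loss`).
#' Co-occurrence within the sample suffices; phasing is not attempted.
#'
#' @param records Mutation records for this sample (any genes; rows outside
#'   `config$gene` are ignored).
#' @param cna_calls Copy-number calls for this sample (may be `NULL`).
#' @param metadata Sample metadata (for the hypermutation flag; may be `NULL`
#'   under the count rule).
#' @param config A [hotspot_config()].
#' @param sample_id Sample identifier; inferred from `records` when unique.
#' @return A list of class `GenotypeCall` with `sample_id`, `status`,
#'   `hypermutated`, `hotspot_alleles`, `second_hits`.
#' @export
classify_sample <- function(records, cna_calls = NULL, metadata = NULL,
                            config = hotspot_config(), sample_id = NULL) {
  if (is.null(sample_id)) {
    ids <- unique(c(records$sample_id,
                    if (!is.null(cna_calls)) cna_calls$sample_id))
    if (length(ids) != 1L)
      stop("sample_id must be given when records cover ", length(ids), " samples")
    sample_id <- ids
  }
  rec <- records[records$sample_id == sample_id &
                   records$gene == config$gene, , drop = FALSE]
  # deduplicate identical protein changes (caller duplication)
  rec <- rec[!duplicated(rec[, c("protein_change", "variant_class")]), ,
             drop = FALSE]
  is_hot <- if (nrow(rec) > 0L)
    vapply(seq_len(nrow(rec)), function(i) is_hotspot(rec[i, ], config), logical(1))
  else logical(0)
  hotspot_alleles <- unique(rec$protein_change[is_hot])

  second_hits <- character(0)
  trunc <- if (nrow(rec) > 0L) is_truncating(rec) else logical(0)
  if (any(trunc))
    second_hits <- c(second_hits,
                     paste0(rec$variant_class[trunc], ":", rec$protein_change[trunc]))
  if (length(hotspot_alleles) > 1L)
    second_hits <- c(second_hits,
                     paste0("second_hotspot:", hotspot_alleles[-1L]))
  if (!is.null(cna_calls)) {
    cna <- cna_calls[cna_calls$sample_id == sample_id &
                       cna_calls$gene == config$gene, , drop = FALSE]
    if (any(cna$call == -2L)) second_hits <- c(second_hits, "DEEP_DELETION")
    if (config$use_copy_loss && any(cna$call == -1L))
      second_hits <- c(second_hits, "HETLOSS")
  }

  status <- if (length(hotspot_alleles) > 0L) {
    if (length(second_hits) > 0L) "HOTSPOT_BIALLELIC" else "HOTSPOT"
  } else if (nrow(rec) > 0L) "VUS" else "WT"

  hyper <- tryCatch(
    flag_hypermutated(sample_id, records, metadata, config),
    error = function(e) FALSE
  )
  structure(list(sample_id = sample_id, status = status, hypermutated = hyper,
                 hotspot_alleles = hotspot_alleles, second_hits = second_hits),
            class = "GenotypeCall")
}

#' Classify every sample in a cohort
#'
#' Vectorized driver over [classify_sample()]. Samples present in `metadata`
#' but absent from the mutation table are classified `WT`.
#'
#' @param mutation_table Mutation records for all samples.
#' @param cna_calls Copy-number calls (may be `NULL`).
#' @param metadata Data frame with `sample_id`, `tumor_type`, and optionally
#'   `hypermutated`.
#' @param config A [hotspot_config()].
#' @return Data frame with one row per sample: `sample_id, tumor_type,
#'   status, hypermutated, hotspot_alleles, second_hits` (the last two are
#'   `;`-collapsed strings, empty when absent).
#' @export
classify_cohort <- function(mutation_table, cna_calls = NULL, metadata,
                            config = hotspot_config()) {
  stopifnot(all(c("sample_id", "tumor_type") %in% names(metadata)))
  calls <- lapply(metadata$sample_id, function(s)
    classify_sample(mutation_table, cna_calls, metadata, config, sample_id = s))
  data.frame(
    sample_id = metadata$sample_id,
    tumor_type = metadata$tumor_type,
    status = vapply(calls, `[[`, character(1), "status"),
    hypermutated = vapply(calls, `[[`, logical(1), "hypermutated"),
    hotspot_alleles = vapply(calls, function(x)
      paste(x$hotspot_alleles, collapse = ";"), character(1)),
    second_hits = vapply(calls, function(x)
      paste(x$second_hits, collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
}
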
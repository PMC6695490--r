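#' @importFrom utils read.delim write.table
#' @importFrom stats median setNames
NULL

# internal: stop with a format-error class so callers can distinguish
.format_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("armshift_format_error", "error")))
}

#' Column-name mapping for MAF-style mutation tables
#'
#' Defaults follow the TCGA MC3 MAF dialect. Override individual entries for
#' other exports (e.g. MSK-IMPACT) whose headers differ.
#'
#' @param sample,gene,protein_change,variant_class,tumor_type Column names in
#'   the input file holding each required field.
#' @return A named character vector used by [read_maf()].
#' @export
maf_columns <- function(sample = "Tumor_Sample_Barcode",
                        gene = "Hugo_Symbol",
                        protein_change = "HGVSp_Short",
                        variant_class = "Variant_Classification",
                        tumor_type = "Tumor_Type") {
  c(sample_id = sample, gene = gene, protein_change = protein_change,
    variant_class = variant_class, tumor_type = tumor_type)
}

# MAF Variant_Classification -> internal enum
.variant_class_map <- c(
  Missense_Mutation = "missense",
  Nonsense_Mutation = "nonsense",
  Frame_Shift_Del   = "frameshift_indel",
  Frame_Shift_Ins   = "frameshift_indel",
  In_Frame_Del      = "inframe_indel",
  In_Frame_Ins      = "inframe_indel",
  Splice_Site       = "splice_site",
  Splice_Region     = "splice_site",
  Silent            = "silent"
)

.variant_class_levels <- c("missense", "nonsense", "frameshift_indel",
                           "inframe_indel", "splice_site", "silent", "other")

#' Read a MAF-style somatic mutation table
#'
#' Reads a tab-separated mutation table into a validated data frame of
#' mutation records with the internal column contract
#' `sample_id, gene, protein_change, variant_class, tumor_type`.
#' Variant classifications outside the recognized MAF vocabulary are mapped
#' to `"other"` with a warning.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param columns Named mapping from internal fields to file column names;
#'   see [maf_columns()].
#' @return A data frame of mutation records (zero rows for a header-only
#'   file). `variant_class` is one of `missense`, `nonsense`,
#'   `frameshift_indel`, `inframe_indel`, `splice_site`, `silent`, `other`.
#' @export
read_maf <- function(path, columns = maf_columns()) {
  if (!file.exists(path)) .format_error("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   check.names = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  missing <- setdiff(unname(columns), names(df))
  if (length(missing) > 0L) {
    .format_error("MAF is missing mandatory column(s): ",
                  paste(missing, collapse = ", "))
  }
  out <- data.frame(
    sample_id      = df[[columns[["sample_id"]]]],
    gene           = df[[columns[["gene"]]]],
    protein_change = df[[columns[["protein_change"]]]],
    variant_class  = df[[columns[["variant_class"]]]],
    tumor_type     = df[[columns[["tumor_type"]]]],
    stringsAsFactors = FALSE
  )
  if (nrow(out) > 0L) {
    if (any(!nzchar(out$sample_id)) || any(!nzchar(out$gene)))
      .format_error("MAF contains rows with empty sample or gene fields")
    mapped <- unname(.variant_class_map[out$variant_class])
    unknown <- is.na(mapped)
    if (any(unknown)) {
      warning("mapping ", sum(unknown), " unrecognized variant class(es) to 'other': ",
              paste(unique(out$variant_class[unknown]), collapse = ", "),
              call. = FALSE)
      mapped[unknown] <- "other"
    }
    out$variant_class <- mapped
  }
  out
}

#' Write mutation records as a MAF-style table
#'
#' Inverse of [read_maf()] under the default column mapping: internal variant
#' classes are serialized back to their canonical MAF labels (records already
#' classed `other` keep the literal string `"other"`).
#'
#' @param records Data frame as returned by [read_maf()].
#' @param path Output path.
#' @param columns Column-name mapping, see [maf_columns()].
#' @return `path`, invisibly.
#' @export
write_maf <- function(records, path, columns = maf_columns()) {
  rev_map <- c(missense = "Missense_Mutation", nonsense = "Nonsense_Mutation",
               frameshift_indel = "Frame_Shift_Del", inframe_indel = "In_Frame_Del",
               splice_site = "Splice_Site", silent = "Silent", other = "other")
  out <- data.frame(
    a = records$sample_id, b = records$gene, c = records$protein_change,
    d = unname(rev_map[records$variant_class]), e = records$tumor_type,
    stringsAsFactors = FALSE
  )
  names(out) <- unname(columns[c("sample_id", "gene", "protein_change",
                                 "variant_class", "tumor_type")])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read GISTIC-style discrete copy-number calls
#'
#' @param path Tab-separated file with columns `sample_id`, `gene`, `call`
#'   (GISTIC convention: -2 deep deletion, -1 heterozygous loss, 0 neutral,
#'   1 gain, 2 amplification).
#' @return Data frame with those three columns; `call` is integer.
#' @export
read_cna <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "gene", "call")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    .format_error("CNA table missing column(s): ", paste(missing, collapse = ", "))
  df$call <- as.integer(df$call)
  if (nrow(df) > 0L && any(is.na(df$call) | df$call < -2L | df$call > 2L))
    .format_error("CNA calls must be integers in -2..2")
  df[, need]
}

#' Read miRNA arm annotations from a miRBase-dialect GFF3
#'
#' Parses `miRNA` features whose `Name` attribute ends in `-5p` or `-3p`
#' (the miRBase convention for mature arms). Features without an arm suffix
#' are skipped with a warning. GFF3 1-based inclusive coordinates are
#' converted to the package-internal 0-based half-open convention, so that
#' `length = end - start` for every feature.
#'
#' @param path Path to a GFF3 file.
#' @return A data frame of arm annotations with columns
#'   `mirna_id, arm, chrom, start, end, strand, conserved, collapse_group`.
#'   `mirna_id` is the `Name` with the arm suffix stripped; `conserved`
#'   defaults to `FALSE` and `collapse_group` to `NA` (fill from external
#'   curation).
#' @export
read_mirna_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == "miRNA"]
  nm <- as.character(gr$Name)
  suffix <- ifelse(grepl("-5p$", nm), "5p", ifelse(grepl("-3p$", nm), "3p", NA))
  if (anyNA(suffix)) {
    warning("skipping ", sum(is.na(suffix)),
            " miRNA feature(s) without a -5p/-3p name suffix", call. = FALSE)
    gr <- gr[!is.na(suffix)]
    nm <- nm[!is.na(suffix)]
    suffix <- suffix[!is.na(suffix)]
  }
  ann <- data.frame(
    mirna_id = sub("-[53]p$", "", nm),
    arm = suffix,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    conserved = FALSE,
    collapse_group = NA_character_,
    stringsAsFactors = FALSE
  )
  dup <- duplicated(ann[, c("mirna_id", "arm")])
  if (any(dup))
    .format_error("duplicate (mirna_id, arm) annotation(s): ",
                  paste(unique(paste0(ann$mirna_id[dup], "|", ann$arm[dup])),
                        collapse = ", "))
  ann
}

#' Read / write an arm-level count matrix
#'
#' The on-disk format is a TSV whose first column (`arm_id`) holds arm
#' identifiers of the form `"mirnaID|5p"` / `"mirnaID|3p"` and whose
#' remaining columns are samples; entries are non-negative integer read
#' counts. `read_count_matrix(write_count_matrix(m, f))` returns `m`.
#'
#' @param path File path.
#' @return For the reader, an integer matrix (arms x samples) with arm
#'   identifiers as rownames and sample identifiers as colnames.
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) .format_error("count matrix needs an arm_id column plus >=1 sample")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage <- matrix(as.numeric(m), nrow = nrow(m),
                                     dimnames = list(ids, colnames(m))))
  bad <- which(is.na(storage) | storage < 0 | storage != floor(storage),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    .format_error("invalid count at row '", ids[bad[1L, 1L]], "', sample '",
                  colnames(storage)[bad[1L, 2L]],
                  "': counts must be non-negative integers")
  }
  storage.mode(storage) <- "integer"
  validate_arm_counts(storage)
}

#' @rdname read_count_matrix
#' @param matrix Integer matrix of counts, arms x samples.
#' @export
write_count_matrix <- function(matrix, path) {
  validate_arm_counts(matrix)
  df <- data.frame(arm_id = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate an arm count matrix
#'
#' Checks the `ArmCountMatrix` contract: named rows (`"mirnaID|arm"`),
#' named samples, non-negative integer counts.
#'
#' @param counts Matrix to validate.
#' @return The matrix, invisibly coerced to integer storage.
#' @export
validate_arm_counts <- function(counts) {
  if (!is.matrix(counts)) .format_error("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    .format_error("counts must carry arm rownames and sample colnames")
  if (!all(grepl("\\|(5p|3p)$", rownames(counts))))
    .format_error("arm identifiers must end in '|5p' or '|3p'")
  if (any(counts < 0) || any(counts != floor(counts)))
    .format_error("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  counts
}

# split "mir|5p" ids into locus / arm
.split_arm_id <- function(ids) {
  data.frame(mirna_id = sub("\\|(5p|3p)$", "", ids),
             arm = sub("^.*\\|", "", ids), stringsAsFactors = FALSE)
}

#' Read a macromolecular structure (PDB or mmCIF)
#'
#' Thin wrapper over bio3d's parsers returning a uniform atom table used by
#' the residue-distance operations. Only polymer (`ATOM`) records are kept;
#' a file without any polymer residues is rejected.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param format `"auto"` (by extension), `"pdb"`, or `"cif"`.
#' @return A `StructureModel`: data frame of atoms with columns
#'   `chain, resno, resname, atom_name, element, x, y, z`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "cif") suppressWarnings(bio3d::read.cif(path))
    else bio3d::read.pdb(path),
    error = function(e) .format_error("unparseable structure file ", path,
                                      ": ", conditionMessage(e))
  )
  at <- parsed$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) .format_error("no polymer residues in ", path)
  element <- at$elesy
  if (is.null(element) || all(is.na(element)) || all(!nzchar(element)))
    element <- substr(gsub("[^A-Za-z].*$", "", at$elety), 1L, 1L)
  model <- data.frame(
    chain = as.character(at$chain), resno = as.integer(at$resno),
    resname = as.character(at$resid), atom_name = as.character(at$elety),
    element = toupper(as.character(element)),
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE
  )
  if (any(!is.finite(model$x) | !is.finite(model$y) | !is.finite(model$z)))
    .format_error("non-finite atom coordinates in ", path)
  class(model) <- c("StructureModel", class(model))
  model
}
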
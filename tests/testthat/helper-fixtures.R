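# Text fixtures built in code: a 2-residue toy structure rendered in both
# PDB and mmCIF dialects, a small MAF, and a miRBase-style GFF3.

# SER 1344 (N, CA, OG) and PHE 1706 (CA, CZ) plus one hydrogen on SER.
# Hand-derived distances: min heavy-atom pair = OG(12,11,10)-CA(14,10,10)
# = sqrt(5); CA-CA = 3.0; the H at (12.5,11,10) would be closer (1.803)
# and must be excluded under all_heavy.
toy_structure_atoms <- function() {
  data.frame(
    name = c("N", "CA", "OG", "HG", "CA", "CZ"),
    elem = c("N", "C", "O", "H", "C", "C"),
    resname = c("SER", "SER", "SER", "SER", "PHE", "PHE"),
    resno = c(1344L, 1344L, 1344L, 1344L, 1706L, 1706L),
    x = c(10, 11, 12, 12.5, 14, 15),
    y = c(10, 10, 11, 11, 10, 13),
    z = c(10, 10, 10, 10, 10, 10),
    stringsAsFactors = FALSE
  )
}

write_toy_pdb <- function(path = tempfile(fileext = ".pdb")) {
  a <- toy_structure_atoms()
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(a)), paste0(" ", a$name), a$resname, a$resno,
    a$x, a$y, a$z, a$elem)
  writeLines(c(lines, "END"), path)
  path
}

write_toy_cif <- function(path = tempfile(fileext = ".cif")) {
  a <- toy_structure_atoms()
  header <- c(
    "data_toy", "loop_",
    paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
      "label_atom_id", "label_alt_id", "label_comp_id", "label_asym_id",
      "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code", "Cartn_x",
      "Cartn_y", "Cartn_z", "occupancy", "B_iso_or_equiv",
      "pdbx_formal_charge", "auth_seq_id", "auth_comp_id", "auth_asym_id",
      "auth_atom_id", "pdbx_PDB_model_num")))
  rows <- sprintf(
    "ATOM %d %s %s . %s A 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s A %s 1",
    seq_len(nrow(a)), a$elem, a$name, a$resname, seq_len(nrow(a)),
    a$x, a$y, a$z, a$resno, a$resname, a$name)
  writeLines(c(header, rows), path)
  path
}

write_toy_maf <- function(rows, path = tempfile(fileext = ".maf")) {
  header <- paste("Tumor_Sample_Barcode", "Hugo_Symbol", "HGVSp_Short",
                  "Variant_Classification", "Tumor_Type", sep = "\t")
  writeLines(c(header, rows), path)
  path
}

write_toy_gff <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

# small deterministic count matrix with both arms of each locus
toy_counts <- function(loci = c("mir-a", "mir-b", "mir-c"),
                       samples = c("S1", "S2"), seed = 7) {
  set.seed(seed)
  ids <- c(rbind(paste0(loci, "|5p"), paste0(loci, "|3p")))
  m <- matrix(rpois(length(ids) * length(samples), 100L),
              nrow = length(ids), dimnames = list(ids, samples))
  storage.mode(m) <- "integer"
  m
}

# one-row mutation record helper
mut_record <- function(sample_id, protein_change, variant_class = "missense",
                       gene = "DICER1", tumor_type = "UCEC") {
  data.frame(sample_id = sample_id, gene = gene,
             protein_change = protein_change, variant_class = variant_class,
             tumor_type = tumor_type, stringsAsFactors = FALSE)
}
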
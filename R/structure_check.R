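#' Residue selector
#'
#' Identifies one residue and the atom subset used for distance
#' measurements: `all_heavy` (every non-hydrogen atom, the default),
#' `side_chain` (heavy atoms excluding the backbone N/CA/C/O/OXT), or `CA`
#' (alpha carbon only).
#'
#' @param resno Residue number (author numbering as parsed from the file).
#' @param chain Optional chain identifier; `NULL` matches any chain.
#' @param subset Atom subset.
#' @return A `ResidueSelector` list.
#' @export
residue_selector <- function(resno, chain = NULL,
                             subset = c("all_heavy", "side_chain", "CA")) {
  subset <- match.arg(subset)
  stopifnot(is.numeric(resno), resno > 0)
  structure(list(resno = as.integer(resno), chain = chain, subset = subset),
            class = "ResidueSelector")
}

# internal: atom rows matched by a selector
.select_atoms <- function(model, sel) {
  idx <- model$resno == sel$resno
  if (!is.null(sel$chain)) idx <- idx & model$chain == sel$chain
  at <- model[idx, , drop = FALSE]
  at <- switch(sel$subset,
    all_heavy  = at[at$element != "H", , drop = FALSE],
    CA         = at[at$atom_name == "CA", , drop = FALSE],
    side_chain = at[at$element != "H" &
                      !(at$atom_name %in% c("N", "CA", "C", "O", "OXT")), ,
                    drop = FALSE]
  )
  if (nrow(at) == 0L)
    stop("residue ", sel$resno,
         if (!is.null(sel$chain)) paste0(" (chain ", sel$chain, ")"),
         " not resolved in the model (subset '", sel$subset, "')")
  at
}

#' Minimum inter-residue distance
#'
#' Minimum Euclidean distance in Angstrom over all selected atom pairs of
#' two residues.
#'
#' @param model A `StructureModel` from [read_structure()].
#' @param a,b [residue_selector()]s (plain residue numbers are promoted to
#'   all-heavy selectors).
#' @return Distance in Angstrom.
#' @export
residue_min_distance <- function(model, a, b) {
  if (!inherits(a, "ResidueSelector")) a <- residue_selector(a)
  if (!inherits(b, "ResidueSelector")) b <- residue_selector(b)
  xa <- .select_atoms(model, a)
  xb <- .select_atoms(model, b)
  d2 <- outer(xa$x, xb$x, "-")^2 + outer(xa$y, xb$y, "-")^2 +
    outer(xa$z, xb$z, "-")^2
  sqrt(min(d2))
}

#' Pairwise minimum-distance table between two residue sites
#'
#' Measures every pair between two residue lists (e.g. an interface residue
#' against the catalytic residues of the partner RNase III domain) and
#' returns the table sorted by ascending distance.
#'
#' @param model A `StructureModel`.
#' @param site_a_residues,site_b_residues Non-empty vectors of residue
#'   numbers.
#' @param chain Optional chain identifier applied to both sites.
#' @param subset Atom subset, see [residue_selector()].
#' @return Data frame `res_a, res_b, distance`, ascending in `distance`.
#' @export
interface_report <- function(model, site_a_residues, site_b_residues,
                             chain = NULL, subset = "all_heavy") {
  if (length(site_a_residues) == 0L || length(site_b_residues) == 0L)
    stop("residue lists must be non-empty")
  grid <- expand.grid(res_a = site_a_residues, res_b = site_b_residues)
  grid$distance <- vapply(seq_len(nrow(grid)), function(i)
    residue_min_distance(model,
                         residue_selector(grid$res_a[i], chain, subset),
                         residue_selector(grid$res_b[i], chain, subset)),
    numeric(1))
  grid <- grid[order(grid$distance), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}
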
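#' Parse a PDB structure into the internal model
#'
#' Reads a PDB file, keeps the ATOM records of one protein chain and the
#' HETATM group matching `ligand_code`, and returns a `protein_structure`
#' object. Alternate locations are resolved by keeping the first listed
#' conformer of each atom, so downstream distances are deterministic.
#' Hydrogens are retained in the model but flagged, and excluded from
#' distance computations unless explicitly requested.
#'
#' Residue numbering follows the author numbering of the file; for the
#' human GAT1 deposition this coincides with the canonical UniProt P30531
#' numbering, so protein-level variant positions can be looked up directly.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier to extract (e.g. `"A"`).
#' @param ligand_code Hetero-group residue name of the bound ligand
#'   (e.g. the inhibitor code of a deposition, or `"LIG"` for the toy
#'   structures written by [make_helix_bundle()]).
#' @param source_id Free-text identifier stored on the object; defaults to
#'   the file name without extension.
#'
#' @return An object of class `protein_structure`: a list with elements
#'   `atoms` (tibble of protein atoms: `chain`, `resno`, `resname`, `aa`,
#'   `elety`, `element`, `x`, `y`, `z`, `is_hydrogen`), `ligand` (tibble of
#'   ligand atoms, same columns), `ligand_code`, `chain` and `source_id`.
#' @export
parse_structure <- function(path, chain, ligand_code, source_id = NULL) {
  if (!file.exists(path)) {
    stop("structure file not found: ", path, call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom

  prot <- at[at$type == "ATOM" & at$chain == chain, , drop = FALSE]
  if (nrow(prot) == 0L) {
    stop("chain not found: no ATOM records for chain '", chain,
         "' (available: ",
         paste(sort(unique(at$chain[at$type == "ATOM"])), collapse = ", "),
         ")", call. = FALSE)
  }
  # first-conformer rule: keep the first listed altloc of each atom
  key <- paste(prot$chain, prot$resno, prot$insert, prot$elety)
  prot <- prot[!duplicated(key), , drop = FALSE]

  het <- at[at$type == "HETATM" & at$resid == ligand_code, , drop = FALSE]
  if (nrow(het) == 0L) {
    avail <- sort(unique(at$resid[at$type == "HETATM"]))
    stop("ligand not found: no HETATM group '", ligand_code,
         "' (available hetero-codes: ",
         if (length(avail)) paste(avail, collapse = ", ") else "none",
         ")", call. = FALSE)
  }
  # one ligand copy per run: keep the first (chain, resno) copy listed
  lkey <- paste(het$chain, het$resno)
  het <- het[lkey == lkey[1L], , drop = FALSE]

  if (is.null(source_id)) {
    source_id <- sub("\\.[^.]*$", "", basename(path))
  }

  structure(
    list(
      atoms       = .atom_tibble(prot, protein = TRUE),
      ligand      = .atom_tibble(het, protein = FALSE),
      ligand_code = ligand_code,
      chain       = chain,
      source_id   = source_id
    ),
    class = "protein_structure"
  )
}

.atom_tibble <- function(at, protein) {
  element <- at$elesy
  missing_el <- is.na(element) | element == ""
  # fall back to the first alphabetic character of the atom name
  element[missing_el] <- sub("^[0-9]*([A-Za-z]).*$", "\\1",
                             at$elety[missing_el])
  element <- toupper(trimws(element))
  aa <- if (protein) {
    suppressWarnings(bio3d::aa321(at$resid))
  } else {
    rep(NA_character_, nrow(at))
  }
  aa[is.na(aa)] <- "X"
  tibble::tibble(
    chain       = at$chain,
    resno       = as.integer(at$resno),
    resname     = at$resid,
    aa          = aa,
    elety       = at$elety,
    element     = element,
    x           = at$x,
    y           = at$y,
    z           = at$z,
    is_hydrogen = element %in% c("H", "D")
  )
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("<protein_structure> ", x$source_id,
      " | chain ", x$chain,
      " | ", length(unique(x$atoms$resno)), " residues, ",
      nrow(x$atoms), " atoms",
      " | ligand ", x$ligand_code, " (", nrow(x$ligand), " atoms)\n",
      sep = "")
  invisible(x)
}

#' Look up a residue by author number
#'
#' Structures routinely lack terminal or flexible residues, so an absent
#' position is an expected ("unresolved") outcome, not an error: it returns
#' `NULL`. Variants at unresolved positions are excluded from spatial
#' metrics and reported as such.
#'
#' @param s A `protein_structure`.
#' @param seq_num Author residue number (1-based).
#' @return A tibble of the residue's atoms, or `NULL` when the position is
#'   not resolved in the model.
#' @export
residue_lookup <- function(s, seq_num) {
  stopifnot(inherits(s, "protein_structure"))
  if (length(seq_num) != 1L || is.na(seq_num) || seq_num < 1) return(NULL)
  res <- s$atoms[s$atoms$resno == seq_num, , drop = FALSE]
  if (nrow(res) == 0L) NULL else res
}

#' Residue numbers resolved in a structure
#' @param s A `protein_structure`.
#' @return Sorted integer vector of author residue numbers present.
#' @export
resolved_positions <- function(s) {
  stopifnot(inherits(s, "protein_structure"))
  sort(unique(s$atoms$resno))
}

#' One-letter sequence of the resolved residues
#' @param s A `protein_structure`.
#' @return Named character vector, names are residue numbers.
#' @export
residue_sequence <- function(s) {
  stopifnot(inherits(s, "protein_structure"))
  first <- !duplicated(s$atoms$resno)
  stats::setNames(s$atoms$aa[first], s$atoms$resno[first])
}

#' Write a `protein_structure` back to PDB format
#'
#' Minimal fixed-width writer (ATOM/HETATM/TER/END records, coordinates to
#' 0.001 Angstrom). Used for the synthetic structures and for round-trip
#' checks; it is independent of the reader code path.
#'
#' @param s A `protein_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(s, path) {
  stopifnot(inherits(s, "protein_structure"))
  fmt <- function(rec, serial, at, resname, chain, resno) {
    elety <- at$elety
    # atom names of <=3 chars are left-justified from column 14
    name <- ifelse(nchar(elety) <= 3L,
                   sprintf(" %-3s", elety), sprintf("%-4s", elety))
    sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, serial, name, "", resname, chain, resno, "",
            at$x, at$y, at$z, 1, 0, at$element)
  }
  a <- s$atoms
  lines <- fmt("ATOM", seq_len(nrow(a)), a, substr(a$resname, 1, 3),
               a$chain, a$resno)
  nser <- nrow(a)
  last <- a[nrow(a), ]
  ter <- sprintf("%-6s%5d      %3s %1s%4d", "TER", nser + 1L,
                 substr(last$resname, 1, 3), last$chain, last$resno)
  lg <- s$ligand
  hlines <- fmt("HETATM", nser + 1L + seq_len(nrow(lg)), lg,
                substr(lg$resname, 1, 3), lg$chain, lg$resno)
  writeLines(c(lines, ter, hlines, "END"), path)
  invisible(path)
}
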
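# Hierarchical coordinate model. A mol_structure holds one atom table shared by
# all models plus one N x 3 coordinate matrix per model, so a multi-model PDB
# doubles as a trajectory container.

#' Construct a molecular structure object
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`, `resid`
#'   (residue name), `chain`, `resno`, `insert`, `occ`, `b`, `mass`.
#' @param xyz a single N x 3 numeric matrix or a list of such matrices (one
#'   per model, identical atom ordering).
#' @param title optional free-text title.
#' @param source optional source path.
#' @return an object of class `mol_structure`.
#' @export
mol_structure <- function(atoms, xyz, title = "", source = NA_character_) {
  if (is.matrix(xyz)) xyz <- list(xyz)
  stopifnot(is.data.frame(atoms), length(xyz) >= 1)
  need <- c("serial", "name", "element", "resid", "chain", "resno",
            "insert", "occ", "b", "mass")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) stop("atoms table lacks columns: ", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (n == 0) stop("structure must contain at least one atom")
  for (m in xyz) {
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != 3)
      stop("every model must be an N x 3 coordinate matrix matching the atom table")
    if (!all(is.finite(m))) stop("non-finite coordinates")
  }
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stop("atom masses must be positive and finite")
  if (any(!nzchar(atoms$name))) stop("atom names must be non-blank")
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name)
  if (anyDuplicated(key))
    warning("duplicate (chain, resno, insert, name) atom identifiers present")
  structure(
    list(atoms = atoms, xyz = xyz, title = title, source = source),
    class = "mol_structure"
  )
}

#' Number of models (frames) in a structure
#' @param s a `mol_structure`.
#' @return integer count.
#' @export
n_models <- function(s) length(s$xyz)

#' Number of atoms in a structure
#' @param s a `mol_structure`.
#' @return integer count.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Coordinates of one model
#' @param s a `mol_structure`.
#' @param model model index (1-based).
#' @return N x 3 numeric matrix.
#' @export
coords <- function(s, model = 1) {
  stopifnot(model >= 1, model <= n_models(s))
  s$xyz[[model]]
}

#' Replace coordinates of one model
#' @param s a `mol_structure`.
#' @param value N x 3 matrix.
#' @param model model index.
#' @return the modified structure.
#' @export
set_coords <- function(s, value, model = 1) {
  stopifnot(is.matrix(value), nrow(value) == n_atoms(s), ncol(value) == 3)
  s$xyz[[model]] <- value
  s
}

#' @export
print.mol_structure <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  nres <- nrow(unique(x$atoms[, c("chain", "resno", "insert")]))
  cat(sprintf("mol_structure: %d atoms, %d residues, chains [%s], %d model(s)\n",
              n_atoms(x), nres, paste(ch, collapse = ","), n_models(x)))
  if (nzchar(x$title)) cat("  title: ", x$title, "\n", sep = "")
  invisible(x)
}

# Residue-name dialect handling: canonical one-letter codes for nucleotides.
NUC_CANON <- c(
  DA = "A", DT = "T", DG = "G", DC = "C", DU = "U",
  A = "A", T = "T", G = "G", C = "C", U = "U",
  ADE = "A", THY = "T", GUA = "G", CYT = "C", URA = "U"
)

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL", "MSE", "HSD", "HSE", "HSP")

#' Canonical nucleotide code for a residue name
#'
#' Accepts the PDB dialects DA/DT/DG/DC/DU, one-letter A/T/G/C/U and
#' ADE/THY/GUA/CYT/URA. Returns NA for non-nucleotide residues.
#'
#' @param resid character vector of residue names.
#' @return character vector of canonical codes ("A","C","G","T","U") or NA.
#' @export
canonical_base <- function(resid) {
  unname(NUC_CANON[toupper(trimws(resid))])
}

is_nucleotide <- function(resid) !is.na(canonical_base(resid))
is_amino <- function(resid) toupper(trimws(resid)) %in% AA3

# Unique residue table of a structure, in atom order.
residue_table <- function(s) {
  unique(s$atoms[, c("chain", "resno", "insert", "resid")])
}

residue_indices <- function(s, chain, resno, insert = "") {
  a <- s$atoms
  which(a$chain == chain & a$resno == resno &
          (a$insert %in% c(insert, "", NA)))
}
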
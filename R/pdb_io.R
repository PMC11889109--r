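# PDB reading and writing. Parsing of the fixed-column format is delegated to
# bio3d; this layer converts to/from the package's mol_structure container,
# infers elements from atom names where the element column is blank, and
# attaches atomic masses.

#' Read a PDB file into a `mol_structure`
#'
#' ATOM and HETATM records are parsed; MODEL/ENDMDL blocks delimit frames.
#' Elements missing from columns 77-78 are inferred from the atom name and
#' masses are assigned per element.
#'
#' @param path path to a PDB file.
#' @param multi read all MODEL blocks as frames (default TRUE). With
#'   `multi = FALSE` only the first model is kept and inconsistent atom
#'   counts across models are tolerated.
#' @return a `mol_structure`.
#' @export
read_pdb <- function(path, multi = TRUE) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = multi, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file ", path, ": ",
                             conditionMessage(e))
  )
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0)
    stop("no ATOM/HETATM records in ", path)
  a <- pdb$atom
  element <- as.character(a$elesy)
  blank <- is.na(element) | !nzchar(trimws(element))
  if (any(blank))
    element[blank] <- guess_element(a$elety[blank])
  mass <- suppressWarnings(element_mass(element))
  atoms <- data.frame(
    serial = a$eleno,
    name = trimws(a$elety),
    element = toupper(trimws(element)),
    resid = trimws(a$resid),
    chain = ifelse(is.na(a$chain), " ", a$chain),
    resno = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    occ = ifelse(is.na(a$o), 1, a$o),
    b = ifelse(is.na(a$b), 0, a$b),
    mass = mass,
    stringsAsFactors = FALSE
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nmod <- nrow(xyz)
  if (ncol(xyz) != 3 * nrow(atoms)) {
    if (multi)
      stop("inconsistent atom counts across MODEL blocks in ", path)
    warning("inconsistent MODEL blocks; keeping first model of ", path)
    xyz <- xyz[1, seq_len(3 * nrow(atoms)), drop = FALSE]
    nmod <- 1
  }
  frames <- lapply(seq_len(nmod), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  mol_structure(atoms, frames, title = basename(path), source = path)
}

#' Write a `mol_structure` to a PDB file
#'
#' Coordinates are written at the standard 8.3 precision; multi-model
#' structures produce MODEL/ENDMDL blocks. A read/write round trip preserves
#' atom identities exactly and coordinates to 0.001 Angstrom.
#'
#' @param s a `mol_structure`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "mol_structure"))
  xyz <- do.call(rbind, lapply(s$xyz, function(m) as.vector(t(m))))
  ok <- tryCatch({
    bio3d::write.pdb(
      file = path,
      xyz = xyz,
      type = rep("ATOM", n_atoms(s)),
      eleno = s$atoms$serial,
      elety = s$atoms$name,
      resid = s$atoms$resid,
      chain = ifelse(s$atoms$chain == " ", "", s$atoms$chain),
      resno = s$atoms$resno,
      insert = ifelse(nzchar(s$atoms$insert), s$atoms$insert, NA),
      o = s$atoms$occ,
      b = s$atoms$b,
      elesy = s$atoms$element
    )
    TRUE
  }, error = function(e) {
    stop("failed to write PDB file ", path, ": ", conditionMessage(e))
  })
  invisible(path)
}
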
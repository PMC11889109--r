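# Atom selection. Criteria are small boolean expressions over atom fields and
# named moiety classes, e.g. "chain A and resno 12 and base" or
# "phosphate or name O3'". Moiety membership is by fixed atom-name tables so
# that group centers of mass are reproducible.

# Fixed moiety atom-name tables (force-field style naming; primed names as in
# PDB v3). The phosphate group is P + both non-bridging oxygens + O5'; the O3'
# of the preceding residue is deliberately excluded.
MOIETY_TABLES <- list(
  phosphate = c("P", "OP1", "OP2", "O1P", "O2P", "O5'", "O5*"),
  sugar = c("C1'", "C2'", "C3'", "C4'", "C5'", "O4'", "O2'", "O3'",
            "C1*", "C2*", "C3*", "C4*", "C5*", "O4*", "O2*", "O3*",
            "H1'", "H2'", "H2''", "H3'", "H4'", "H5'", "H5''", "HO3'", "HO5'")
)

# Base atoms = everything in a nucleotide that is neither sugar nor phosphate.
is_base_atom <- function(name, resid) {
  nuc <- is_nucleotide(resid)
  nm <- toupper(name)
  nuc & !(nm %in% toupper(c(MOIETY_TABLES$phosphate, MOIETY_TABLES$sugar)))
}

#' Select atoms by a criteria expression
#'
#' The criteria language supports clauses `chain <id>`, `resno <n>` (or
#' `resno <a>:<b>`), `resid <name>`, `name <atom>`, `element <symbol>`, the
#' moiety keywords `base`, `sugar`, `phosphate`, `heavy`, `hydrogen`,
#' `calpha` (alias `ca`), `protein`, `nucleic`, `all`, combined with `and`,
#' `or`, `not` and parentheses. Matching is case-insensitive except for chain
#' identifiers.
#'
#' @param s a `mol_structure`.
#' @param criteria selection string, or an integer vector of atom indices
#'   (returned unchanged after validation).
#' @param model model index the selection refers to (stored on the result).
#' @return an integer vector of atom indices (class `atom_set`), possibly
#'   empty, in structure order.
#' @export
select_atoms <- function(s, criteria, model = 1) {
  stopifnot(inherits(s, "mol_structure"))
  if (is.numeric(criteria)) {
    idx <- as.integer(criteria)
    if (any(idx < 1 | idx > n_atoms(s))) stop("atom indices out of range")
    if (anyDuplicated(idx)) stop("duplicate atom indices in selection")
    return(structure(idx, class = "atom_set", model = model))
  }
  mask <- eval_criteria(s, criteria)
  structure(which(mask), class = "atom_set", model = model)
}

eval_criteria <- function(s, text) {
  toks <- tokenize_criteria(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- parse_or(s, st)
  if (st$pos <= length(st$toks))
    stop("trailing tokens in selection criteria: ",
         paste(st$toks[st$pos:length(st$toks)], collapse = " "))
  mask
}

tokenize_criteria <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  text <- gsub("\\(", " ( ", text)
  text <- gsub("\\)", " ) ", text)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  if (length(toks) == 0 || !nzchar(toks[1])) stop("empty selection criteria")
  toks
}

peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_
advance <- function(st) { st$pos <- st$pos + 1L; invisible(NULL) }

parse_or <- function(s, st) {
  left <- parse_and(s, st)
  while (!is.na(peek(st)) && tolower(peek(st)) == "or") {
    advance(st)
    left <- left | parse_and(s, st)
  }
  left
}

parse_and <- function(s, st) {
  left <- parse_unary(s, st)
  while (!is.na(peek(st)) && tolower(peek(st)) == "and") {
    advance(st)
    left <- left & parse_unary(s, st)
  }
  left
}

parse_unary <- function(s, st) {
  tok <- peek(st)
  if (is.na(tok)) stop("unexpected end of selection criteria")
  if (tolower(tok) == "not") {
    advance(st)
    return(!parse_unary(s, st))
  }
  if (tok == "(") {
    advance(st)
    m <- parse_or(s, st)
    if (is.na(peek(st)) || peek(st) != ")") stop("unbalanced parentheses in criteria")
    advance(st)
    return(m)
  }
  parse_clause(s, st)
}

parse_clause <- function(s, st) {
  a <- s$atoms
  tok <- peek(st); advance(st)
  key <- tolower(tok)
  one_arg <- function() {
    v <- peek(st)
    if (is.na(v)) stop("selection keyword '", tok, "' needs a value")
    advance(st)
    v
  }
  switch(key,
    "chain" = a$chain == one_arg(),
    "resno" = ,
    "residue" = {
      v <- one_arg()
      if (grepl(":", v, fixed = TRUE)) {
        rng <- as.integer(strsplit(v, ":", fixed = TRUE)[[1]])
        a$resno >= rng[1] & a$resno <= rng[2]
      } else a$resno == as.integer(v)
    },
    "resid" = ,
    "resname" = toupper(a$resid) == toupper(one_arg()),
    "name" = toupper(a$name) == toupper(one_arg()),
    "element" = toupper(a$element) == toupper(one_arg()),
    "base" = is_base_atom(a$name, a$resid),
    "sugar" = is_nucleotide(a$resid) &
      toupper(a$name) %in% toupper(MOIETY_TABLES$sugar),
    "phosphate" = is_nucleotide(a$resid) &
      toupper(a$name) %in% toupper(MOIETY_TABLES$phosphate),
    "heavy" = toupper(a$element) != "H",
    "hydrogen" = toupper(a$element) == "H",
    "calpha" = ,
    "ca" = toupper(a$name) == "CA" & is_amino(a$resid),
    "protein" = is_amino(a$resid),
    "nucleic" = is_nucleotide(a$resid),
    "all" = rep(TRUE, nrow(a)),
    stop("unknown selection keyword: ", tok)
  )
}

#' Center of mass of an atom selection
#'
#' @param s a `mol_structure`.
#' @param sel an `atom_set`, integer indices, or a criteria string.
#' @param model model index.
#' @param weighting `"mass"` (default) for the mass-weighted center, or
#'   `"geometric"` for the unweighted centroid.
#' @return length-3 numeric vector (Angstrom).
#' @export
center_of_mass <- function(s, sel, model = 1,
                           weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  idx <- if (is.character(sel)) select_atoms(s, sel, model) else as.integer(sel)
  if (length(idx) == 0) stop("center_of_mass of an empty atom set")
  x <- coords(s, model)[idx, , drop = FALSE]
  w <- if (weighting == "mass") s$atoms$mass[idx] else rep(1, length(idx))
  colSums(x * w) / sum(w)
}
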
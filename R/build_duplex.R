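# Idealized B-DNA duplex builder. Base pairs are generated in the standard
# reference frame and propagated along the helix through per-step rigid-body
# parameters (uniform twist 36 deg / rise 3.38 A by default), which makes the
# builder the exact inverse of the helical-parameter analyzer.

#' Specify a DNA duplex
#'
#' @param sequence strand I sequence, 5' to 3', over A/C/G/T/U.
#' @param uracil_positions strand I positions whose base becomes uracil
#'   (thymine positions in the printed sequence are typically given here).
#' @param with_hydrogens place base hydrogens (needed for Watson-Crick
#'   hydrogen-bond distances).
#' @param steps optional data.frame with N-1 rows and columns `twist`,
#'   `roll`, `tilt` (degrees), `shift`, `slide`, `rise` (Angstrom); default
#'   is the uniform fiber geometry twist 36, rise 3.38, all else 0.
#' @return object of class `duplex_spec`.
#' @export
duplex_spec <- function(sequence, uracil_positions = integer(),
                        with_hydrogens = TRUE, steps = NULL) {
  bases <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(bases, c("A", "C", "G", "T", "U"))
  if (length(bad) > 0) stop("invalid sequence characters: ", paste(bad, collapse = ""))
  n <- length(bases)
  if (n < 1) stop("empty sequence")
  if (length(uracil_positions) > 0) {
    if (any(uracil_positions < 1 | uracil_positions > n))
      stop("uracil positions outside [1, ", n, "]")
    bases[uracil_positions] <- "U"
  }
  if (is.null(steps)) {
    k <- max(n - 1, 0)
    steps <- data.frame(twist = rep(36, k), roll = rep(0, k), tilt = rep(0, k),
                        shift = rep(0, k), slide = rep(0, k),
                        rise = rep(3.38, k))
  } else {
    steps <- as.data.frame(steps)
    if (nrow(steps) != n - 1) stop("steps must have N-1 rows")
    need <- c("twist", "roll", "tilt", "shift", "slide", "rise")
    for (k in setdiff(need, names(steps))) steps[[k]] <- if (k == "rise") 3.38 else 0
    if (any(steps$rise <= 0)) stop("rise must be positive")
  }
  structure(list(bases = bases, n = n, with_hydrogens = with_hydrogens,
                 steps = steps), class = "duplex_spec")
}

#' Build an idealized B-DNA duplex
#'
#' Two antiparallel Watson-Crick-paired strands. Strand I is chain A with
#' residues 1..N (5' to 3'); strand II is chain B with residues N+1..2N,
#' numbered so residue j on strand II pairs residue 2N+1-j on strand I.
#' Both 5'-terminal residues lack the phosphate group.
#'
#' @param spec a `duplex_spec` (or a bare sequence string).
#' @param ... passed to [duplex_spec()] when `spec` is a string.
#' @return a `mol_structure` with one model.
#' @export
build_duplex <- function(spec, ...) {
  if (is.character(spec)) spec <- duplex_spec(spec, ...)
  stopifnot(inherits(spec, "duplex_spec"))
  n <- spec$n

  # pair frames along the helix
  frames <- vector("list", n)
  frames[[1]] <- list(T = diag(3), o = c(0, 0, 0))
  if (n > 1) for (i in seq_len(n - 1)) {
    st <- spec$steps[i, ]
    nxt <- step_compose(frames[[i]]$T, frames[[i]]$o, st$twist, st$roll,
                        st$tilt, st$shift, st$slide, st$rise)
    frames[[i + 1]] <- list(T = nxt$T2, o = nxt$o2)
  }

  mirror <- diag(c(1, -1, -1))
  rows <- list()
  for (i in seq_len(n)) {
    b1 <- spec$bases[i]
    b2 <- WC_COMPLEMENT[[b1]]
    t1 <- nucleotide_template(b1, spec$with_hydrogens)
    t2 <- nucleotide_template(b2, spec$with_hydrogens)
    Tf <- frames[[i]]$T; of <- frames[[i]]$o
    x1 <- sweep(as.matrix(t1[, c("x", "y", "z")]) %*% t(Tf), 2, of, "+")
    x2 <- sweep(as.matrix(t2[, c("x", "y", "z")]) %*% mirror %*% t(Tf), 2, of, "+")
    colnames(x1) <- colnames(x2) <- c("x", "y", "z")
    keep1 <- if (i == 1) !(t1$name %in% c("P", "OP1", "OP2")) else rep(TRUE, nrow(t1))
    keep2 <- if (i == n) !(t2$name %in% c("P", "OP1", "OP2")) else rep(TRUE, nrow(t2))
    rows[[length(rows) + 1]] <- data.frame(
      name = t1$name[keep1], element = t1$element[keep1],
      resid = BASE_TO_RESID[[b1]], chain = "A", resno = i,
      x1[keep1, , drop = FALSE], stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      name = t2$name[keep2], element = t2$element[keep2],
      resid = BASE_TO_RESID[[b2]], chain = "B", resno = 2 * n + 1 - i,
      x2[keep2, , drop = FALSE], stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  # atom order: chain A by resno ascending, then chain B by resno ascending
  tab <- tab[order(tab$chain, tab$resno), ]
  atoms <- data.frame(
    serial = seq_len(nrow(tab)),
    name = tab$name, element = tab$element, resid = tab$resid,
    chain = tab$chain, resno = tab$resno, insert = "",
    occ = 1, b = 0,
    mass = element_mass(tab$element),
    stringsAsFactors = FALSE
  )
  s <- mol_structure(atoms, as.matrix(tab[, c("x", "y", "z")]),
                     title = paste0("idealized B-DNA duplex ",
                                    paste(spec$bases, collapse = "")))
  attr(s, "provenance") <- "synthetic"
  attr(s, "duplex_n") <- n
  s
}

#' Mutate a thymine residue to uracil
#'
#' Removes the C7/C5M methyl group (and its hydrogens) and renames the
#' residue to the uracil code; all other atoms are untouched.
#'
#' @param s a `mol_structure`.
#' @param chain chain identifier.
#' @param resnum residue number.
#' @return the mutated `mol_structure`.
#' @export
mutate_thymine_to_uracil <- function(s, chain, resnum) {
  idx <- residue_indices(s, chain, resnum)
  if (length(idx) == 0) stop("residue ", chain, ":", resnum, " not found")
  base <- canonical_base(s$atoms$resid[idx[1]])
  if (is.na(base) || base != "T")
    stop("residue ", chain, ":", resnum, " is not thymine; cannot mutate")
  nm <- toupper(s$atoms$name[idx])
  methyl_c <- idx[nm %in% c("C7", "C5M")]
  if (length(methyl_c) == 0) stop("thymine methyl carbon (C7/C5M) not found")
  drop <- idx[nm %in% c("C7", "C5M", "H71", "H72", "H73",
                        "1H5M", "2H5M", "3H5M", "H51", "H52", "H53")]
  keep <- setdiff(seq_len(n_atoms(s)), drop)
  atoms <- s$atoms[keep, , drop = FALSE]
  atoms$resid[atoms$chain == chain & atoms$resno == resnum] <- "DU"
  atoms$serial <- seq_len(nrow(atoms))
  xyz <- lapply(s$xyz, function(m) m[keep, , drop = FALSE])
  out <- mol_structure(atoms, xyz, title = s$title, source = s$source)
  attributes(out)[c("provenance", "duplex_n")] <-
    attributes(s)[c("provenance", "duplex_n")]
  out
}
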
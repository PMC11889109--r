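# Per-structure geometric metrics of the base-flipping process: the
# center-of-mass pseudo-dihedral schemes (CPD, CPDa, CPDb), the
# groove-accessibility distance, Watson-Crick hydrogen-bond distances and the
# paired-residue center distance.

FLIP_SCHEMES <- c("CPD", "CPDa", "CPDb")

# Uracil-analog residue names accepted when locating the flipped base in a
# recognition complex (2'-deoxypseudouridine and friends).
URACIL_ANALOGS <- c("DU", "U", "URA", "PSU", "PDU", "UPS", "5IU", "UMS")

opposing_residue <- function(s, chain, resno, model = 1) {
  # builder-numbered duplexes pair residue i with 2N+1-i on the other chain
  n <- attr(s, "duplex_n")
  if (!is.null(n)) {
    other <- setdiff(unique(s$atoms$chain[is_nucleotide(s$atoms$resid)]), chain)
    if (length(other) == 1 &&
        length(residue_indices(s, other, 2 * n + 1 - resno)) > 0) {
      rt <- residue_table(s)
      hit <- rt[rt$chain == other & rt$resno == 2 * n + 1 - resno, , drop = FALSE]
      return(hit[1, ])
    }
  }
  rt <- residue_table(s)
  rt <- rt[is_nucleotide(rt$resid) & rt$chain != chain, , drop = FALSE]
  if (nrow(rt) == 0) stop("no nucleotides on any other chain to pair with")
  # pairing by Watson-Crick edge proximity: the glycosidic-edge nitrogen
  # (N1 of purines, N3 of pyrimidines) of true partners sits ~2.9 A away,
  # closer than any stacking contact
  edge_n <- function(ch, rn) {
    idx <- residue_indices(s, ch, rn)
    base <- canonical_base(s$atoms$resid[idx[1]])
    nm <- if (!is.na(base) && base %in% c("A", "G")) "N1" else "N3"
    hit <- idx[toupper(s$atoms$name[idx]) == nm]
    if (length(hit) == 0) NULL else coords(s, model)[hit[1], ]
  }
  tn <- edge_n(chain, resno)
  if (is.null(tn)) stop("no glycosidic-edge nitrogen in ", chain, ":", resno)
  best <- NULL; bestd <- Inf
  for (k in seq_len(nrow(rt))) {
    cn <- edge_n(rt$chain[k], rt$resno[k])
    if (is.null(cn)) next
    d <- vnorm(cn - tn)
    if (d < bestd) { bestd <- d; best <- rt[k, ] }
  }
  if (is.null(best) || bestd > 12)
    stop("could not identify the opposing residue of ", chain, ":", resno)
  best
}

scheme_group_criteria <- function(s, chain, resno, scheme, cpd_neighbor = "5p") {
  sel <- function(ch, rn, what) sprintf("chain %s and resno %d and %s and heavy", ch, rn, what)
  has_res <- function(rn) length(residue_indices(s, chain, rn)) > 0
  if (!has_res(resno)) stop("target residue ", chain, ":", resno, " not found")
  p5 <- resno - 1; p3 <- resno + 1
  if (scheme == "CPD") {
    # "next" nucleotide: the 5'-side neighbor by default, which makes the
    # CPD sign convention (+ = major groove) agree with CPDb and puts the
    # intrahelical minimum near +35 deg on the ideal duplex
    nb <- if (cpd_neighbor == "5p") p5 else p3
    if (!has_res(nb))
      stop("CPD scheme needs the ", cpd_neighbor, " neighbor of ", chain, ":", resno)
    opp <- opposing_residue(s, chain, nb)
    list(P1 = c(sel(chain, nb, "base"), sel(opp$chain, opp$resno, "base")),
         P2 = sel(chain, nb, "sugar"),
         P3 = sel(chain, resno, "sugar"),
         P4 = sel(chain, resno, "base"))
  } else {
    if (!has_res(p5) || !has_res(p3))
      stop(scheme, " scheme needs both flanking residues of ", chain, ":", resno)
    opp5 <- opposing_residue(s, chain, p5)
    opp3 <- opposing_residue(s, chain, p3)
    P1 <- c(sel(chain, p5, "base"), sel(opp5$chain, opp5$resno, "base"),
            sel(chain, p3, "base"), sel(opp3$chain, opp3$resno, "base"))
    if (scheme == "CPDa") {
      list(P1 = P1,
           P2 = sel(chain, p5, "sugar"),
           P3 = sel(chain, p3, "sugar"),
           P4 = sel(chain, resno, "base"))
    } else {
      list(P1 = P1,
           P2 = sel(chain, resno, "phosphate"),
           P3 = sel(chain, p3, "phosphate"),
           P4 = sel(chain, resno, "base"))
    }
  }
}

#' Atom groups of a pseudo-dihedral flipping scheme
#'
#' Resolves the four center-of-mass groups P1..P4 for a flipping coordinate.
#' CPD uses the 3'-neighbor base (+ its pairing partner), the neighbor and
#' target sugars, and the target base. CPDa replaces P1 by both flanking
#' base pairs and P2/P3 by the flanking sugars; CPDb uses the flanking
#' phosphate groups instead of the sugars.
#'
#' @param s a `mol_structure`.
#' @param chain,resno target (flipping) residue.
#' @param scheme one of "CPD", "CPDa", "CPDb".
#' @param cpd_neighbor which neighbor is the CPD "next" nucleotide:
#'   `"5p"` (default) or `"3p"`.
#' @return named list of `atom_set` index vectors P1..P4.
#' @export
flip_scheme_groups <- function(s, chain, resno, scheme = c("CPD", "CPDa", "CPDb"),
                               cpd_neighbor = c("5p", "3p")) {
  scheme <- match.arg(scheme)
  cpd_neighbor <- match.arg(cpd_neighbor)
  crit <- scheme_group_criteria(s, chain, resno, scheme, cpd_neighbor)
  groups <- lapply(crit, function(cr) {
    idx <- unique(unlist(lapply(cr, function(x) as.integer(select_atoms(s, x)))))
    sort(idx)
  })
  empty <- names(groups)[vapply(groups, length, 1L) == 0]
  if (length(empty) > 0)
    stop("scheme ", scheme, " group(s) ", paste(empty, collapse = ","),
         " are empty for ", chain, ":", resno,
         " (terminal residue or missing phosphate?)")
  groups
}

#' Center-of-mass pseudo-dihedral flipping angle
#'
#' The signed dihedral of the four group centers of mass P1-P2-P3-P4, the
#' collective coordinate that tracks rotation of the target base about its
#' backbone. Positive angles flip toward the major groove, negative toward
#' the minor groove; the intrahelical state is near 0.
#'
#' @inheritParams flip_scheme_groups
#' @param model model index.
#' @return signed angle in degrees, in (-180, 180].
#' @export
pseudo_dihedral <- function(s, chain, resno, scheme = c("CPD", "CPDa", "CPDb"),
                            model = 1, cpd_neighbor = c("5p", "3p")) {
  scheme <- match.arg(scheme)
  g <- flip_scheme_groups(s, chain, resno, scheme, match.arg(cpd_neighbor))
  p <- lapply(g, function(idx) center_of_mass(s, idx, model))
  dihedral_angle(p$P1, p$P2, p$P3, p$P4)
}

#' Groove-accessibility distance of a flipping uracil
#'
#' Minimum distance from the uracil N1 atom to any phosphorus atom of the
#' opposite strand -- a proxy for how sterically hindered the flipped base
#' is by the far edge of the groove.
#'
#' @param s a `mol_structure`.
#' @param chain,resno the uracil residue.
#' @param model model index.
#' @return distance in Angstrom.
#' @export
u_groove_distance <- function(s, chain, resno, model = 1) {
  idx <- residue_indices(s, chain, resno)
  if (length(idx) == 0) stop("residue ", chain, ":", resno, " not found")
  n1 <- idx[toupper(s$atoms$name[idx]) == "N1"]
  if (length(n1) != 1) stop("uracil N1 atom not resolvable in ", chain, ":", resno)
  p_idx <- which(toupper(s$atoms$name) == "P" &
                   s$atoms$chain != chain & is_nucleotide(s$atoms$resid))
  if (length(p_idx) == 0) stop("no phosphorus atoms on the opposite strand")
  x <- coords(s, model)
  min(sqrt(rowSums(sweep(x[p_idx, , drop = FALSE], 2, x[n1, ])^2)))
}

#' Watson-Crick hydrogen-bond distances of a U:A pair
#'
#' Returns the two donor-acceptor hydrogen distances of the uracil:adenine
#' pair: N1(adenine)...H3(uracil) and O4(uracil)...H61(adenine). Hydrogens
#' must be present.
#'
#' @param s a `mol_structure`.
#' @param uracil,adenine `c(chain, resno)` residue identifiers.
#' @param model model index.
#' @return named numeric vector `c(N1_H3 = , O4_H6 = )` in Angstrom.
#' @export
wc_hbond_distances <- function(s, uracil, adenine, model = 1) {
  x <- coords(s, model)
  get1 <- function(res, names, what) {
    idx <- residue_indices(s, res[1], as.integer(res[2]))
    hit <- idx[toupper(s$atoms$name[idx]) %in% toupper(names)]
    if (length(hit) == 0)
      stop("atom ", what, " not found in ", res[1], ":", res[2],
           if (grepl("^H", names[1])) " (are hydrogens present?)" else "")
    hit[1]
  }
  h3 <- get1(uracil, "H3", "H3")
  o4 <- get1(uracil, "O4", "O4")
  n1 <- get1(adenine, "N1", "N1")
  h6 <- get1(adenine, c("H61", "H6'", "1H6"), "H61/H6'")
  c(N1_H3 = vnorm(x[n1, ] - x[h3, ]), O4_H6 = vnorm(x[o4, ] - x[h6, ]))
}

#' Center distance between two paired residues
#'
#' Distance between the whole-residue centers of the two nucleotides.
#' The default is the unweighted (geometric) center over all atoms, the
#' convention of the common MD analysis toolchain; mass weighting and a
#' base-only selection are available for sensitivity checks.
#'
#' @param s a `mol_structure`.
#' @param res_i,res_j `c(chain, resno)` residue identifiers.
#' @param weighting `"geometric"` (default) or `"mass"`.
#' @param atoms `"residue"` (default, all atoms) or `"base"`.
#' @param model model index.
#' @return distance in Angstrom.
#' @export
pair_com_distance <- function(s, res_i, res_j,
                              weighting = c("geometric", "mass"),
                              atoms = c("residue", "base"), model = 1) {
  weighting <- match.arg(weighting)
  atoms <- match.arg(atoms)
  one <- function(res) {
    crit <- sprintf("chain %s and resno %d", res[1], as.integer(res[2]))
    if (atoms == "base") crit <- paste(crit, "and base")
    idx <- select_atoms(s, crit)
    if (length(idx) == 0) stop("residue ", res[1], ":", res[2], " is empty")
    center_of_mass(s, idx, model, weighting)
  }
  vnorm(one(res_i) - one(res_j))
}

#' Flip metrics for one structure
#'
#' Convenience record combining the pseudo-dihedral, groove distance and,
#' when a paired adenine is identifiable and hydrogens are present, the
#' Watson-Crick hydrogen-bond and center distances.
#'
#' @param s a `mol_structure`.
#' @param chain,resno the flipping uracil.
#' @param scheme flipping scheme.
#' @param model model index.
#' @return a one-row data.frame.
#' @export
flip_metrics <- function(s, chain, resno, scheme = "CPD", model = 1) {
  dih <- pseudo_dihedral(s, chain, resno, scheme, model)
  dg <- u_groove_distance(s, chain, resno, model)
  hb <- c(N1_H3 = NA_real_, O4_H6 = NA_real_)
  cd <- NA_real_
  opp <- tryCatch(opposing_residue(s, chain, resno, model), error = function(e) NULL)
  if (!is.null(opp)) {
    cd <- pair_com_distance(s, c(chain, resno), c(opp$chain, opp$resno),
                            model = model)
    hb <- tryCatch(wc_hbond_distances(s, c(chain, resno),
                                      c(opp$chain, opp$resno), model),
                   error = function(e) hb)
  }
  data.frame(scheme = scheme, dihedral = dih, d_U_groove = dg,
             hbond_N1_H3 = hb[["N1_H3"]], hbond_O4_H6 = hb[["O4_H6"]],
             com_pair_distance = cd, groove_side = sign(dih))
}
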
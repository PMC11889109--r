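# Idealized nucleotide templates. Base rings are placed from the standard
# (Tsukuba-convention) base reference-frame coordinates, in which the x axis
# points into the major groove and a Watson-Crick partner is obtained by
# negating y and z (a 180 degree rotation about x). The sugar, phosphate and
# hydrogens come from idealized residue geometries (PDB Chemical Component
# Dictionary) grafted onto the placed base, with the glycosidic torsion and
# backbone torsions reset to canonical B-form values so the duplex backbone
# is helix-regular.

# Standard reference frame coordinates (Angstrom) of the base heavy atoms and
# C1' for the five bases; z = 0 for all.
STD_BASE_FRAME <- list(
  A = matrix(c(
    -1.291, 4.498,  0.024, 4.897,  0.877, 3.902,  0.071, 2.771,
     0.369, 1.398,  1.611, 0.909, -0.668, 0.532, -1.912, 1.023,
    -2.320, 2.290, -1.267, 3.124, -2.479, 5.346
  ), ncol = 2, byrow = TRUE,
  dimnames = list(c("N9","C8","N7","C5","C6","N6","N1","C2","N3","C4","C1'"), NULL)),
  G = matrix(c(
    -1.289, 4.551,  0.023, 4.962,  0.870, 3.969,  0.071, 2.833,
     0.424, 1.460,  1.554, 0.955, -0.700, 0.641, -1.999, 1.087,
    -2.949, 0.139, -2.342, 2.364, -1.265, 3.177, -2.477, 5.399
  ), ncol = 2, byrow = TRUE,
  dimnames = list(c("N9","C8","N7","C5","C6","O6","N1","C2","N2","N3","C4","C1'"), NULL)),
  C = matrix(c(
    -1.285, 4.542, -1.472, 3.158, -2.628, 2.709, -0.391, 2.344,
     0.837, 2.868,  1.875, 2.027,  1.056, 4.275, -0.023, 5.068,
    -2.477, 5.402
  ), ncol = 2, byrow = TRUE,
  dimnames = list(c("N1","C2","O2","N3","C4","N4","C5","C6","C1'"), NULL)),
  T = matrix(c(
    -1.284, 4.500, -1.462, 3.135, -2.562, 2.608, -0.298, 2.407,
     0.994, 2.897,  1.944, 2.119,  1.106, 4.338,  2.466, 4.961,
    -0.024, 5.057, -2.481, 5.354
  ), ncol = 2, byrow = TRUE,
  dimnames = list(c("N1","C2","O2","N3","C4","O4","C5","C7","C6","C1'"), NULL)),
  U = matrix(c(
    -1.284, 4.500, -1.462, 3.131, -2.563, 2.608, -0.302, 2.397,
     0.989, 2.884,  1.935, 2.094,  1.089, 4.311, -0.024, 5.053,
    -2.481, 5.354
  ), ncol = 2, byrow = TRUE,
  dimnames = list(c("N1","C2","O2","N3","C4","O4","C5","C6","C1'"), NULL))
)

# Ring atoms used for least-squares base-frame fitting (no exocyclics).
RING_ATOMS <- list(
  A = c("N9","C8","N7","C5","C6","N1","C2","N3","C4"),
  G = c("N9","C8","N7","C5","C6","N1","C2","N3","C4"),
  C = c("N1","C2","N3","C4","C5","C6"),
  T = c("N1","C2","N3","C4","C5","C6"),
  U = c("N1","C2","N3","C4","C5","C6")
)

# Canonical B-form backbone geometry (degrees): glycosidic chi (anti),
# gamma (O5'-C5'-C4'-C3'), beta (P-O5'-C5'-C4'), and the C2'-endo sugar
# pucker as pseudorotation phase P / amplitude tau_m.
BDNA_TORSIONS <- c(chi = -98, gamma = 54, beta = 171,
                   pucker_P = 162, pucker_amp = 38)

WC_COMPLEMENT <- c(A = "T", T = "A", G = "C", C = "G", U = "A")
BASE_TO_RESID <- c(A = "DA", C = "DC", G = "DG", T = "DT", U = "DU")

std_base_xyz <- function(base) {
  m <- STD_BASE_FRAME[[base]]
  cbind(m, 0)
}

ccd_templates_env <- new.env(parent = emptyenv())

# Idealized residue geometry table shipped with the package.
load_ccd_templates <- function() {
  if (!is.null(ccd_templates_env$tab)) return(ccd_templates_env$tab)
  path <- system.file("extdata", "nucleotide_templates.csv", package = "baseflip")
  if (!nzchar(path)) stop("nucleotide template table not found")
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  ccd_templates_env$tab <- tab
  tab
}

# Hydrogens that ride the base (kept); sugar/backbone hydrogens are dropped
# from the built structures.
base_hydrogens <- function(names, base_heavy) {
  h <- grepl("^H", names)
  h & !(names %in% MOIETY_TABLES$sugar)
}

#' Idealized nucleotide template in the base-pair standard frame
#'
#' Returns the full-atom template of one deoxyribonucleotide oriented in the
#' standard base reference frame, backbone rebuilt at canonical B-form
#' torsions. Used by the duplex builder.
#'
#' @param base one of "A","C","G","T","U".
#' @param with_hydrogens keep base hydrogens.
#' @return data.frame with columns name, element, x, y, z.
#' @keywords internal
nucleotide_template <- function(base, with_hydrogens = TRUE) {
  key <- paste0(base, if (with_hydrogens) "H" else "")
  if (!is.null(ccd_templates_env[[key]])) return(ccd_templates_env[[key]])
  tab <- load_ccd_templates()
  res <- tab[tab$resid == BASE_TO_RESID[[base]], ]
  xyz <- as.matrix(res[, c("x", "y", "z")])
  rownames(xyz) <- res$name

  # 1. superpose the idealized residue's ring + C1' onto the standard frame
  std <- std_base_xyz(base)
  fitn <- intersect(rownames(std), res$name)
  fit <- kabsch_fit(std[fitn, , drop = FALSE], xyz[fitn, , drop = FALSE])
  xyz <- apply_transform(xyz, fit$transform)

  # exact standard-frame coordinates for the fitted base atoms
  xyz[fitn, ] <- std[fitn, ]

  glyN <- if (base %in% c("A", "G")) "N9" else "N1"
  glyC <- if (base %in% c("A", "G")) "C4" else "C2"

  # 2. rebuild the deoxyribose and backbone from internal coordinates: chi
  # anti, C2'-endo pucker (endocyclic torsions nu_j = tau_m cos(P + 144(j-2)))
  # and canonical gamma/beta. Branch torsion offsets (+/-118, +/-119 deg)
  # reproduce the stereocenters of the idealized residue geometry.
  chi <- BDNA_TORSIONS[["chi"]]
  nu <- BDNA_TORSIONS[["pucker_amp"]] *
    cos(deg2rad(BDNA_TORSIONS[["pucker_P"]] + 144 * ((0:4) - 2)))
  xyz["O4'", ] <- place_atom_zmat(xyz[glyC, ], xyz[glyN, ], xyz["C1'", ],
                                  1.44, 109.8, chi)
  xyz["C2'", ] <- place_atom_zmat(xyz[glyC, ], xyz[glyN, ], xyz["C1'", ],
                                  1.54, 109.9, chi - 118)
  xyz["C3'", ] <- place_atom_zmat(xyz["O4'", ], xyz["C1'", ], xyz["C2'", ],
                                  1.55, 104.2, nu[2])
  xyz["C4'", ] <- place_atom_zmat(xyz["C1'", ], xyz["C2'", ], xyz["C3'", ],
                                  1.55, 102.1, nu[3])
  xyz["C5'", ] <- place_atom_zmat(xyz["C2'", ], xyz["C3'", ], xyz["C4'", ],
                                  1.51, 110.6, nu[4] - 119)
  xyz["O3'", ] <- place_atom_zmat(xyz["C1'", ], xyz["C2'", ], xyz["C3'", ],
                                  1.42, 110.9, nu[3] + 118)
  xyz["O5'", ] <- place_atom_zmat(xyz["C3'", ], xyz["C4'", ], xyz["C5'", ],
                                  1.44, 110.5, BDNA_TORSIONS[["gamma"]])
  xyz["P", ] <- place_atom_zmat(xyz["C4'", ], xyz["C5'", ], xyz["O5'", ],
                                1.60, 120.0, BDNA_TORSIONS[["beta"]])
  xyz["OP1", ] <- place_atom_zmat(xyz["C5'", ], xyz["O5'", ], xyz["P", ],
                                  1.48, 108.0, 60)
  xyz["OP2", ] <- place_atom_zmat(xyz["C5'", ], xyz["O5'", ], xyz["P", ],
                                  1.48, 108.0, -60)
  ring_gap <- vnorm(xyz["C4'", ] - xyz["O4'", ])
  if (abs(ring_gap - 1.45) > 0.35)
    stop(sprintf("sugar ring failed to close (C4'-O4' %.2f A)", ring_gap))

  keep <- res$name
  if (!with_hydrogens) keep <- keep[!grepl("^H", keep)]
  keep <- keep[!(grepl("^H", keep) & keep %in% MOIETY_TABLES$sugar)]
  out <- data.frame(
    name = keep,
    element = res$element[match(keep, res$name)],
    x = xyz[keep, 1], y = xyz[keep, 2], z = xyz[keep, 3],
    stringsAsFactors = FALSE, row.names = NULL
  )
  ccd_templates_env[[key]] <- out
  out
}
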
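# Shared fixtures and independent oracles used across the test files.

# Horn's quaternion method for optimal proper superposition: an independent
# oracle for the SVD-based Kabsch fit. Returns the minimal RMSD.
quaternion_rmsd <- function(reference, mobile) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  M <- t(P) %*% Q
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  n <- nrow(P)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lam) / n
  sqrt(max(0, msd))
}

# Independent signed dihedral: angle between the two plane normals, sign
# from the triple product with the central bond.
dihedral_oracle <- function(a, b, c, d) {
  n1 <- crossprod_vec(b - a, c - b)
  n2 <- crossprod_vec(c - b, d - c)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  if (sum(crossprod_vec(n1, n2) * (c - b)) < 0) ang <- -ang
  ang
}

crossprod_vec <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Hand-written three-atom PDB text (fixed columns), for parser echo tests.
write_three_atom_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  0.50 12.30           C",
    "ATOM      3  C   ALA A   1      10.736   6.822  -4.147  1.00  0.00           C",
    "END"), path)
  path
}

# Small two-residue peptide structure built in code.
tiny_peptide <- function() {
  atoms <- data.frame(
    serial = 1:6,
    name = c("N", "CA", "C", "N", "CA", "C"),
    element = c("N", "C", "C", "N", "C", "C"),
    resid = "GLY", chain = "A", resno = c(1, 1, 1, 2, 2, 2),
    insert = "", occ = 1, b = 0,
    mass = c(14.007, 12.011, 12.011, 14.007, 12.011, 12.011),
    stringsAsFactors = FALSE
  )
  xyz <- matrix(c(0, 0, 0, 1.5, 0, 0, 2.2, 1.2, 0,
                  3.5, 1.3, 0, 4.6, 2.2, 0, 6.0, 1.9, 0),
                ncol = 3, byrow = TRUE)
  mol_structure(atoms, xyz)
}

# The 17-mer flipping system used throughout: printed strand-I sequence with
# the thymine at position 12 replaced by uracil.
flip_sequence <- "CAGGATGTATATATCTG"

build_flip_duplex <- function(...) {
  build_duplex(flip_sequence, uracil_positions = 12, ...)
}
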
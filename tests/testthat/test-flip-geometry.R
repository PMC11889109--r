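# Pseudo-dihedral schemes, groove distance, hydrogen-bond and pair-center
# distances.

test_that("the four-point dihedral matches an independent oracle", {
  # analytic case: unit step points with a 90-degree twist
  a <- c(1, 0, 0); b <- c(0, 0, 0); cc <- c(0, 0, 1); d <- c(0, -1, 1)
  expect_equal(abs(dihedral_angle(a, b, cc, d)), 90, tolerance = 1e-9)
  set.seed(8)
  for (k in 1:25) {
    p <- matrix(rnorm(12, sd = 3), 4, 3)
    expect_equal(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 dihedral_oracle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
  }
})

test_that("flipped duplexes read back their angle through group COMs", {
  s <- build_flip_duplex()
  for (ang in c(-150, -60, 75, 150)) {
    f <- apply_base_flip(s, "A", 12, ang, scheme = "CPD")
    expect_equal(pseudo_dihedral(f, "A", 12, "CPD"), ang, tolerance = 1)
    # same number through the independent oracle on the exported group COMs
    g <- flip_scheme_groups(f, "A", 12, "CPD")
    p <- lapply(g, function(idx) center_of_mass(f, idx))
    expect_equal(dihedral_oracle(p$P1, p$P2, p$P3, p$P4), ang, tolerance = 1)
  }
})

test_that("pseudo-dihedral is invariant under global rigid motion", {
  f <- apply_base_flip(build_flip_duplex(), "A", 12, 120, scheme = "CPDb")
  ref <- pseudo_dihedral(f, "A", 12, "CPDb")
  set.seed(13)
  for (k in 1:6) {
    moved <- apply_transform(f, random_transform(25, 150))
    expect_equal(pseudo_dihedral(moved, "A", 12, "CPDb"), ref, tolerance = 1e-6)
  }
})

test_that("scheme errors are raised for terminal residues", {
  s <- build_flip_duplex()
  expect_error(pseudo_dihedral(s, "A", 17, "CPDb"), "flanking")
  expect_error(pseudo_dihedral(s, "A", 1, "CPDa"), "flanking")
  expect_error(pseudo_dihedral(s, "A", 1, "CPD"), "neighbor")
})

test_that("groove distance equals the exhaustive minimum over opposite-strand P", {
  # construction: single P atom placed 7 A from N1
  s <- build_flip_duplex()
  n1 <- coords(s)[which(s$atoms$chain == "A" & s$atoms$resno == 12 &
                          s$atoms$name == "N1"), ]
  oracle <- function(st) {
    ip <- which(st$atoms$name == "P" & st$atoms$chain == "B")
    min(sqrt(rowSums(sweep(coords(st)[ip, , drop = FALSE], 2,
                           coords(st)[which(st$atoms$chain == "A" &
                                              st$atoms$resno == 12 &
                                              st$atoms$name == "N1"), ])^2)))
  }
  expect_equal(u_groove_distance(s, "A", 12), oracle(s), tolerance = 1e-12)
  for (ang in c(-120, 90, 170)) {
    f <- apply_base_flip(s, "A", 12, ang, scheme = "CPDb")
    expect_equal(u_groove_distance(f, "A", 12), oracle(f), tolerance = 1e-12)
  }
  # toy with one opposite-strand P at a hand-set 7 A
  atoms <- data.frame(
    serial = 1:2, name = c("N1", "P"), element = c("N", "P"),
    resid = c("DU", "DA"), chain = c("A", "B"), resno = c(1, 2), insert = "",
    occ = 1, b = 0, mass = c(14.007, 30.974))
  toy <- mol_structure(atoms, matrix(c(0, 0, 0, 7, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(u_groove_distance(toy, "A", 1), 7)
})

test_that("Watson-Crick hydrogen bonds are short when paired, long when flipped", {
  s <- build_flip_duplex()
  hb <- wc_hbond_distances(s, c("A", 12), c("B", 23))
  expect_gt(hb[["N1_H3"]], 1.6)
  expect_lt(hb[["N1_H3"]], 2.1)
  expect_gt(hb[["O4_H6"]], 1.7)
  expect_lt(hb[["O4_H6"]], 2.4)
  # monotone growth with the flip angle, far beyond 5 A when fully flipped
  angs <- c(30, 90, 150, 175)
  d <- vapply(angs, function(a)
    wc_hbond_distances(apply_base_flip(s, "A", 12, a, scheme = "CPDb"),
                       c("A", 12), c("B", 23))[["N1_H3"]], numeric(1))
  expect_true(all(diff(d) > 0))
  expect_gt(d[length(d)], 5)
  # hydrogens absent -> requires-hydrogens error
  bare <- build_duplex(flip_sequence, uracil_positions = 12,
                       with_hydrogens = FALSE)
  expect_error(wc_hbond_distances(bare, c("A", 12), c("B", 23)), "hydrogens")
  # hand-set coordinates: two atoms 2.00 A apart
  atoms <- data.frame(
    serial = 1:4, name = c("H3", "O4", "N1", "H61"),
    element = c("H", "O", "N", "H"),
    resid = c("DU", "DU", "DA", "DA"), chain = c("A", "A", "B", "B"),
    resno = c(1, 1, 2, 2), insert = "", occ = 1, b = 0,
    mass = c(1.008, 15.999, 14.007, 1.008))
  toy <- mol_structure(atoms, matrix(c(0, 0, 0, 1, 1, 0, 2, 0, 0, 1, 1, 2),
                                     4, 3, byrow = TRUE))
  hb <- wc_hbond_distances(toy, c("A", 1), c("B", 2))
  expect_equal(hb[["N1_H3"]], 2.00)
  expect_equal(hb[["O4_H6"]], 2.00)
})

test_that("pair center distance follows the summation oracle and conventions", {
  s <- build_flip_duplex()
  expect_equal(pair_com_distance(s, c("A", 12), c("A", 12)), 0)
  # oracle: direct unweighted mean over residue atoms
  ctr <- function(ch, rn) {
    idx <- which(s$atoms$chain == ch & s$atoms$resno == rn)
    colMeans(coords(s)[idx, ])
  }
  expect_equal(pair_com_distance(s, c("A", 12), c("B", 23)),
               sqrt(sum((ctr("A", 12) - ctr("B", 23))^2)), tolerance = 1e-12)
  # mass weighting oracle
  ctrm <- function(ch, rn) {
    idx <- which(s$atoms$chain == ch & s$atoms$resno == rn)
    colSums(coords(s)[idx, ] * s$atoms$mass[idx]) / sum(s$atoms$mass[idx])
  }
  expect_equal(pair_com_distance(s, c("A", 12), c("B", 23), weighting = "mass"),
               sqrt(sum((ctrm("A", 12) - ctrm("B", 23))^2)), tolerance = 1e-12)
  # the base-only distance is much shorter than the whole-residue one
  expect_lt(pair_com_distance(s, c("A", 12), c("B", 23), atoms = "base"),
            pair_com_distance(s, c("A", 12), c("B", 23)))
})

test_that("flips toward each groove carry the documented sign", {
  s <- build_flip_duplex()
  for (ang in c(30, 90, 160)) {
    fmaj <- apply_base_flip(s, "A", 12, ang, groove = "major", scheme = "CPD")
    fmin <- apply_base_flip(s, "A", 12, ang, groove = "minor", scheme = "CPD")
    expect_gt(pseudo_dihedral(fmaj, "A", 12, "CPD"), 0)
    expect_lt(pseudo_dihedral(fmin, "A", 12, "CPD"), 0)
    # CPDb agrees on the side
    expect_gt(pseudo_dihedral(fmaj, "A", 12, "CPDb"),
              pseudo_dihedral(fmin, "A", 12, "CPDb"))
  }
})

test_that("flip_metrics assembles a coherent record", {
  f <- apply_base_flip(build_flip_duplex(), "A", 12, 170, scheme = "CPD")
  m <- flip_metrics(f, "A", 12, "CPD")
  expect_equal(m$dihedral, 170, tolerance = 1)
  expect_gt(m$d_U_groove, 0)
  expect_gt(m$hbond_N1_H3, 5)
  expect_equal(m$groove_side, 1)
})
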
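# The idealized duplex builder, its helical-parameter round trips and the
# controlled base flip.

test_that("the printed 17-mer builds 17 Watson-Crick pairs", {
  s <- build_flip_duplex()
  rt <- unique(s$atoms[, c("chain", "resno", "resid")])
  expect_equal(nrow(rt), 34)
  expect_equal(sum(rt$chain == "A"), 17)
  expect_equal(rt$resid[rt$chain == "A" & rt$resno == 12], "DU")
  expect_equal(rt$resid[rt$chain == "B" & rt$resno == 23], "DA")
  # strand II complements strand I under the 2N+1-j pairing
  comp <- c(A = "T", T = "A", G = "C", C = "G", U = "A")
  b1 <- canonical_base(rt$resid[rt$chain == "A"][order(rt$resno[rt$chain == "A"])])
  b2 <- canonical_base(rt$resid[rt$chain == "B"][order(rt$resno[rt$chain == "B"])])
  expect_equal(rev(b2), unname(comp[b1]))
})

test_that("degenerate sizes and bad characters are handled", {
  one <- build_duplex("G")
  expect_equal(nrow(unique(one$atoms[, c("chain", "resno")])), 2)
  expect_error(build_duplex("ACGX"), "invalid sequence")
  expect_error(duplex_spec("ACGT", uracil_positions = 9), "positions")
})

test_that("step parameters recovered from the build match the generating values", {
  two <- build_duplex("AT")
  st <- step_parameters(two, list("A", 1, "B", 4), list("A", 2, "B", 3))
  expect_equal(st$twist, 36, tolerance = 0.5)
  expect_equal(st$rise, 3.38, tolerance = 0.05)
  expect_equal(st$roll, 0, tolerance = 0.5)
  expect_equal(st$tilt, 0, tolerance = 0.5)

  steps <- data.frame(twist = c(34, 38), roll = c(5, -3), tilt = c(2, 0),
                      shift = c(0.3, 0), slide = c(-0.4, 0.2), rise = c(3.2, 3.5))
  s <- build_duplex(duplex_spec("ACG", steps = steps))
  for (i in 1:2) {
    st <- step_parameters(s, list("A", i, "B", 7 - i), list("A", i + 1, "B", 6 - i))
    expect_equal(st$twist, steps$twist[i], tolerance = 0.5)
    expect_equal(st$roll, steps$roll[i], tolerance = 0.5)
    expect_equal(st$tilt, steps$tilt[i], tolerance = 0.5)
    expect_equal(st$rise, steps$rise[i], tolerance = 0.05)
    expect_equal(st$shift, steps$shift[i], tolerance = 0.05)
    expect_equal(st$slide, steps$slide[i], tolerance = 0.05)
  }
})

test_that("the idealized build is planar-paired: |buckle|, |opening| < 2 deg", {
  s <- build_flip_duplex()
  for (i in c(1, 5, 9, 12, 17)) {
    bp <- base_pair_parameters(s, list("A", i, "B", 35 - i))
    expect_lt(abs(bp$buckle), 2)
    expect_lt(abs(bp$opening), 2)
    expect_lt(abs(bp$propeller), 2)
  }
})

test_that("constructed pair deformations are recovered by name", {
  s <- build_flip_duplex()
  bp0 <- base_pair_parameters(s, list("A", 9, "B", 26))
  axes <- bp0$frame$axes
  rotate_base <- function(st, axis_col, ang) {
    idx <- select_atoms(st, "chain A and resno 9 and base")
    x <- coords(st)
    ctr <- bp0$frame$origin
    R <- rotation_about_axis(axes[, axis_col], ang)
    x[idx, ] <- sweep(sweep(x[idx, , drop = FALSE], 2, ctr) %*% t(R), 2, ctr, "+")
    set_coords(st, x)
  }
  # rotation about the pair x (short) axis reads as buckle
  bx <- base_pair_parameters(rotate_base(s, 1, 20), list("A", 9, "B", 26))
  expect_equal(abs(bx$buckle), 20, tolerance = 1.5)
  # rotation about the pair y (long) axis reads as propeller
  by <- base_pair_parameters(rotate_base(s, 2, 20), list("A", 9, "B", 26))
  expect_equal(abs(by$propeller), 20, tolerance = 1.5)
  # rotation about the pair normal reads as opening
  bz <- base_pair_parameters(rotate_base(s, 3, 25), list("A", 9, "B", 26))
  expect_equal(abs(bz$opening), 25, tolerance = 1.5)
})

test_that("bend angle is near zero when straight and recovers a designed arc", {
  s <- build_flip_duplex()
  expect_lt(bend_angle(s), 5)
  # accumulate 5 deg of roll over the 8 central steps -> 40 deg designed bend
  steps <- data.frame(twist = 36, roll = c(rep(0, 4), rep(5, 8), rep(0, 4)),
                      tilt = 0, shift = 0, slide = 0, rise = 3.38)
  bent <- build_duplex(duplex_spec(flip_sequence, uracil_positions = 12,
                                   steps = steps))
  expect_equal(bend_angle(bent), 40, tolerance = 5)
  # rigid rotation leaves the bend unchanged
  set.seed(3)
  moved <- apply_transform(bent, random_transform(20, 120))
  expect_equal(bend_angle(moved), bend_angle(bent), tolerance = 1e-6)
  expect_error(bend_angle(build_duplex("ACGTACG")), "at least 8")
})

test_that("apply_base_flip reaches the requested angle over the full sweep", {
  s <- build_flip_duplex()
  for (scheme in c("CPD", "CPDb")) {
    for (ang in seq(-180, 180, by = 15)) {
      f <- apply_base_flip(s, "A", 12, ang, scheme = scheme)
      expect_equal(wrap_angle(pseudo_dihedral(f, "A", 12, scheme) - ang), 0,
                   tolerance = 1)
    }
  }
})

test_that("flipping moves only the target base atoms", {
  s <- build_flip_duplex()
  f <- apply_base_flip(s, "A", 12, 120, scheme = "CPDb")
  base_idx <- as.integer(select_atoms(s, "chain A and resno 12 and base"))
  other <- setdiff(seq_len(n_atoms(s)), base_idx)
  expect_lt(max(abs(coords(f)[other, ] - coords(s)[other, ])), 1e-6)
  expect_gt(max(abs(coords(f)[base_idx, ] - coords(s)[base_idx, ])), 1)
  # a 0-degree request on an already-flat structure barely moves anything
  f0 <- apply_base_flip(s, "A", 12, pseudo_dihedral(s, "A", 12, "CPDb"),
                        scheme = "CPDb")
  expect_lt(max(abs(coords(f0) - coords(s))), 0.01)
})

test_that("the groove argument forces the sign convention", {
  s <- build_flip_duplex()
  fmaj <- apply_base_flip(s, "A", 12, 100, groove = "major", scheme = "CPDb")
  fmin <- apply_base_flip(s, "A", 12, 100, groove = "minor", scheme = "CPDb")
  expect_gt(pseudo_dihedral(fmaj, "A", 12, "CPDb"), 0)
  expect_lt(pseudo_dihedral(fmin, "A", 12, "CPDb"), 0)
})

test_that("mock complexes are deterministic with the pocket where requested", {
  s <- apply_base_flip(build_flip_duplex(), "A", 12, 170, scheme = "CPDb")
  cx0 <- build_mock_complex(s, pocket_offset = c(0, 0, 0), seed = 4)
  n3 <- coords(cx0)[which(cx0$atoms$resid == "DU" & cx0$atoms$name == "N3"), ]
  marker <- coords(cx0)[which(cx0$atoms$chain == "R" & cx0$atoms$resno == 1), ]
  expect_equal(as.numeric(marker), as.numeric(n3), tolerance = 1e-9)
  off <- c(3, 0, 4)
  cx5 <- build_mock_complex(s, pocket_offset = off, seed = 4)
  marker5 <- coords(cx5)[which(cx5$atoms$chain == "R" & cx5$atoms$resno == 1), ]
  expect_equal(sqrt(sum((marker5 - n3)^2)), 5, tolerance = 1e-9)
  cx5b <- build_mock_complex(s, pocket_offset = off, seed = 4)
  expect_equal(coords(cx5b), coords(cx5))
  expect_error(build_mock_complex(build_duplex("ACGT")), "no uracil")
})

test_that("pose sets are reproducible and scale with their parameters", {
  s <- apply_base_flip(build_flip_duplex(), "A", 12, 170, scheme = "CPDb")
  cx <- build_mock_complex(s, seed = 4)
  one <- generate_pose_set(cx, 1, seed = 2)
  expect_equal(uracil_similarity_distance(pose_structure(one, 0), cx), 0,
               tolerance = 1e-9)
  frozen <- generate_pose_set(cx, 50, displacement = 0, rotation = 0, seed = 2)
  for (id in c(0, 10, 49))
    expect_equal(coords(pose_structure(frozen, id)), coords(cx))
  # mean uracil displacement grows with the displacement scale
  n3 <- which(cx$atoms$resid == "DU" & cx$atoms$name == "N3")
  mean_disp <- function(scale) {
    ps <- generate_pose_set(cx, 120, displacement = scale, rotation = 0, seed = 5)
    mean(vapply(seq_len(119), function(id)
      sqrt(sum((coords(pose_structure(ps, id))[n3, ] - coords(cx)[n3, ])^2)),
      numeric(1)))
  }
  d <- vapply(c(1, 4, 8), mean_disp, numeric(1))
  expect_true(all(diff(d) > 0))
})
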
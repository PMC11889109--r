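# The docking-evaluation protocol: uracil similarity distance, success
# classification and the summary over flip metrics.

is_dna_atom <- function(cx) !is.na(canonical_base(cx$atoms$resid))

make_reference <- function(seed = 4) {
  f <- apply_base_flip(build_flip_duplex(), "A", 12, 170, scheme = "CPDb")
  build_mock_complex(f, seed = seed)
}

test_that("success classification maps the documented intervals", {
  expect_equal(as.character(classify_success(2.0)), "High")
  expect_equal(as.character(classify_success(4.5)), "Medium")
  expect_equal(as.character(classify_success(7.5)), "Low")
  expect_equal(as.character(classify_success(12)), "None")
  # boundaries fall to the worse class
  expect_equal(as.character(classify_success(c(3, 6, 9))),
               c("Medium", "Low", "None"))
  expect_error(classify_success(-1), "non-negative")
  # total monotone step function: larger distance never improves the label
  d <- seq(0, 20, by = 0.25)
  lv <- as.integer(classify_success(d))
  expect_true(all(diff(lv) <= 0))
})

test_that("the similarity distance reads constructed displacements", {
  cx <- make_reference()
  expect_equal(uracil_similarity_distance(cx, cx), 0, tolerance = 1e-9)
  # pure receptor-frame rotation of the entire complex: alignment removes it
  set.seed(31)
  for (k in 1:5) {
    g <- apply_transform(cx, random_transform(15, 120))
    expect_equal(uracil_similarity_distance(g, cx), 0, tolerance = 1e-6)
  }
  # DNA partner translated 4 A in the receptor frame
  dna <- which(is_dna_atom(cx))
  shifted <- apply_transform(cx, rigid_transform(diag(3), c(4, 0, 0)),
                             atoms = dna)
  expect_equal(uracil_similarity_distance(shifted, cx), 4, tolerance = 0.1)
  # and global motion on top of that changes nothing
  g2 <- apply_transform(shifted, random_transform(20, 90))
  expect_equal(uracil_similarity_distance(g2, cx), 4, tolerance = 0.1)
})

test_that("pose-set evaluation flags retention and classifies by the minimum", {
  cx <- make_reference()
  ps <- generate_pose_set(cx, 30, displacement = 4, rotation = 15, seed = 7)
  ev <- evaluate_pose_set(ps)
  expect_equal(nrow(ev), 30)
  expect_equal(attr(ev, "best_distance"), 0, tolerance = 1e-9)  # identity pose
  expect_equal(as.character(attr(ev, "label")), "High")
  expect_equal(ev$retained, ev$d_U1_U2 < 15)

  # far scenario: every pose pushed beyond the cutoff; the label still comes
  # from the unfiltered minimum
  far <- ps
  far$transforms <- lapply(far$transforms, function(tf)
    compose_transforms(rigid_transform(diag(3), c(40, 0, 0)), tf))
  evf <- evaluate_pose_set(far)
  expect_equal(sum(evf$retained), 0)
  expect_equal(as.character(attr(evf, "label")), "None")
  expect_equal(attr(evf, "best_distance"), min(evf$d_U1_U2))
})

test_that("constructed displacement magnitudes rank the poses", {
  cx <- make_reference()
  ps <- generate_pose_set(cx, 300, displacement = 6, rotation = 25, seed = 9)
  n3 <- which(cx$atoms$resid == "DU" & cx$atoms$name == "N3")
  truth <- vapply(seq_len(300) - 1, function(id)
    sqrt(sum((coords(pose_structure(ps, id))[n3, ] - coords(cx)[n3, ])^2)),
    numeric(1))
  ev <- evaluate_pose_set(ps)
  expect_equal(ev$pose[which.min(ev$d_U1_U2)], which.min(truth) - 1)
  expect_gte(cor(truth, ev$d_U1_U2, method = "spearman"), 0.95)
})

test_that("the benchmark summary reproduces the published groove threshold", {
  bench <- udg_docking_benchmark()
  expect_equal(nrow(bench), 21)
  sm <- summarize_success_table(bench[, c("structure", "dihedral", "d_U_groove")],
                                bench[, c("structure", "success")])
  expect_equal(sm$n, 21)
  expect_equal(unname(sm$counts["High"]), 5L)
  expect_equal(sm$min_d_u_groove_high_int, 13)
  expect_equal(sm$high_dihedral_range, c(51.9, 173.2))

  one <- bench[bench$structure == "O4", ]
  s1 <- summarize_success_table(one[, c("structure", "dihedral", "d_U_groove")],
                                one[, c("structure", "success")])
  expect_equal(s1$min_d_u_groove_high, s1$min_d_u_groove_high)
  expect_equal(s1$high_dihedral_range[1], s1$high_dihedral_range[2])

  none <- bench[bench$success == "None", ]
  s0 <- summarize_success_table(none[, c("structure", "dihedral", "d_U_groove")],
                                none[, c("structure", "success")])
  expect_null(s0$min_d_u_groove_high)
  expect_error(summarize_success_table(
    bench[1:3, c("structure", "dihedral", "d_U_groove")],
    bench[4:6, c("structure", "success")]), "do not match")
})
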
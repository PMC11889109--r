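# Synthetic docking stand-ins: a mock receptor with a binding pocket at a
# known location relative to the flipped uracil, and randomized rigid-body
# pose sets emulating the raw output of an FFT docking run.

#' Build a mock receptor-DNA complex
#'
#' Adds a rigid pseudo-protein chain (a C-alpha cloud plus a pocket marker
#' C-alpha placed at the uracil N3 position plus `pocket_offset`) to a
#' structure containing a uracil. The receptor is a deterministic function
#' of `seed`.
#'
#' @param flipped_dna a `mol_structure` containing a uracil (resid DU/URA/U).
#' @param pocket_atoms number of receptor residues (C-alpha atoms) beyond
#'   the pocket marker.
#' @param pocket_offset length-3 offset (Angstrom) of the pocket marker from
#'   the uracil N3 atom.
#' @param seed integer seed for the receptor cloud.
#' @param chain receptor chain identifier.
#' @return a `mol_structure` with the extra receptor chain; attribute
#'   `uracil` holds `c(chain, resno)` of the uracil found.
#' @export
build_mock_complex <- function(flipped_dna, pocket_atoms = 60,
                               pocket_offset = c(0, 0, 0), seed = 1,
                               chain = "R") {
  stopifnot(inherits(flipped_dna, "mol_structure"))
  a <- flipped_dna$atoms
  u <- which(toupper(a$resid) %in% URACIL_ANALOGS & toupper(a$name) == "N3")
  if (length(u) == 0) stop("no uracil with an N3 atom in the input structure")
  n3 <- coords(flipped_dna)[u[1], ]
  marker <- n3 + pocket_offset
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  # rigid cloud on the pocket side: shells 6..18 A from the marker
  cloud <- matrix(stats::rnorm(3 * pocket_atoms), ncol = 3)
  cloud <- cloud / sqrt(rowSums(cloud^2)) * stats::runif(pocket_atoms, 6, 18)
  cloud <- sweep(cloud, 2, marker, "+")
  xyz <- rbind(marker, cloud)
  rec <- data.frame(
    serial = max(a$serial) + seq_len(nrow(xyz)),
    name = "CA", element = "C", resid = "ALA", chain = chain,
    resno = seq_len(nrow(xyz)), insert = "", occ = 1, b = 0,
    mass = 12.011, stringsAsFactors = FALSE
  )
  atoms <- rbind(a, rec)
  out_xyz <- lapply(flipped_dna$xyz, function(m) rbind(m, xyz))
  out <- mol_structure(atoms, out_xyz,
                       title = paste(flipped_dna$title, "+ mock receptor"))
  attr(out, "uracil") <- c(a$chain[u[1]], a$resno[u[1]])
  attr(out, "receptor_chain") <- chain
  attr(out, "provenance") <- "synthetic"
  out
}

#' Generate a randomized rigid-body docking pose set
#'
#' Draws `n` rigid perturbations of the DNA partner of a reference complex
#' (rotations about the DNA centroid with angle `|N(0, rotation^2)|` about a
#' uniform axis, translations `N(0, displacement^2/3)` per component). Pose
#' 0 is always the identity. Reproducible given `seed`.
#'
#' @param reference a complex `mol_structure` (receptor chain of amino
#'   acids + DNA chains).
#' @param n number of poses (>= 1).
#' @param displacement translation scale in Angstrom.
#' @param rotation rotation scale in degrees.
#' @param seed integer seed.
#' @return object of class `pose_set`: list with `reference`, `transforms`
#'   (length n, ids 0..n-1), `dna_atoms`, `seed` and the scales.
#' @export
generate_pose_set <- function(reference, n, displacement = 4, rotation = 20,
                              seed = 1) {
  stopifnot(inherits(reference, "mol_structure"), n >= 1)
  dna_atoms <- which(is_nucleotide(reference$atoms$resid))
  if (length(dna_atoms) == 0) stop("reference complex has no DNA partner")
  centroid <- colMeans(coords(reference)[dna_atoms, , drop = FALSE])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  transforms <- vector("list", n)
  transforms[[1]] <- transform_identity()
  if (n > 1) for (i in 2:n)
    transforms[[i]] <- random_transform(displacement, rotation, about = centroid)
  structure(list(reference = reference, transforms = transforms,
                 dna_atoms = dna_atoms, seed = seed,
                 displacement = displacement, rotation = rotation),
            class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  cat(sprintf("pose_set: %d poses (seed %d, displacement %.1f A, rotation %.1f deg)\n",
              length(x$transforms), x$seed, x$displacement, x$rotation))
  invisible(x)
}

#' Materialize one pose of a pose set
#'
#' @param poses a `pose_set`.
#' @param id pose id, 0-based (0 = identity pose).
#' @return a `mol_structure` with the DNA partner transformed.
#' @export
pose_structure <- function(poses, id) {
  stopifnot(inherits(poses, "pose_set"),
            id >= 0, id < length(poses$transforms))
  apply_transform(poses$reference, poses$transforms[[id + 1]],
                  atoms = poses$dna_atoms)
}

#' Serialize a pose set's transforms to CSV
#'
#' One row per pose: id, the nine rotation entries (row major), the three
#' translation components, and the seed.
#'
#' @param poses a `pose_set`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_pose_set <- function(poses, path) {
  rows <- lapply(seq_along(poses$transforms), function(i) {
    tf <- poses$transforms[[i]]
    c(id = i - 1, as.vector(t(tf$R)), tf$t, seed = poses$seed)
  })
  m <- do.call(rbind, rows)
  colnames(m) <- c("id", paste0("r", rep(1:3, each = 3), rep(1:3, 3)),
                   "tx", "ty", "tz", "seed")
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}
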
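# Docking-pose evaluation against a reference recognition complex: after
# superposing the receptors, the distance between the N3 atoms of the
# evaluated uracil and the reference uracil (d_U1-U2) scores each pose; the
# best pose per structure is classified None/Low/Medium/High.

SUCCESS_LEVELS <- c("None", "Low", "Medium", "High")

detect_receptor_chain <- function(s) {
  rt <- residue_table(s)
  aa <- rt[is_amino(rt$resid), , drop = FALSE]
  if (nrow(aa) == 0) stop("no amino-acid (receptor) chain found")
  names(sort(table(aa$chain), decreasing = TRUE))[1]
}

find_uracil_n3 <- function(s, analog_names = URACIL_ANALOGS) {
  a <- s$atoms
  hit <- which(toupper(a$resid) %in% toupper(analog_names) &
                 toupper(a$name) == "N3")
  if (length(hit) == 0) stop("no uracil (or uracil analog) N3 atom found")
  hit[1]
}

#' Uracil similarity distance of a docking pose
#'
#' Superposes the pose's receptor onto the reference receptor (Kabsch on
#' C-alpha atoms of residues common to both, by residue number), applies the
#' transform to the whole pose, and returns the distance between the N3 atom
#' of the pose's uracil and that of the reference uracil.
#'
#' @param pose,reference complex `mol_structure`s, each with a receptor
#'   chain and a uracil.
#' @param receptor_chain optional receptor chain id (auto-detected as the
#'   chain with amino-acid residues when NULL).
#' @param analog_names residue names accepted as uracil/uracil-analog.
#' @return distance in Angstrom.
#' @export
uracil_similarity_distance <- function(pose, reference,
                                       receptor_chain = NULL,
                                       analog_names = URACIL_ANALOGS) {
  rc_pose <- if (is.null(receptor_chain)) detect_receptor_chain(pose) else receptor_chain
  rc_ref <- if (is.null(receptor_chain)) detect_receptor_chain(reference) else receptor_chain
  ca <- function(s, ch) {
    idx <- select_atoms(s, sprintf("chain %s and calpha", ch))
    data.frame(resno = s$atoms$resno[idx], idx = as.integer(idx))
  }
  cp <- ca(pose, rc_pose); cr <- ca(reference, rc_ref)
  common <- intersect(cp$resno, cr$resno)
  if (length(common) < 3)
    stop("fewer than 3 shared receptor residues; cannot align")
  ip <- cp$idx[match(common, cp$resno)]
  ir <- cr$idx[match(common, cr$resno)]
  fit <- kabsch_fit(coords(reference)[ir, , drop = FALSE],
                    coords(pose)[ip, , drop = FALSE])
  posed <- apply_transform(pose, fit$transform)
  n3p <- find_uracil_n3(posed, analog_names)
  n3r <- find_uracil_n3(reference, analog_names)
  vnorm(coords(posed)[n3p, ] - coords(reference)[n3r, ])
}

#' Classify docking success from the best-pose distance
#'
#' Interval map on d_U1-U2: High below 3 A, Medium in [3, 6), Low in
#' [6, 9), None at 9 A and beyond. Boundaries fall to the worse class.
#'
#' @param best_distance distance(s) in Angstrom, >= 0.
#' @return ordered factor with levels None < Low < Medium < High.
#' @export
classify_success <- function(best_distance) {
  if (any(best_distance < 0)) stop("distance must be non-negative")
  cut(best_distance, breaks = c(-Inf, 3, 6, 9, Inf),
      labels = rev(SUCCESS_LEVELS), right = FALSE) |>
    factor(levels = SUCCESS_LEVELS, ordered = TRUE)
}

#' Evaluate every pose of a pose set
#'
#' Scores each pose by its uracil similarity distance against the reference
#' complex, flags the subset retained under the display cutoff, and
#' classifies the set by its best (minimum) distance. The cutoff is a
#' retention filter only; classification always uses the global minimum.
#'
#' @param poses a `pose_set`.
#' @param reference reference complex (defaults to the pose set's own
#'   reference, which contains the identity pose geometry).
#' @param cutoff retention cutoff in Angstrom.
#' @param receptor_chain optional receptor chain id.
#' @return data.frame (class `pose_evaluation`) with columns `pose`,
#'   `d_U1_U2`, `retained`; attributes `best_distance`, `best_pose`,
#'   `label`.
#' @export
evaluate_pose_set <- function(poses, reference = NULL, cutoff = 15,
                              receptor_chain = NULL) {
  stopifnot(inherits(poses, "pose_set"))
  if (length(poses$transforms) == 0) stop("empty pose set")
  if (is.null(reference)) reference <- poses$reference
  d <- vapply(seq_along(poses$transforms) - 1, function(id)
    uracil_similarity_distance(pose_structure(poses, id), reference,
                               receptor_chain), numeric(1))
  out <- data.frame(pose = seq_along(d) - 1, d_U1_U2 = d,
                    retained = d < cutoff)
  attr(out, "best_distance") <- min(d)
  attr(out, "best_pose") <- out$pose[which.min(d)]
  attr(out, "label") <- classify_success(min(d))
  class(out) <- c("pose_evaluation", "data.frame")
  out
}

#' @export
print.pose_evaluation <- function(x, ...) {
  cat(sprintf("pose_evaluation: %d poses, %d retained; best d_U1-U2 %.2f A (pose %d) -> %s\n",
              nrow(x), sum(x$retained), attr(x, "best_distance"),
              attr(x, "best_pose"), as.character(attr(x, "label"))))
  invisible(x)
}

#' Summarize flip metrics against docking success labels
#'
#' Joins a table of per-structure flip metrics (columns `structure`,
#' `dihedral`, `d_U_groove`) with success labels (columns `structure`,
#' `success`) and reports per-label counts, the dihedral magnitude range
#' among High entries, and the minimum groove distance among High entries
#' (to 0.1 A, plus its integer rounding).
#'
#' @param metrics data.frame of flip metrics.
#' @param labels data.frame of success labels.
#' @return list summary record.
#' @export
summarize_success_table <- function(metrics, labels) {
  need_m <- c("structure", "dihedral", "d_U_groove")
  need_l <- c("structure", "success")
  if (!all(need_m %in% names(metrics)) || !all(need_l %in% names(labels)))
    stop("metrics needs columns ", paste(need_m, collapse = ","),
         "; labels needs ", paste(need_l, collapse = ","))
  j <- merge(metrics, labels, by = "structure")
  if (nrow(j) < nrow(metrics) || nrow(j) < nrow(labels))
    stop("structure ids do not match between metrics and labels")
  j$success <- factor(as.character(j$success), levels = SUCCESS_LEVELS,
                      ordered = TRUE)
  hi <- j[j$success == "High", , drop = FALSE]
  list(
    n = nrow(j),
    counts = table(j$success),
    high_dihedral_range = if (nrow(hi)) range(abs(hi$dihedral)) else NULL,
    min_d_u_groove_high = if (nrow(hi)) round(min(hi$d_U_groove), 1) else NULL,
    min_d_u_groove_high_int = if (nrow(hi)) round(round(min(hi$d_U_groove), 1)) else NULL
  )
}

#' Benchmark table of flip metrics and docking success
#'
#' The published evaluation of 21 base-flip structures (the crystal
#' recognition complex, twelve trinucleosome-derived snapshots T1..T12 and
#' eight oligomer snapshots O1..O8): flipping pseudo-dihedral, groove
#' distance and docking success class for each. Useful as a reference input
#' for [summarize_success_table()].
#'
#' @return data.frame with columns `structure`, `dihedral`, `d_U_groove`,
#'   `success`.
#' @export
udg_docking_benchmark <- function() {
  data.frame(
    structure = c("1EMH", paste0("T", 1:12), paste0("O", 1:8)),
    dihedral = c(-171.75,
                 -5.85, 2.61, -4.71, -3.16, -8.66, -66.12, -96.58, -83.18,
                 -108.82, 145.12, -119.20, 175.94,
                 1.82, 9.81, 51.9, -173.2, -103.6, 151.7, 103.9, 160.5),
    d_U_groove = c(20.8,
                   11.8, 12.9, 14.2, 11.5, 12.9, 12.0, 10.4, 10.8, 11.1, 8.3,
                   12.8, 10.4,
                   14.4, 15.2, 13.2, 16.4, 10.9, 15.8, 10.0, 13.3),
    success = c("High",
                "None", "None", "None", "None", "None", "Low", "Medium",
                "Medium", "Medium", "Medium", "Medium", "Medium",
                "None", "None", "High", "High", "Medium", "High", "Low", "High"),
    stringsAsFactors = FALSE
  )
}
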
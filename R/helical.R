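# Base-pair and base-pair-step rigid-body parameters. Frames are fitted by
# least squares onto the standard base reference frames; parameters follow
# the mid-frame (CEHS-style) convention, so the builder's generation and the
# analyzer's extraction are exact inverses of each other.
#
# The core identity: with frames T1, T2 (columns = x, y, z axes) and origins
# o1, o2, the relative rotation t(T1) %*% T2 is the ZYZ Euler product
# Rz(twist/2 - phi) Ry(Gamma) Rz(twist/2 + phi) with Gamma the bend
# magnitude and phi its phase; roll = Gamma cos(phi), tilt = Gamma sin(phi).
# Translations (shift, slide, rise) are the mid-frame components of o2 - o1.

# Compose: given frame (T1, o1) and the six parameters, return (T2, o2).
step_compose <- function(T1, o1, twist, roll, tilt, shift, slide, rise) {
  gam <- sqrt(roll^2 + tilt^2)
  phi <- if (gam < 1e-12) 0 else rad2deg(atan2(tilt, roll))
  M <- rot_z(twist / 2 - phi) %*% rot_y(gam) %*% rot_z(twist / 2 + phi)
  Tm <- T1 %*% rot_z(twist / 2 - phi) %*% rot_y(gam / 2) %*% rot_z(phi)
  list(T2 = T1 %*% M,
       o2 = o1 + as.numeric(Tm %*% c(shift, slide, rise)),
       Tm = Tm, om = o1 + as.numeric(Tm %*% c(shift, slide, rise)) / 2)
}

# Decompose: given two frames, recover the six parameters and the mid-frame.
step_decompose <- function(T1, o1, T2, o2) {
  M <- t(T1) %*% T2
  cb <- max(-1, min(1, M[3, 3]))
  gam <- rad2deg(acos(cb))
  if (gam > 1e-7 && gam < 180 - 1e-7) {
    alpha <- rad2deg(atan2(M[2, 3], M[1, 3]))
    gamma <- rad2deg(atan2(M[3, 2], -M[3, 1]))
  } else {
    # z axes (anti)parallel: twist about z only, phase undefined -> 0
    alpha <- rad2deg(atan2(M[2, 1], M[1, 1])) / 2
    gamma <- alpha
  }
  twist <- wrap_angle(alpha + gamma)
  # phi from the wrapped twist, not (gamma - alpha)/2: alpha and gamma are
  # each only defined mod 360, which would leave phi ambiguous mod 180
  phi <- wrap_angle(twist / 2 - alpha)
  roll <- gam * cos(deg2rad(phi))
  tilt <- gam * sin(deg2rad(phi))
  Tm <- T1 %*% rot_z(alpha) %*% rot_y(gam / 2) %*% rot_z(phi)
  disp <- as.numeric(t(Tm) %*% (o2 - o1))
  list(twist = twist, roll = roll, tilt = tilt,
       shift = disp[1], slide = disp[2], rise = disp[3],
       Tm = Tm, om = (o1 + o2) / 2)
}

#' Fit the standard reference frame of one base
#'
#' Least-squares (Kabsch) fit of the base's ring atoms onto the standard
#' base-frame template. The returned rotation's columns are the frame's
#' x, y, z axes in laboratory coordinates; the origin is the frame center.
#'
#' @param s a `mol_structure`.
#' @param chain,resno residue identifier.
#' @param model model index.
#' @return list with `axes` (3x3), `origin`, `rmsd` (fit quality, Angstrom)
#'   and `base` (canonical code).
#' @export
base_frame <- function(s, chain, resno, model = 1) {
  idx <- residue_indices(s, chain, resno)
  if (length(idx) == 0) stop("residue ", chain, ":", resno, " not found")
  base <- canonical_base(s$atoms$resid[idx[1]])
  if (is.na(base)) stop("residue ", chain, ":", resno, " is not a nucleotide")
  ring <- RING_ATOMS[[base]]
  sel <- idx[match(ring, s$atoms$name[idx])]
  if (anyNA(sel)) {
    # tolerate C-linked analogs (e.g. pseudouridine): fit on present atoms
    pres <- ring %in% s$atoms$name[idx]
    if (sum(pres) < 3) stop("missing ring atoms for residue ", chain, ":", resno)
    ring <- ring[pres]
    sel <- idx[match(ring, s$atoms$name[idx])]
  }
  std <- std_base_xyz(base)[ring, , drop = FALSE]
  obs <- coords(s, model)[sel, , drop = FALSE]
  fit <- kabsch_fit(obs, std)
  if (fit$rmsd > 0.5)
    warning(sprintf("degenerate base: frame fit RMSD %.2f A for %s:%d",
                    fit$rmsd, chain, resno))
  list(axes = fit$transform$R, origin = fit$transform$t,
       rmsd = fit$rmsd, base = base)
}

# Frame of a base on the complementary strand, flipped (y and z negated) so
# both frames of a Watson-Crick pair have matching orientation.
flipped_frame <- function(fr) {
  list(axes = fr$axes %*% diag(c(1, -1, -1)), origin = fr$origin,
       rmsd = fr$rmsd, base = fr$base)
}

#' Intra-base-pair parameters
#'
#' Buckle, propeller, opening (degrees) and shear, stretch, stagger
#' (Angstrom) of one Watson-Crick pair, from the two fitted base frames via
#' the mid-frame convention. The strand II frame is flipped before
#' decomposition; parameters describe strand I relative to strand II.
#'
#' @param s a `mol_structure`.
#' @param pair list/vector of two residue ids: `chain1, resno1, chain2,
#'   resno2` (strand I first).
#' @param model model index.
#' @return list with the six parameters plus `frame` (the pair mid-frame:
#'   `axes`, `origin`).
#' @export
base_pair_parameters <- function(s, pair, model = 1) {
  f1 <- base_frame(s, pair[[1]], as.integer(pair[[2]]), model)
  f2 <- flipped_frame(base_frame(s, pair[[3]], as.integer(pair[[4]]), model))
  d <- step_decompose(f2$axes, f2$origin, f1$axes, f1$origin)
  list(buckle = d$tilt, propeller = d$roll, opening = d$twist,
       shear = d$shift, stretch = d$slide, stagger = d$rise,
       frame = list(axes = d$Tm, origin = d$om))
}

#' Base-pair-step parameters
#'
#' Tilt, roll, twist (degrees) and shift, slide, rise (Angstrom) between two
#' consecutive base pairs, from the two pair mid-frames.
#'
#' @param s a `mol_structure`.
#' @param pair1,pair2 residue-id quadruples as in
#'   [base_pair_parameters()]; `pair2` is the 3'-side pair.
#' @param model model index.
#' @return list with the six step parameters.
#' @export
step_parameters <- function(s, pair1, pair2, model = 1) {
  p1 <- base_pair_parameters(s, pair1, model)
  p2 <- base_pair_parameters(s, pair2, model)
  d <- step_decompose(p1$frame$axes, p1$frame$origin,
                      p2$frame$axes, p2$frame$origin)
  d[c("twist", "roll", "tilt", "shift", "slide", "rise")]
}

#' Global bend angle of a duplex
#'
#' Angle between the helical-axis direction fitted over the first four steps
#' and over the last four steps. The local axis direction is the principal
#' axis of the base-pair centers, oriented 5' to 3' on strand I.
#'
#' @param s a `mol_structure` built with strand I = chain A, resno 1..N and
#'   strand II = chain B, resno 2N+1-i, or an explicit list of pairs.
#' @param pairs optional list of residue-id quadruples (one per pair, 5' to
#'   3'); derived from the builder numbering when omitted.
#' @param model model index.
#' @return bend angle in degrees.
#' @export
bend_angle <- function(s, pairs = NULL, model = 1) {
  if (is.null(pairs)) pairs <- builder_pairs(s)
  if (length(pairs) < 8) stop("need at least 8 base pairs for a bend angle")
  centers <- t(vapply(pairs, function(p)
    base_pair_parameters(s, p, model)$frame$origin, numeric(3)))
  seg_dir <- function(rows) {
    x <- centers[rows, , drop = FALSE]
    x <- sweep(x, 2, colMeans(x))
    v <- svd(x)$v[, 1]
    # orient along increasing pair index
    if (sum(v * (centers[rows[length(rows)], ] - centers[rows[1], ])) < 0) v <- -v
    v
  }
  n <- nrow(centers)
  v1 <- seg_dir(1:5)
  v2 <- seg_dir((n - 4):n)
  rad2deg(acos(max(-1, min(1, sum(v1 * v2)))))
}

# Pair list implied by the builder numbering (chain A 1..N vs chain B
# 2N+1-i); also accepts any two-chain duplex with that pairing pattern.
builder_pairs <- function(s) {
  rt <- residue_table(s)
  rt <- rt[is_nucleotide(rt$resid), ]
  ch <- unique(rt$chain)
  if (length(ch) != 2) stop("cannot infer pairing: expected exactly 2 DNA chains")
  r1 <- sort(rt$resno[rt$chain == ch[1]])
  n <- length(r1)
  lapply(r1, function(i) list(ch[1], i, ch[2], 2 * n + 1 - i))
}
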
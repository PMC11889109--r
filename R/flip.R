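# Controlled base flipping: rotate the target base as a rigid body about the
# backbone anchor axis of the active pseudo-dihedral scheme until the
# recomputed coordinate equals the requested signed angle. Because the
# dihedral is measured about the same P2-P3 axis the rotation is performed
# about, the relation is exact up to round-off; a small fixed-point loop
# absorbs the COM shift of the moving base re-entering P4.

#' Rotate a base out of the helix to a prescribed flipping angle
#'
#' Only the base moiety of the target residue (ring, exocyclics and base
#' hydrogens) moves; the backbone and every other residue are untouched.
#' Positive angles open toward the major groove, negative toward the minor
#' groove, matching the pseudo-dihedral sign convention.
#'
#' @param s a `mol_structure`.
#' @param chain,resno target residue.
#' @param angle requested flipping angle in degrees; its sign is overridden
#'   by `groove` when that is given.
#' @param groove optional `"major"` or `"minor"`: forces the sign of the
#'   requested angle (+ for major).
#' @param scheme pseudo-dihedral scheme whose P2-P3 axis anchors the
#'   rotation and whose coordinate is matched.
#' @param model model index.
#' @param tol convergence tolerance on the achieved angle (degrees).
#' @return the modified structure, with attribute `achieved_angle`.
#' @export
apply_base_flip <- function(s, chain, resno, angle, groove = NULL,
                            scheme = c("CPD", "CPDa", "CPDb"), model = 1,
                            tol = 1) {
  scheme <- match.arg(scheme)
  if (abs(angle) > 180) stop("|angle| must be <= 180 degrees")
  if (!is.null(groove)) {
    groove <- match.arg(groove, c("major", "minor"))
    angle <- if (groove == "major") abs(angle) else -abs(angle)
  }
  base_idx <- select_atoms(
    s, sprintf("chain %s and resno %d and base", chain, resno))
  if (length(base_idx) == 0)
    stop("residue ", chain, ":", resno, " has no base moiety")
  g <- flip_scheme_groups(s, chain, resno, scheme)
  p2 <- center_of_mass(s, g$P2, model)
  p3 <- center_of_mass(s, g$P3, model)
  axis <- p3 - p2
  if (vnorm(axis) < 0.5) stop("degenerate anchor axis for scheme ", scheme)

  rotate_base <- function(st, delta) {
    x <- coords(st, model)
    R <- rotation_about_axis(axis, delta)
    x[base_idx, ] <- sweep(sweep(x[base_idx, , drop = FALSE], 2, p3) %*% t(R),
                           2, p3, "+")
    set_coords(st, x, model)
  }

  # sign probe: determine the rotation sense that increases the dihedral
  cur <- pseudo_dihedral(s, chain, resno, scheme, model)
  probe <- pseudo_dihedral(rotate_base(s, 1), chain, resno, scheme, model)
  sense <- if (wrap_angle(probe - cur) >= 0) 1 else -1

  achieved <- cur
  for (it in 1:8) {
    resid <- wrap_angle(angle - achieved)
    if (abs(resid) < min(tol, 1e-6)) break
    s <- rotate_base(s, sense * resid)
    achieved <- pseudo_dihedral(s, chain, resno, scheme, model)
  }
  if (abs(wrap_angle(angle - achieved)) > tol)
    stop(sprintf(
      "base flip did not converge: requested %.2f, achieved %.2f degrees",
      angle, achieved))
  attr(s, "achieved_angle") <- achieved
  s
}
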
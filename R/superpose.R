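# Rigid-body superposition (Kabsch) and the transform algebra used by the
# docking evaluation and trajectory analysis.

#' Construct a rigid transform
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation length-3 numeric vector (Angstrom).
#' @return object of class `rigid_transform` mapping x to R x + t.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3, 3)),
            length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation matrix is not orthogonal")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rotation matrix is not proper (det != +1)")
  structure(list(R = rotation, t = as.numeric(translation)),
            class = "rigid_transform")
}

#' Identity transform
#' @return a `rigid_transform`.
#' @export
transform_identity <- function() rigid_transform()

#' Compose two rigid transforms
#'
#' `compose_transforms(t2, t1)` is the transform "apply t1, then t2".
#'
#' @param t2,t1 `rigid_transform` objects.
#' @return a `rigid_transform`.
#' @export
compose_transforms <- function(t2, t1) {
  rigid_transform(t2$R %*% t1$R, as.numeric(t2$R %*% t1$t) + t2$t)
}

#' Invert a rigid transform
#' @param tf a `rigid_transform`.
#' @return a `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$R), as.numeric(-t(tf$R) %*% tf$t))
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rad2deg(acos(pmin(1, pmax(-1, (sum(diag(x$R)) - 1) / 2))))
  cat(sprintf("rigid_transform: rotation %.2f deg, translation %.3f A\n",
              ang, vnorm(x$t)))
  invisible(x)
}

#' Optimal proper superposition of two point sets (Kabsch)
#'
#' Finds the rigid transform (rotation + translation, reflections excluded)
#' minimizing the RMSD between `mobile` mapped onto `reference`.
#'
#' @param reference,mobile N x 3 coordinate matrices, equal N >= 3.
#' @return list with `transform` (a `rigid_transform` such that
#'   `transform(mobile)` best matches `reference`) and `rmsd` (Angstrom).
#' @export
kabsch_fit <- function(reference, mobile) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  if (nrow(reference) != nrow(mobile))
    stop("point sets differ in length; cannot pair")
  if (nrow(reference) < 3) stop("need at least 3 points for superposition")
  cr <- colMeans(reference)
  cm <- colMeans(mobile)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  H <- crossprod(P, Q)
  sv <- svd(H)
  if (sv$d[2] < 1e-10)
    warning("degenerate (near-collinear) point set; superposition is not unique")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  tvec <- cr - as.numeric(R %*% cm)
  moved <- sweep(mobile %*% t(R), 2, tvec, "+")
  list(transform = rigid_transform(R, tvec),
       rmsd = rmsd_nofit(reference, moved))
}

#' Root-mean-square deviation without fitting
#'
#' @param a,b N x 3 coordinate matrices of equal size.
#' @return RMSD in Angstrom.
#' @export
rmsd_nofit <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("coordinate sets differ in size")
  sqrt(sum((a - b)^2) / nrow(a))
}

#' Apply a rigid transform to coordinates or a structure
#'
#' @param x a `mol_structure` or an N x 3 matrix.
#' @param tf a `rigid_transform`.
#' @param atoms optional atom indices: only these atoms are moved (structures
#'   only).
#' @param model model index for structures; `NULL` (default) moves all models.
#' @return the transformed object.
#' @export
apply_transform <- function(x, tf, atoms = NULL, model = NULL) {
  stopifnot(inherits(tf, "rigid_transform"))
  mov <- function(m) sweep(m %*% t(tf$R), 2, tf$t, "+")
  if (is.matrix(x)) return(mov(x))
  stopifnot(inherits(x, "mol_structure"))
  models <- if (is.null(model)) seq_len(n_models(x)) else model
  for (mi in models) {
    m <- coords(x, mi)
    if (is.null(atoms)) m <- mov(m)
    else m[atoms, ] <- mov(m[atoms, , drop = FALSE])
    x <- set_coords(x, m, mi)
  }
  x
}

#' Draw a random rigid transform
#'
#' Rotation axis uniform on the sphere with angle `|N(0, rotation^2)|`
#' degrees; translation components i.i.d. `N(0, displacement^2/3)` so the
#' expected squared displacement norm is `displacement^2`.
#'
#' @param displacement translation scale in Angstrom.
#' @param rotation rotation scale in degrees.
#' @param about optional length-3 center: the rotation is taken about this
#'   point rather than the origin.
#' @return a `rigid_transform`.
#' @export
random_transform <- function(displacement = 1, rotation = 10, about = NULL) {
  ax <- stats::rnorm(3)
  while (vnorm(ax) < 1e-8) ax <- stats::rnorm(3)
  ang <- abs(stats::rnorm(1, 0, rotation))
  R <- rotation_about_axis(ax, ang)
  tr <- stats::rnorm(3, 0, displacement / sqrt(3))
  if (!is.null(about))
    tr <- tr + as.numeric(about - R %*% about)
  rigid_transform(R, tr)
}
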
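# Desk-scale metadynamics on a 1D periodic flipping coordinate: overdamped
# Langevin dynamics on a toy free-energy surface plus a history-dependent
# bias built from deposited Gaussian hills; the negative accumulated bias
# reconstructs the potential of mean force (PMF).

#' Metadynamics configuration
#'
#' Defaults follow the production settings of pseudo-dihedral base-flipping
#' metadynamics: coordinate range -180..180 degrees in 5-degree windows,
#' Gaussian hill weight 0.001 kcal/mol, hill width of 2 bin widths
#' (read as the Gaussian sigma, 10 degrees), 310 K.
#'
#' @param bin_width PMF bin width in degrees (must divide 360).
#' @param hill_weight Gaussian hill height in kcal/mol.
#' @param hill_width hill width in degrees; interpreted as sigma when
#'   `width_is_sigma` is TRUE (default), else as FWHM.
#' @param width_is_sigma interpretation flag for `hill_width`.
#' @param stride steps between hill depositions.
#' @param temperature K.
#' @param friction friction coefficient in kcal/mol * ps / deg^2; the
#'   mobility is 1/friction.
#' @param timestep integration step in fs.
#' @param steps total integration steps.
#' @param seed RNG seed.
#' @param sample_stride steps between trajectory samples.
#' @return object of class `metad_config`.
#' @export
metad_config <- function(bin_width = 5, hill_weight = 0.001, hill_width = 10,
                         width_is_sigma = TRUE, stride = 25,
                         temperature = 310, friction = 0.001, timestep = 1,
                         steps = 4e6, seed = 1, sample_stride = 1000) {
  if (360 %% bin_width != 0) stop("bin width must divide 360 degrees")
  if (hill_weight <= 0) stop("hill weight must be positive")
  if (stride < 1) stop("deposition stride must be >= 1")
  sigma <- if (width_is_sigma) hill_width else hill_width / (2 * sqrt(2 * log(2)))
  structure(list(bin_width = bin_width, hill_weight = hill_weight,
                 hill_sigma = sigma, stride = as.integer(stride),
                 temperature = temperature, friction = friction,
                 timestep = timestep, steps = as.integer(steps),
                 seed = as.integer(seed),
                 sample_stride = as.integer(sample_stride),
                 kT = 0.0019872041 * temperature),
            class = "metad_config")
}

#' Periodic double-well toy surface
#'
#' Wells at 0 (intrahelical) and 180 degrees (fully flipped), equal barriers
#' of height `barrier` at +/-90 degrees: U(s) = barrier/2 (1 - cos 2s).
#'
#' @param barrier barrier height in kcal/mol.
#' @return list with `f(s)` and `grad(s)` (degrees -> kcal/mol).
#' @export
surface_double_well <- function(barrier = 8.2) {
  list(f = function(s) barrier / 2 * (1 - cos(2 * deg2rad(s))),
       grad = function(s) barrier * sin(2 * deg2rad(s)) * pi / 180,
       name = sprintf("double well, barrier %.2f kcal/mol", barrier))
}

#' Asymmetric two-branch flipping surface
#'
#' Wells at 0 and 180 degrees; the barrier on the positive (major-groove)
#' branch at +90 has height `b_major`, the one on the negative
#' (minor-groove) branch at -90 has height `b_minor`. Gaussian bumps of
#' width `w` degrees on a flat background.
#'
#' @param b_major,b_minor branch barrier heights in kcal/mol.
#' @param w bump width (sigma) in degrees.
#' @return list with `f(s)` and `grad(s)`.
#' @export
surface_two_branch <- function(b_major = 7.5, b_minor = 8.2, w = 30) {
  pgauss <- function(s, c0) {
    x <- wrap_angle(s - c0)
    exp(-x^2 / (2 * w^2))
  }
  dpgauss <- function(s, c0) {
    x <- wrap_angle(s - c0)
    -x / w^2 * exp(-x^2 / (2 * w^2))
  }
  list(f = function(s) b_major * pgauss(s, 90) + b_minor * pgauss(s, -90),
       grad = function(s) b_major * dpgauss(s, 90) + b_minor * dpgauss(s, -90),
       name = sprintf("two-branch, %.1f/%.1f kcal/mol", b_major, b_minor))
}

#' Run metadynamics on a toy surface
#'
#' Overdamped Langevin dynamics on `surface` plus the accumulating bias;
#' a Gaussian hill is deposited at the walker position every `stride` steps.
#' Fully reproducible given the config seed.
#'
#' @param surface a surface list (`f`, `grad`) as returned by
#'   [surface_double_well()] or [surface_two_branch()].
#' @param config a `metad_config`.
#' @param s0 starting position in degrees.
#' @return object of class `metad_run`: list with `traj` (sampled
#'   positions), `hills` (data.frame step, center, height, width) and
#'   `config`.
#' @export
run_metadynamics <- function(surface, config = metad_config(), s0 = 0) {
  stopifnot(inherits(config, "metad_config"))
  ng <- 360L
  grid <- seq(-180, 180 - 360 / ng, length.out = ng)
  surf_force <- -surface$grad(grid)
  if (any(!is.finite(surf_force))) stop("surface gradient is not finite")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  res <- .metad_run_cpp(surf_force, s0, config$steps,
                        config$timestep * 1e-3, 1 / config$friction,
                        config$kT, config$stride, config$hill_weight,
                        config$hill_sigma, config$sample_stride,
                        -180, 180)
  hills <- data.frame(step = res$hill_steps, center = res$centers,
                      height = rep(config$hill_weight, length(res$centers)),
                      width = rep(config$hill_sigma, length(res$centers)))
  structure(list(traj = res$traj, hills = hills, config = config,
                 surface = surface$name), class = "metad_run")
}

#' @export
print.metad_run <- function(x, ...) {
  cat(sprintf("metad_run: %d steps on %s; %d hills deposited\n",
              x$config$steps, x$surface, nrow(x$hills)))
  invisible(x)
}

#' Bias potential of an accumulated hill trace
#'
#' Sum of periodic Gaussians: V(s) = sum_i h_i exp(-d(s, c_i)^2 / (2 w_i^2))
#' with d the minimum-image difference on the 360-degree circle.
#'
#' @param hills data.frame with columns `center`, `height`, `width` (or a
#'   `metad_run`).
#' @param s positions in degrees (vectorized).
#' @return bias energies in kcal/mol.
#' @export
bias_potential <- function(hills, s) {
  if (inherits(hills, "metad_run")) hills <- hills$hills
  if (nrow(hills) == 0) return(rep(0, length(s)))
  vapply(s, function(si) {
    d <- wrap_angle(si - hills$center)
    sum(hills$height * exp(-d^2 / (2 * hills$width^2)))
  }, numeric(1))
}

#' Reconstruct the PMF from deposited hills
#'
#' Standard metadynamics estimator: F(s) = -V_bias(s) + const, evaluated at
#' the bin centers of the configured grid and shifted so the minimum is 0.
#'
#' @param run a `metad_run` (or a hills data.frame, with `config` given).
#' @param config a `metad_config` (taken from `run` when omitted).
#' @return object of class `pmf_grid`: data.frame with `center` (degrees)
#'   and `free_energy` (kcal/mol).
#' @export
pmf_estimate <- function(run, config = NULL) {
  hills <- if (inherits(run, "metad_run")) run$hills else run
  if (is.null(config)) {
    if (!inherits(run, "metad_run")) stop("config needed when passing bare hills")
    config <- run$config
  }
  if (nrow(hills) == 0) stop("no hills deposited; cannot estimate a PMF")
  centers <- seq(-180 + config$bin_width / 2, 180 - config$bin_width / 2,
                 by = config$bin_width)
  fe <- -bias_potential(hills, centers)
  fe <- fe - min(fe)
  structure(data.frame(center = centers, free_energy = fe),
            class = c("pmf_grid", "data.frame"))
}

#' @export
print.pmf_grid <- function(x, ...) {
  cat(sprintf("pmf_grid: %d bins, range %.2f kcal/mol\n",
              nrow(x), max(x$free_energy)))
  invisible(x)
}

#' @export
plot.pmf_grid <- function(x, ...) {
  plot(x$center, x$free_energy, type = "l",
       xlab = "flipping coordinate (degrees)",
       ylab = "free energy (kcal/mol)", ...)
}

#' Barrier height read off a PMF
#'
#' Free energy at the bin nearest `at` degrees, relative to the minimum over
#' the well region within `well_half_width` of `well` degrees.
#'
#' @param pmf a `pmf_grid`.
#' @param at barrier-top position in degrees.
#' @param well well-bottom position in degrees.
#' @param well_half_width half width of the well search window (degrees).
#' @return barrier height in kcal/mol.
#' @export
pmf_barrier <- function(pmf, at = 90, well = 0, well_half_width = 45) {
  top <- pmf$free_energy[which.min(abs(wrap_angle(pmf$center - at)))]
  in_well <- abs(wrap_angle(pmf$center - well)) <= well_half_width
  top - min(pmf$free_energy[in_well])
}
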
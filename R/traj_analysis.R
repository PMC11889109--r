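# Trajectory descriptors for multi-model structures: RMSD time series,
# radius of gyration with probability distribution, per-residue RMSF.

traj_selection <- function(s, selection) {
  idx <- if (is.character(selection)) select_atoms(s, selection)
  else as.integer(selection)
  if (length(idx) == 0) stop("empty selection")
  idx
}

#' RMSD time series over a trajectory
#'
#' Each frame is superposed (Kabsch) onto the reference frame on the
#' selection; the fitted RMSD is reported per frame.
#'
#' @param s a multi-model `mol_structure`.
#' @param selection criteria string or atom indices.
#' @param reference reference frame index.
#' @param fit superpose before measuring (default TRUE).
#' @return data.frame with `frame` and `rmsd` (Angstrom).
#' @export
rmsd_series <- function(s, selection = "heavy", reference = 1, fit = TRUE) {
  if (n_models(s) < 2) stop("need at least 2 frames for an RMSD series")
  idx <- traj_selection(s, selection)
  ref <- coords(s, reference)[idx, , drop = FALSE]
  vals <- vapply(seq_len(n_models(s)), function(i) {
    m <- coords(s, i)[idx, , drop = FALSE]
    if (fit) kabsch_fit(ref, m)$rmsd else rmsd_nofit(ref, m)
  }, numeric(1))
  data.frame(frame = seq_len(n_models(s)), rmsd = vals)
}

#' Radius of gyration series
#'
#' Mass-weighted by default: Rg^2 = sum(m_i |r_i - com|^2) / sum(m_i).
#'
#' @param s a `mol_structure` (any number of models).
#' @param selection criteria string or atom indices.
#' @param weighting `"mass"` or `"geometric"`.
#' @return data.frame with `frame` and `rg` (Angstrom).
#' @export
rg_series <- function(s, selection = "heavy",
                      weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  idx <- traj_selection(s, selection)
  w <- if (weighting == "mass") s$atoms$mass[idx] else rep(1, length(idx))
  vals <- vapply(seq_len(n_models(s)), function(i) {
    m <- coords(s, i)[idx, , drop = FALSE]
    com <- colSums(m * w) / sum(w)
    sqrt(sum(w * rowSums(sweep(m, 2, com)^2)) / sum(w))
  }, numeric(1))
  data.frame(frame = seq_len(n_models(s)), rg = vals)
}

#' Probability histogram of a value series
#'
#' Fixed-width bins covering the data range; normalized so the bin
#' probabilities sum to one.
#'
#' @param values numeric vector.
#' @param bin_width bin width in the value's units.
#' @return data.frame with `center` and `probability`.
#' @export
probability_histogram <- function(values, bin_width) {
  stopifnot(bin_width > 0, length(values) > 0)
  lo <- floor(min(values) / bin_width) * bin_width
  hi <- ceiling(max(values) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- hist(values, breaks = breaks, plot = FALSE)
  data.frame(center = h$mids, probability = h$counts / length(values))
}

#' Per-residue RMSF profile
#'
#' Frames are iteratively superposed onto the mean structure (two passes),
#' then RMSF_i = sqrt(<|r_i - <r_i>|^2>) is aggregated per residue over the
#' selected atoms.
#'
#' @param s a multi-model `mol_structure`.
#' @param selection criteria string or atom indices.
#' @param fit_selection atoms used for the superposition (defaults to
#'   `selection`; needs >= 3 atoms).
#' @return data.frame with `chain`, `resno`, `rmsf` (Angstrom).
#' @export
rmsf_profile <- function(s, selection = "heavy", fit_selection = selection) {
  if (n_models(s) < 2) stop("need at least 2 frames for RMSF")
  idx <- traj_selection(s, selection)
  fidx <- traj_selection(s, fit_selection)
  frames <- lapply(seq_len(n_models(s)), function(i)
    coords(s, i)[idx, , drop = FALSE])
  fit_frames <- lapply(seq_len(n_models(s)), function(i)
    coords(s, i)[fidx, , drop = FALSE])
  mean_fit <- Reduce("+", fit_frames) / length(fit_frames)
  for (pass in 1:2) {
    tfs <- lapply(fit_frames, function(m) kabsch_fit(mean_fit, m)$transform)
    fit_frames <- Map(apply_transform, fit_frames, tfs)
    frames <- Map(apply_transform, frames, tfs)
    mean_fit <- Reduce("+", fit_frames) / length(fit_frames)
  }
  mean_xyz <- Reduce("+", frames) / length(frames)
  dev2 <- Reduce("+", lapply(frames, function(m)
    rowSums((m - mean_xyz)^2))) / length(frames)
  key <- paste(s$atoms$chain[idx], s$atoms$resno[idx])
  agg <- tapply(dev2, key, mean)
  ord <- !duplicated(key)
  data.frame(chain = s$atoms$chain[idx][ord],
             resno = s$atoms$resno[idx][ord],
             rmsf = sqrt(as.numeric(agg[match(key[ord], names(agg))])))
}
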
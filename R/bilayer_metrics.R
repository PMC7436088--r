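#' Bilayer thickness of a single frame
#'
#' Thickness is the distance between the mean z of the upper-leaflet
#' phosphorus atoms and the mean z of the lower-leaflet ones — the P-P
#' definition commonly used to validate membrane simulations.
#'
#' @param frame an `mp_frame`.
#' @param topology the lipid topology.
#' @param leaflets leaflet labels from [assign_leaflets()]; computed when
#'   omitted.
#' @return thickness in Angstrom.
#' @export
bilayer_thickness <- function(frame, topology, leaflets = NULL) {
  leaflets <- leaflets %||% assign_leaflets(frame, topology)
  sel <- frame$residue_names == topology$name &
    frame$atom_names == topology$phosphorus_atom
  z <- frame$xyz[sel, 3]
  lab <- leaflets[as.character(frame$residue_ids[sel])]
  if (!any(lab == "upper") || !any(lab == "lower"))
    stopf("degenerate bilayer: a leaflet has no phosphorus atoms")
  mean(z[lab == "upper"]) - mean(z[lab == "lower"])
}

#' Area per lipid of a single frame
#'
#' The xy box area divided by the number of phospholipids in a leaflet,
#' computed per leaflet and averaged. When the cholesterol fraction exceeds
#' 20% the reported value must be reduced by 10-20%, so a corrected range
#' `(0.80*A_l, 0.90*A_l)` accompanies the raw value; below that threshold
#' the range collapses to the raw value.
#'
#' @inheritParams bilayer_thickness
#' @param chol_fraction cholesterol mole fraction in `[0, 1]`.
#' @return list with `apl` (Angstrom^2), `corrected_low`, `corrected_high`,
#'   and `per_leaflet` counts.
#' @export
area_per_lipid <- function(frame, topology, leaflets = NULL,
                           chol_fraction = 0) {
  stopifnot(chol_fraction >= 0, chol_fraction <= 1)
  leaflets <- leaflets %||% assign_leaflets(frame, topology)
  n_up <- sum(leaflets == "upper")
  n_lo <- sum(leaflets == "lower")
  if (n_up == 0 || n_lo == 0)
    stopf("degenerate bilayer: a leaflet contains no lipids")
  area <- frame$box[1] * frame$box[2]
  apl <- mean(c(area / n_up, area / n_lo))
  if (chol_fraction > 0.20)
    corrected <- c(0.80 * apl, 0.90 * apl)
  else
    corrected <- c(apl, apl)
  list(apl = apl, corrected_low = corrected[1], corrected_high = corrected[2],
       per_leaflet = c(upper = n_up, lower = n_lo))
}

#' Aggregate thickness and area per lipid over a trajectory
#'
#' @param trajectory an `mp_trajectory` (typically the output of
#'   [analysis_frames()]).
#' @param topology the lipid topology.
#' @param chol_fraction cholesterol mole fraction in `[0, 1]`.
#' @return an object of class `mp_bilayer_metrics` with per-frame values,
#'   means, sample SDs (0 for a single frame) and the cholesterol-corrected
#'   area-per-lipid range.
#' @examples
#' sim <- gen_bilayer(bilayer_preset("popc", n_lipids_per_leaflet = 16),
#'                    n_frames = 3)
#' bilayer_metrics(sim$trajectory, sim$topology)
#' @export
bilayer_metrics <- function(trajectory, topology, chol_fraction = 0) {
  stopifnot(inherits(trajectory, "mp_trajectory"))
  th <- numeric(0); ap <- numeric(0)
  for (fr in trajectory$frames) {
    leaf <- assign_leaflets(fr, topology)
    th <- c(th, bilayer_thickness(fr, topology, leaf))
    ap <- c(ap, area_per_lipid(fr, topology, leaf, chol_fraction)$apl)
  }
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  apl_mean <- mean(ap)
  corr <- if (chol_fraction > 0.20) c(0.80, 0.90) * apl_mean
          else c(apl_mean, apl_mean)
  structure(list(
    per_frame_time = frame_times(trajectory),
    per_frame_thickness = th,
    per_frame_area_per_lipid = ap,
    thickness_mean = mean(th), thickness_sd = sd0(th),
    apl_mean = apl_mean, apl_sd = sd0(ap),
    chol_fraction = chol_fraction,
    apl_corrected_range = corr), class = "mp_bilayer_metrics")
}

#' @export
print.mp_bilayer_metrics <- function(x, ...) {
  cat(sprintf("Bilayer metrics over %d frame(s)\n",
              length(x$per_frame_thickness)))
  cat(sprintf("  thickness: %.2f +/- %.2f A\n",
              x$thickness_mean, x$thickness_sd))
  cat(sprintf("  area per lipid: %.2f +/- %.2f A^2\n", x$apl_mean, x$apl_sd))
  if (x$chol_fraction > 0.20)
    cat(sprintf("  cholesterol %.0f%% > 20%%: corrected A_l %.2f-%.2f A^2\n",
                100 * x$chol_fraction, x$apl_corrected_range[1],
                x$apl_corrected_range[2]))
  invisible(x)
}
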
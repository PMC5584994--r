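#' Random-access scanning schedule
#'
#' In random-access multiphoton (RAMP) imaging the laser visits a fixed list
#' of voxels in turn, dwelling `dwell_time` microseconds at each; the frame
#' rate is the reciprocal of the time to complete one sweep, so fewer voxels
#' mean faster sampling. The default per-voxel period of 54.054 us (50 us
#' dwell plus repositioning) is calibrated so that 5 voxels give exactly
#' 3700 Hz, reproducing the published frequency ladder
#' (5 voxels - 3700 Hz, 10 - 1850, 20 - 925, 40 - 462, 80 - 231).
#'
#' @param n_voxels Number of voxels visited per frame.
#' @param dwell_time Photon-collection time per voxel per visit, us
#'   (default 50).
#' @param per_voxel_period Total time per voxel per frame including
#'   repositioning, us (default `1e6 / (5 * 3700)` = 54.054).
#' @return A `scan_schedule` with fields `n_voxels`, `dwell_time`,
#'   `per_voxel_period` (us) and `frame_rate` (Hz).
#' @export
scan_schedule <- function(n_voxels, dwell_time = 50,
                          per_voxel_period = 1e6 / (5 * 3700)) {
  if (n_voxels < 1) stop("n_voxels must be at least 1")
  if (per_voxel_period < dwell_time) {
    stop("per_voxel_period must be at least the dwell time")
  }
  structure(list(n_voxels = as.integer(n_voxels), dwell_time = dwell_time,
                 per_voxel_period = per_voxel_period,
                 frame_rate = scan_frequency(n_voxels, per_voxel_period)),
            class = "scan_schedule")
}

#' Frame rate implied by a scanning schedule
#'
#' @param n_voxels Number of voxels visited per frame (>= 1).
#' @param per_voxel_period Time per voxel per frame in us
#'   (default 54.054, see [scan_schedule()]).
#' @return Frame rate in Hz: `1 / (n_voxels * per_voxel_period)` in
#'   consistent units.
#' @examples
#' scan_frequency(5)   # 3700 Hz
#' scan_frequency(20)  # 925 Hz
#' @export
scan_frequency <- function(n_voxels, per_voxel_period = 1e6 / (5 * 3700)) {
  if (any(n_voxels < 1)) stop("n_voxels must be at least 1")
  1e6 / (n_voxels * per_voxel_period)
}

#' @export
print.scan_schedule <- function(x, ...) {
  cat(sprintf(
    "Scan schedule: %d voxels, %.3g us dwell, %.4g us/voxel -> %.4g Hz\n",
    x$n_voxels, x$dwell_time, x$per_voxel_period, x$frame_rate))
  invisible(x)
}

#' Multi-exponential photobleaching model
#'
#' Fluorophore brightness decays under illumination as a weighted sum of
#' exponentials, normalized to 1 at t = 0. Applied multiplicatively to the
#' instantaneous photon rate in the forward model.
#'
#' @param weights Component weights, summing to 1.
#' @param taus Component time constants in seconds (may be `Inf` for a
#'   non-bleaching component).
#' @return A `bleach_model`.
#' @examples
#' b <- bleach_model(c(0.3, 0.7), c(5, 200))
#' bleach_value(b, 0)  # 1
#' @export
bleach_model <- function(weights = 1, taus = Inf) {
  if (length(weights) != length(taus)) {
    stop("weights and taus must have equal length")
  }
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (any(taus <= 0)) stop("taus must be positive")
  structure(list(weights = weights, taus = taus), class = "bleach_model")
}

#' Evaluate a bleach model
#'
#' @param model A [bleach_model()].
#' @param t Time(s) in seconds.
#' @return Relative brightness in (0, 1], equal to 1 at t = 0 and monotone
#'   non-increasing.
#' @export
bleach_value <- function(model, t) {
  stopifnot(inherits(model, "bleach_model"))
  out <- numeric(length(t))
  for (i in seq_along(model$weights)) {
    out <- out + model$weights[i] * exp(-t / model$taus[i])
  }
  out
}

#' Imaged-cell geometry for multi-voxel simulations
#'
#' Describes the voxels placed on a cell: distance from the soma, resting
#' photon rate, and the amplitude attenuation applied to backpropagating
#' signals at that distance. Attenuation must be 1 at the soma and
#' non-increasing with distance; signal arrival is delayed by
#' `distance / conduction_velocity`.
#'
#' @param voxels data.frame with columns `voxel_id`, `distance_um`,
#'   `rest_rate` (photons per dwell) and `attenuation` (in (0, 1\]).
#' @param conduction_velocity Propagation speed in m/s (default 0.16);
#'   `Inf` means simultaneous arrival everywhere.
#' @return A `cell_geometry`.
#' @export
cell_geometry <- function(voxels, conduction_velocity = 0.16) {
  voxels <- as.data.frame(voxels)
  need <- c("voxel_id", "distance_um", "rest_rate", "attenuation")
  if (!all(need %in% names(voxels))) {
    stop("voxels must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(voxels) == 0) stop("geometry must contain at least one voxel")
  if (any(voxels$attenuation <= 0 | voxels$attenuation > 1)) {
    stop("attenuation factors must lie in (0, 1]")
  }
  o <- order(voxels$distance_um)
  at_soma <- voxels$distance_um == 0
  if (any(at_soma) && any(voxels$attenuation[at_soma] != 1)) {
    stop("attenuation must equal 1 at distance 0")
  }
  if (is.unsorted(rev(voxels$attenuation[o]))) {
    stop("attenuation must be non-increasing with distance")
  }
  if (conduction_velocity <= 0 && any(voxels$distance_um > 0)) {
    stop("conduction_velocity must be positive (or Inf) when voxels lie ",
         "away from the soma")
  }
  structure(list(voxels = voxels, conduction_velocity = conduction_velocity),
            class = "cell_geometry")
}
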
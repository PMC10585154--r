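#' Convert a velocity-encoded phase image to velocity
#'
#' Linear mapping \eqn{v = venc \cdot \phi / \pi}. With the \code{"shift"}
#' unwrap policy, flow is assumed predominantly caudocranial (positive): any
#' pixel whose phase falls below \code{wrap_threshold} (default
#' \eqn{-\pi/2}, i.e. an apparent velocity below -venc/2) is taken to be a
#' single positive wrap and has \eqn{2\pi} added before scaling, so true
#' velocities up to 1.5 venc are restored. Double wraps are outside the
#' policy and raise an error via the resulting out-of-range magnitude.
#'
#' @param phase Matrix of phase values in (-pi, pi], radians.
#' @param venc Velocity encoding, cm/s.
#' @param unwrap \code{"none"} or \code{"shift"}.
#' @param pixel_size Pixel edge, mm (carried to the flow computation).
#' @param wrap_threshold Phase below which a pixel is treated as wrapped
#'   (only under \code{"shift"}).
#' @return Object of class \code{velocity_image}: list with \code{velocity}
#'   (cm/s), \code{pixel_size}, \code{venc}.
#' @export
phase_to_velocity <- function(phase, venc, unwrap = c("none", "shift"),
                              pixel_size = 0.75, wrap_threshold = -pi / 2) {
  unwrap <- match.arg(unwrap)
  if (venc <= 0) stop_bad("venc must be positive")
  if (any(phase > pi + 1e-9 | phase <= -pi - 1e-9)) {
    stop_bad("input phase must lie in (-pi, pi]")
  }
  if (unwrap == "shift") {
    phase <- phase + ifelse(phase < wrap_threshold, 2 * pi, 0)
    if (any(phase > 2 * pi)) {
      stop_bad("phase beyond a single wrap; double-wrap correction is not supported")
    }
  }
  structure(list(velocity = venc * phase / pi, pixel_size = pixel_size,
                 venc = venc),
            class = "velocity_image")
}

#' Wrap a velocity matrix as a velocity image
#'
#' @param velocity Matrix of velocities, cm/s.
#' @param pixel_size Pixel edge, mm.
#' @param venc Velocity encoding, cm/s.
#' @return A \code{velocity_image}.
#' @export
velocity_image <- function(velocity, pixel_size = 0.75, venc = 100) {
  if (venc <= 0) stop_bad("venc must be positive")
  structure(list(velocity = velocity, pixel_size = pixel_size, venc = venc),
            class = "velocity_image")
}

#' Blood flow through a vessel ROI
#'
#' Mean velocity over the ROI multiplied by the ROI cross-sectional area,
#' converted to ml/min; the sign of the mean velocity is preserved
#' (caudocranial positive). Numeric masks are binarized at 0.5, i.e. a pixel
#' belongs to the vessel when its mask value is at least one half.
#'
#' @param vel A \code{velocity_image}.
#' @param roi Logical or numeric mask with the image's dimensions.
#' @return Flow in ml/min.
#' @export
vessel_flow <- function(vel, roi) {
  stopifnot(inherits(vel, "velocity_image"))
  mask <- as_mask(roi)
  if (!any(mask)) stop_bad("empty vessel ROI")
  if (!all(dim(mask) == dim(vel$velocity))) {
    stop_bad("ROI dimensions do not match the image")
  }
  area_mm2 <- sum(mask) * vel$pixel_size^2
  mean(vel$velocity[mask]) * area_mm2 * 0.6  # cm/s x mm^2 -> ml/min
}

#' Normalize total arterial inflow to cerebral blood flow
#'
#' Sum of the per-vessel flows divided by the brain mass (volume times
#' density), expressed per 100 g.
#'
#' @param flows Numeric vector of vessel flows, ml/min.
#' @param brain_volume_ml Total brain volume, ml.
#' @param brain_density Tissue density, g/ml.
#' @return CBF in ml/100 g/min.
#' @export
total_cbf <- function(flows, brain_volume_ml, brain_density = 1.05) {
  if (!length(flows)) stop_bad("at least one vessel flow is required")
  if (brain_volume_ml <= 0) stop_bad("brain volume must be positive")
  if (brain_density <= 0) stop_bad("brain density must be positive")
  sum(flows) / (brain_volume_ml * brain_density) * 100
}
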
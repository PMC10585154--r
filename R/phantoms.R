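#' Velocity-encoded phase-contrast phantom with analytic ground truth
#'
#' Builds a single-slice phase image containing circular "vessels" with a
#' uniform or parabolic through-plane velocity profile. Pixel phase is
#' \eqn{\pi v / venc} wrapped into (-pi, pi], so velocities beyond the
#' encoding limit alias, allowing wrap-correction policies to be exercised.
#' The analytically integrated flow of each vessel (uniform: area x velocity;
#' parabolic: area x peak/2) is stored as ground truth together with a pixel
#' ROI mask per vessel.
#'
#' @param vessels List of vessel descriptions, each a list with fields
#'   \code{center} (x, y in pixel units), \code{radius_mm},
#'   \code{peak_velocity} (cm/s, signed) and \code{profile}
#'   (\code{"uniform"} or \code{"parabolic"}).
#' @param image_size Image side length in pixels.
#' @param pixel_size Pixel edge, mm.
#' @param venc Velocity encoding, cm/s (velocity mapped to a phase of pi).
#' @param noise_sd Phase noise, radians.
#' @param seed Optional seed.
#' @return List with \code{phase} (matrix, rad), \code{venc},
#'   \code{pixel_size}, \code{rois} (list of logical matrices) and
#'   \code{true_flow_ml_min} (named numeric, one entry per vessel).
#' @export
generate_pcm_phantom <- function(vessels, image_size = 64, pixel_size = 0.75,
                                 venc = 100, noise_sd = 0, seed = NULL) {
  if (venc <= 0) stop_bad("venc must be positive")
  if (!is.null(seed)) set.seed(seed)
  xs <- matrix(rep(seq_len(image_size), image_size), image_size)
  ys <- t(xs)
  velocity <- matrix(0, image_size, image_size)
  rois <- list()
  truth <- numeric(length(vessels))
  names(truth) <- vapply(seq_along(vessels), function(i) {
    v <- vessels[[i]]
    if (!is.null(v$name)) v$name else paste0("vessel", i)
  }, character(1))
  for (i in seq_along(vessels)) {
    v <- vessels[[i]]
    if (v$radius_mm <= 0) stop_bad("vessel radius must be positive")
    profile <- match.arg(v$profile, c("uniform", "parabolic"))
    r_px <- v$radius_mm / pixel_size
    d2 <- (xs - v$center[1])^2 + (ys - v$center[2])^2
    inside <- d2 <= r_px^2
    if (profile == "uniform") {
      velocity[inside] <- v$peak_velocity
      mean_v <- v$peak_velocity
    } else {
      velocity[inside] <- v$peak_velocity * (1 - d2[inside] / r_px^2)
      mean_v <- v$peak_velocity / 2
    }
    area_mm2 <- pi * v$radius_mm^2
    # cm/s x mm^2 -> ml/min: 1 cm/s = 600 mm/min, 1 mm^3 = 1e-3 ml
    truth[i] <- mean_v * area_mm2 * 0.6
    rois[[names(truth)[i]]] <- inside
  }
  phase <- wrap_phase(pi * velocity / venc +
                        stats::rnorm(length(velocity), 0, noise_sd))
  list(phase = phase, venc = venc, pixel_size = pixel_size, rois = rois,
       true_flow_ml_min = truth)
}

#' Dual-echo susceptibility-oximetry phantom
#'
#' Simulates the two gradient-echo phase images used for venous oximetry of
#' the sagittal sinus. Tissue accrues a common background phase per echo;
#' pixels inside the sinus disc additionally accrue the deoxyhemoglobin-driven
#' frequency offset given by the parallel infinite-cylinder susceptibility
#' model for the requested true venous saturation. Both images are wrapped
#' into (-pi, pi].
#'
#' @param svo2_true True venous oxygen saturation, fraction in [0, 1].
#' @param hct Hematocrit fraction.
#' @param theta_deg Vessel angle to the main field, degrees (|theta| < 54.7).
#' @param b0 Field strength, tesla.
#' @param te1,te2 Echo times, ms (te2 > te1).
#' @param noise_sd Phase noise per image, radians.
#' @param seed Optional seed.
#' @param image_size Image side, pixels.
#' @param tissue_freq Background tissue off-resonance, rad/s.
#' @return List with \code{phase_te1}, \code{phase_te2} (matrices),
#'   \code{sinus_roi}, \code{tissue_roi} (logical matrices), \code{acq}
#'   (\code{\link{sbo_acquisition}}), \code{blood}
#'   (\code{\link{blood_model}}) and \code{truth} with the generating
#'   \code{svo2} and inter-echo phase offset \code{dphi}.
#' @export
generate_sbo_phantom <- function(svo2_true, hct = 0.42, theta_deg = 0,
                                 b0 = 3, te1 = 8.07, te2 = 17.77,
                                 noise_sd = 0, seed = NULL, image_size = 64,
                                 tissue_freq = 2) {
  if (svo2_true < 0 || svo2_true > 1) {
    stop_bad("svo2_true must lie in [0, 1]")
  }
  acq <- sbo_acquisition(b0 = b0, te1 = te1, te2 = te2,
                         theta_deg = theta_deg)
  blood <- blood_model(hct = hct)
  if (!is.null(seed)) set.seed(seed)
  dphi_true <- phase_from_svo2(svo2_true, acq, blood)
  cx <- image_size / 2
  xs <- matrix(rep(seq_len(image_size), image_size), image_size)
  ys <- t(xs)
  d2 <- (xs - cx)^2 + (ys - cx)^2
  sinus <- d2 <= 5^2
  tissue <- d2 > 8^2 & d2 <= 14^2
  freq <- matrix(tissue_freq, image_size, image_size)
  freq[sinus] <- tissue_freq + dphi_true / ((te2 - te1) * 1e-3)
  mk <- function(te) {
    wrap_phase(freq * te * 1e-3 +
                 stats::rnorm(length(freq), 0, noise_sd))
  }
  list(phase_te1 = mk(te1), phase_te2 = mk(te2), sinus_roi = sinus,
       tissue_roi = tissue, acq = acq, blood = blood,
       truth = list(svo2 = svo2_true, dphi = dphi_true))
}

#' Forward-simulate a fitted spectroscopy observation
#'
#' Emulates the output of spectral fitting for a long-echo-time water and
#' lactate measurement: signal amplitudes are concentration times proton
#' count times \eqn{\exp(-TE/T_2)}, the water signal summed over the tissue
#' compartments of the voxel, plus optional amplitude noise. The inverse
#' quantification (\code{\link{lactate_concentration}}) recovers the true
#' concentration exactly in the noise-free limit.
#'
#' @param lactate_true True lactate concentration, mmol/l.
#' @param gm_frac,wm_frac,csf_frac Voxel tissue fractions (must sum to 1).
#' @param te Echo time, ms.
#' @param noise_sd Amplitude noise (a.u.).
#' @param seed Optional seed.
#' @param table Relaxation/water-content constants,
#'   \code{\link{relaxation_table}}.
#' @return Object of class \code{mrs_observation}: amplitudes, echo time,
#'   tissue fractions and the generating truth.
#' @export
generate_mrs_observation <- function(lactate_true, gm_frac, wm_frac,
                                     csf_frac, te = 288, noise_sd = 0,
                                     seed = NULL,
                                     table = relaxation_table()) {
  if (lactate_true < 0) stop_bad("lactate_true must be non-negative")
  fr <- c(gm_frac, wm_frac, csf_frac)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-6) {
    stop_bad("tissue fractions must be non-negative and sum to 1 (got %s)",
             paste(signif(fr, 4), collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  contents <- c(table$water_content_gm, table$water_content_wm,
                table$water_content_csf)
  t2w <- c(table$t2_water_gm, table$t2_water_wm, table$t2_water_csf)
  water_amp <- sum(fr * contents * table$pure_water_molarity * 2 *
                     exp(-te / t2w))
  lac_amp <- lactate_true * 3 * exp(-te / table$t2_lactate)
  if (noise_sd > 0) {
    water_amp <- max(water_amp + stats::rnorm(1, 0, noise_sd), 0)
    lac_amp <- max(lac_amp + stats::rnorm(1, 0, noise_sd), 0)
  }
  structure(list(lactate_amplitude = lac_amp, water_amplitude = water_amp,
                 te = te, gm_frac = gm_frac, wm_frac = wm_frac,
                 csf_frac = csf_frac, truth = lactate_true),
            class = "mrs_observation")
}

#' Synthetic segmentation label map with exact tissue volumes
#'
#' Builds a 3-D label volume (0 background, 1 gray matter, 2 white matter,
#' 3 CSF) whose per-label voxel counts equal the requested volumes divided by
#' the voxel volume, rounded to the nearest voxel, so volumetry round-trips
#' the inputs to within one voxel.
#'
#' @param gm_ml,wm_ml,csf_ml Tissue volumes, ml.
#' @param voxel_mm Isotropic voxel edge, mm.
#' @return Integer 3-D array with attribute \code{voxel_mm}.
#' @export
generate_label_map <- function(gm_ml, wm_ml, csf_ml, voxel_mm = 0.70) {
  vols <- c(gm_ml, wm_ml, csf_ml)
  if (any(vols < 0)) stop_bad("tissue volumes must be non-negative")
  if (voxel_mm <= 0) stop_bad("voxel_mm must be positive")
  vox_vol <- voxel_mm^3
  counts <- round(vols * 1000 / vox_vol)
  total <- sum(counts)
  side <- max(2L, ceiling((total + 1)^(1 / 3)))
  n <- side^3
  labels <- c(rep.int(1L, counts[1]), rep.int(2L, counts[2]),
              rep.int(3L, counts[3]), rep.int(0L, n - total))
  map <- array(labels, dim = c(side, side, side))
  attr(map, "voxel_mm") <- voxel_mm
  map
}
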
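#' Dual-echo acquisition parameters for susceptibility-based oximetry
#'
#' @param b0 Main field strength, tesla.
#' @param te1,te2 Echo times, ms; \code{te2 > te1}.
#' @param theta_deg Angle of the vessel to the main field, degrees; the
#'   parallel-cylinder model requires |theta| below the magic angle (54.7
#'   degrees), where the geometric factor changes sign.
#' @param gamma Proton gyromagnetic ratio, rad/s/T.
#' @return List of class \code{sbo_acquisition}.
#' @export
sbo_acquisition <- function(b0 = 3, te1 = 8.07, te2 = 17.77, theta_deg = 0,
                            gamma = 2.67513e8) {
  if (te2 <= te1) stop_bad("te2 (%g ms) must exceed te1 (%g ms)", te2, te1)
  if (abs(theta_deg) >= 54.7356) {
    stop_bad("|theta| must be below the magic angle (54.7 deg)")
  }
  if (b0 <= 0 || gamma <= 0) stop_bad("b0 and gamma must be positive")
  structure(list(b0 = b0, te1 = te1, te2 = te2, theta_deg = theta_deg,
                 gamma = gamma),
            class = "sbo_acquisition")
}

#' Blood susceptibility model constants
#'
#' Houses the susceptibility difference between fully deoxygenated and fully
#' oxygenated red cells (SI convention, per unit hematocrit) and the
#' hemoglobin-to-hematocrit conversion constants.
#'
#' @param hct Hematocrit fraction in (0, 1).
#' @param dchi_do_ppm Deoxy-oxy susceptibility difference, ppm (SI); default
#'   4 pi x 0.27.
#' @param hgb_mw_monomer Molar mass of the hemoglobin monomer, g/mol.
#' @param hct_per_gdl Hematocrit per g/dl of hemoglobin.
#' @return List of class \code{blood_model}.
#' @export
blood_model <- function(hct = 0.42, dchi_do_ppm = 4 * pi * 0.27,
                        hgb_mw_monomer = 16114, hct_per_gdl = 0.03) {
  if (hct <= 0 || hct >= 1) stop_bad("hct must lie in (0, 1)")
  if (dchi_do_ppm <= 0) stop_bad("dchi_do_ppm must be positive")
  structure(list(hct = hct, dchi_do_ppm = dchi_do_ppm,
                 hgb_mw_monomer = hgb_mw_monomer,
                 hct_per_gdl = hct_per_gdl),
            class = "blood_model")
}

sbo_scale <- function(acq, blood) {
  dte_s <- (acq$te2 - acq$te1) * 1e-3
  theta <- acq$theta_deg * pi / 180
  0.5 * acq$gamma * acq$b0 * dte_s * blood$dchi_do_ppm * 1e-6 * blood$hct *
    (cos(theta)^2 - 1 / 3)
}

#' Forward cylinder model: inter-echo phase offset from venous saturation
#'
#' Parallel infinite-cylinder susceptibility model:
#' \deqn{\Delta\phi = \tfrac{1}{2}\gamma B_0 \Delta TE\, \Delta\chi_{do}\,
#' Hct (1 - SvO_2)(\cos^2\theta - 1/3)}
#'
#' @param svo2 Venous oxygen saturation, fraction.
#' @param acq An \code{\link{sbo_acquisition}}.
#' @param blood A \code{\link{blood_model}}.
#' @return Phase offset in radians.
#' @export
phase_from_svo2 <- function(svo2, acq = sbo_acquisition(),
                            blood = blood_model()) {
  sbo_scale(acq, blood) * (1 - svo2)
}

#' Invert the cylinder model: venous saturation from a phase offset
#'
#' Inverse of \code{\link{phase_from_svo2}}. Results outside [0, 1] are
#' clipped, with a warning and a \code{clipped} attribute set.
#'
#' @param dphi Sinus-minus-tissue inter-echo phase offset, radians
#'   (non-negative under the sign convention).
#' @param acq An \code{\link{sbo_acquisition}}.
#' @param blood A \code{\link{blood_model}}.
#' @return Venous saturation fraction in [0, 1].
#' @export
svo2_from_phase <- function(dphi, acq = sbo_acquisition(),
                            blood = blood_model()) {
  svo2 <- 1 - dphi / sbo_scale(acq, blood)
  clipped <- svo2 < -1e-9 | svo2 > 1 + 1e-9  # beyond numerical round-off
  if (any(clipped)) warning("SvO2 outside [0, 1]; clipped", call. = FALSE)
  svo2 <- pmin(pmax(svo2, 0), 1)
  attr(svo2, "clipped") <- any(clipped)
  svo2
}

#' Sinus-minus-tissue inter-echo phase difference
#'
#' Mean per-pixel phase evolution between the two echoes inside the sinus ROI
#' minus the same quantity in the adjacent-tissue ROI. Per-pixel inter-echo
#' differences falling outside (-pi, pi] receive an automatic single
#' plus/minus 2 pi correction (the in-scanner practice of manually correcting
#' aliased ROI values); an error is raised if more than half of either ROI
#' would need a multi-wrap correction.
#'
#' @param phase_te1,phase_te2 Phase images at the two echoes, radians.
#' @param sinus_roi,tissue_roi Disjoint, non-empty logical masks.
#' @return Phase difference in radians.
#' @export
interecho_phase_difference <- function(phase_te1, phase_te2, sinus_roi,
                                       tissue_roi) {
  sinus_roi <- as_mask(sinus_roi)
  tissue_roi <- as_mask(tissue_roi)
  if (!any(sinus_roi) || !any(tissue_roi)) stop_bad("empty ROI")
  if (any(sinus_roi & tissue_roi)) {
    stop_bad("sinus and tissue ROIs must be disjoint")
  }
  evolution <- function(mask) {
    d <- (phase_te2 - phase_te1)[mask]
    k <- round(d / (2 * pi))
    if (mean(abs(d - 2 * pi * k) > pi + 1e-9) > 0 ||
        mean(abs(k) > 1) > 0.5) {
      stop_bad("more than half the ROI needs multi-wrap correction")
    }
    mean(d - 2 * pi * k)
  }
  evolution(sinus_roi) - evolution(tissue_roi)
}

#' Hematocrit from hemoglobin concentration
#'
#' Converts a hemoglobin concentration in Danish clinical units (mmol/l of
#' monomer) to g/dl via the monomer molar mass and then to hematocrit with a
#' fixed hematocrit-per-g/dl factor. Set \code{from_gdl = TRUE} when the
#' input is already in g/dl.
#'
#' @param hgb Hemoglobin concentration, mmol/l monomer (or g/dl).
#' @param blood A \code{\link{blood_model}} supplying the constants.
#' @param from_gdl Input already in g/dl?
#' @return Hematocrit fraction.
#' @export
hct_from_hgb <- function(hgb, blood = blood_model(), from_gdl = FALSE) {
  if (any(hgb <= 0)) stop_bad("hgb must be positive")
  gdl <- if (from_gdl) hgb else hgb * blood$hgb_mw_monomer / 1e4
  gdl * blood$hct_per_gdl
}

#' Cerebral metabolic rate of oxygen by the Fick principle
#'
#' \deqn{CMRO_2 = Hgb \cdot CBF \cdot (SaO_2 - SvO_2)} with hemoglobin in
#' mmol/l of monomer (equal to micromoles of O2-binding sites per ml of
#' blood, one O2 per monomer). With \code{hgb_units = "g_dl"} the g/dl value
#' is combined with the matching Huefner oxygen capacity
#' (\code{o2_capacity_ml_g}, ml O2 per g hemoglobin at STP) instead.
#'
#' @param hgb Hemoglobin concentration.
#' @param cbf Cerebral blood flow, ml/100 g/min.
#' @param sao2,svo2 Arterial and venous saturations, fractions;
#'   \code{sao2 >= svo2}.
#' @param hgb_units \code{"mmol_l"} (monomer) or \code{"g_dl"}.
#' @param o2_capacity_ml_g Oxygen capacity for the g/dl path.
#' @return CMRO2 in micromol/100 g/min.
#' @export
cmro2_fick <- function(hgb, cbf, sao2, svo2,
                       hgb_units = c("mmol_l", "g_dl"),
                       o2_capacity_ml_g = 1.39) {
  hgb_units <- match.arg(hgb_units)
  if (any(hgb <= 0) || any(cbf < 0)) {
    stop_bad("hgb must be positive and cbf non-negative")
  }
  if (any(sao2 < svo2)) {
    stop_bad("sao2 below svo2: physically inconsistent saturation pair")
  }
  umol_per_ml <- if (hgb_units == "mmol_l") {
    hgb  # mmol/l monomer == umol O2-binding sites per ml
  } else {
    hgb / 100 * o2_capacity_ml_g / 22.414 * 1e3  # g/dl -> umol O2 per ml
  }
  umol_per_ml * cbf * (sao2 - svo2)
}
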
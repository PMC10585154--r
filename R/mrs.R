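#' Relaxation and water-content constants for MRS quantification
#'
#' Literature-style constants used by the water-referenced lactate
#' quantification: water T2 per tissue compartment, lactate methyl T2, water
#' content per compartment, and the molar concentration of pure water. All
#' values are editable.
#'
#' @param t2_water_gm,t2_water_wm,t2_water_csf Water T2 per compartment, ms.
#' @param t2_lactate Lactate methyl T2, ms.
#' @param water_content_gm,water_content_wm,water_content_csf Relative water
#'   content per compartment, in (0, 1].
#' @param pure_water_molarity Pure water concentration, mmol/l.
#' @return List of class \code{relaxation_table}.
#' @export
relaxation_table <- function(t2_water_gm = 90, t2_water_wm = 70,
                             t2_water_csf = 500, t2_lactate = 240,
                             water_content_gm = 0.78,
                             water_content_wm = 0.65,
                             water_content_csf = 0.97,
                             pure_water_molarity = 55510) {
  vals <- c(t2_water_gm, t2_water_wm, t2_water_csf, t2_lactate,
            water_content_gm, water_content_wm, water_content_csf,
            pure_water_molarity)
  if (any(vals <= 0)) stop_bad("all relaxation-table entries must be positive")
  if (any(c(water_content_gm, water_content_wm, water_content_csf) > 1)) {
    stop_bad("water contents must lie in (0, 1]")
  }
  structure(list(t2_water_gm = t2_water_gm, t2_water_wm = t2_water_wm,
                 t2_water_csf = t2_water_csf, t2_lactate = t2_lactate,
                 water_content_gm = water_content_gm,
                 water_content_wm = water_content_wm,
                 water_content_csf = water_content_csf,
                 pure_water_molarity = pure_water_molarity),
            class = "relaxation_table")
}

#' Construct a fitted-spectrum observation
#'
#' @param lactate_amplitude,water_amplitude Fitted signal amplitudes, a.u.
#' @param te Echo time, ms.
#' @param gm_frac,wm_frac,csf_frac Voxel tissue fractions summing to 1.
#' @return Object of class \code{mrs_observation}.
#' @export
mrs_observation <- function(lactate_amplitude, water_amplitude, te,
                            gm_frac, wm_frac, csf_frac) {
  if (lactate_amplitude < 0 || water_amplitude < 0) {
    stop_bad("amplitudes must be non-negative")
  }
  fr <- c(gm_frac, wm_frac, csf_frac)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-6) {
    stop_bad("tissue fractions must be non-negative and sum to 1")
  }
  structure(list(lactate_amplitude = lactate_amplitude,
                 water_amplitude = water_amplitude, te = te,
                 gm_frac = gm_frac, wm_frac = wm_frac, csf_frac = csf_frac),
            class = "mrs_observation")
}

#' Water concentration of a mixed-tissue voxel
#'
#' Sum over compartments of tissue fraction times water content times the
#' pure-water molarity.
#'
#' @param gm_frac,wm_frac,csf_frac Voxel tissue fractions summing to 1.
#' @param table A \code{\link{relaxation_table}}.
#' @return Voxel water concentration, mmol/l.
#' @export
voxel_water_concentration <- function(gm_frac, wm_frac, csf_frac,
                                      table = relaxation_table()) {
  fr <- c(gm_frac, wm_frac, csf_frac)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-6) {
    stop_bad("tissue fractions must be non-negative and sum to 1")
  }
  contents <- c(table$water_content_gm, table$water_content_wm,
                table$water_content_csf)
  sum(fr * contents) * table$pure_water_molarity
}

#' Absolute lactate concentration by water referencing
#'
#' Both signals are decay-corrected back to TE = 0 before ratioing: the
#' lactate amplitude with \eqn{\exp(TE/T_{2,lac})}, the water amplitude with
#' the tissue-fraction-weighted water decay factor. The corrected ratio is
#' scaled by the proton-count ratio (2 water protons to 3 methyl protons)
#' and the voxel water concentration.
#'
#' @param obs An \code{\link{mrs_observation}}.
#' @param table A \code{\link{relaxation_table}}.
#' @return Lactate concentration, mmol/l ("wet", per liter of water-visible
#'   voxel tissue).
#' @export
lactate_concentration <- function(obs, table = relaxation_table()) {
  stopifnot(inherits(obs, "mrs_observation"))
  if (obs$water_amplitude <= 0) stop_bad("water amplitude must be positive")
  if (obs$lactate_amplitude < 0) stop_bad("negative lactate amplitude")
  fr <- c(obs$gm_frac, obs$wm_frac, obs$csf_frac)
  contents <- c(table$water_content_gm, table$water_content_wm,
                table$water_content_csf)
  t2w <- c(table$t2_water_gm, table$t2_water_wm, table$t2_water_csf)
  water_frac <- sum(fr * contents)
  decay_w <- sum(fr * contents * exp(-obs$te / t2w)) / water_frac
  water_te0 <- obs$water_amplitude / decay_w
  lac_te0 <- obs$lactate_amplitude * exp(obs$te / table$t2_lactate)
  (lac_te0 / water_te0) * (2 / 3) * water_frac * table$pure_water_molarity
}
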
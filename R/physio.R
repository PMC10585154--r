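#' Simulate a pulse-oximetry / capnography trace for a hypoxic challenge
#'
#' Produces second-by-second arterial saturation, end-tidal CO2 and heart-rate
#' traces: saturation fluctuates around its baseline before the hypoxic gas is
#' switched on, then declines exponentially toward a plateau; end-tidal CO2
#' falls modestly (hypoxic ventilatory drive) and heart rate rises slightly.
#'
#' @param baseline_sao2 Baseline arterial saturation, percent.
#' @param plateau_sao2 Saturation plateau reached under hypoxia, percent; must
#'   be below the baseline.
#' @param onset Time of hypoxic-gas onset, seconds.
#' @param duration Total trace duration, seconds; must exceed \code{onset}.
#' @param noise_sd Additive measurement noise, percentage points.
#' @param seed Optional integer seed.
#' @param tau Exponential time constant of the desaturation, seconds.
#' @param dt Sampling interval, seconds.
#' @param petco2_baseline,petco2_drop End-tidal CO2 baseline and asymptotic
#'   drop, mmHg.
#' @param hr_baseline,hr_rise Heart-rate baseline and asymptotic rise,
#'   beats/min.
#' @return Data frame with columns \code{time}, \code{sao2}, \code{petco2},
#'   \code{heart_rate}; attribute \code{hypoxia_onset}.
#' @export
generate_physio_trace <- function(baseline_sao2 = 98, plateau_sao2 = 78,
                                  onset = 60, duration = 900, noise_sd = 0.8,
                                  seed = NULL, tau = 120, dt = 1,
                                  petco2_baseline = 40, petco2_drop = 4,
                                  hr_baseline = 65, hr_rise = 8) {
  if (plateau_sao2 >= baseline_sao2) {
    stop_bad("plateau_sao2 (%g) must be below baseline_sao2 (%g)",
             plateau_sao2, baseline_sao2)
  }
  if (duration <= onset) stop_bad("duration must exceed onset")
  if (!is.null(seed)) set.seed(seed)
  time <- seq(0, duration, by = dt)
  ramp <- ifelse(time < onset, 0, 1 - exp(-(time - onset) / tau))
  sao2 <- baseline_sao2 - (baseline_sao2 - plateau_sao2) * ramp +
    stats::rnorm(length(time), 0, noise_sd)
  sao2 <- pmin(pmax(sao2, 50), 100)
  petco2 <- petco2_baseline - petco2_drop * ramp +
    stats::rnorm(length(time), 0, noise_sd / 2)
  heart_rate <- hr_baseline + hr_rise * ramp +
    stats::rnorm(length(time), 0, noise_sd)
  trace <- data.frame(time = time, sao2 = sao2, petco2 = petco2,
                      heart_rate = heart_rate)
  attr(trace, "hypoxia_onset") <- onset
  trace
}
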
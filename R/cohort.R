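#' Default configuration for the synthetic hypoxic-challenge cohort
#'
#' Encodes the study conditions the generator emulates: three groups (healthy
#' controls, type 1 diabetes without albuminuria, type 1 diabetes with
#' albuminuria) with the published demographic, volumetric and resting
#' physiology distributions, the per-group true response slopes of each
#' physiologic variable versus arterial saturation, and the structural link
#' between brain volumes and the individual lactate response ratio.
#'
#' Brain volumes are generated from a single linear model
#' \deqn{vol = \alpha + \beta_{age}(age - age_{ref}) + \beta_{sex}(male -
#' p_{ref}) + \lambda (r - r_{ref}) + \varepsilon}
#' where \eqn{r} is the subject's true lactate response ratio (mmol/l per
#' percentage point of desaturation) and \eqn{\lambda} the volume-response
#' link in ml per ratio unit. The intercepts anchor the healthy-group means;
#' the age coefficients and the link together reproduce the albuminuria-group
#' means through that group's higher age and blunted lactate response.
#'
#' @param group_sizes Named integer vector of subjects per group.
#' @param ... Replacement values for any top-level configuration field.
#' @return A list of class \code{cohort_config}.
#' @export
cohort_config <- function(group_sizes = c(healthy = 19L, T1D_no_alb = 22L,
                                          T1D_alb = 11L), ...) {
  groups <- c("healthy", "T1D_no_alb", "T1D_alb")
  per_group <- function(x) stats::setNames(x, groups)
  cfg <- list(
    group_sizes        = group_sizes,
    age_mean           = per_group(c(45.0, 47.3, 56.0)),
    age_sd             = per_group(c(14.0, 12.9, 10.8)),
    female_prop        = per_group(c(7 / 19, 13 / 22, 4 / 11)),
    hgb_mean           = per_group(c(8.9, 8.9, 8.6)),
    hgb_sd             = per_group(c(0.6, 0.7, 0.7)),
    cbf_mean           = per_group(c(42.0, 41.3, 39.3)),
    cbf_sd             = per_group(c(4.9, 8.6, 8.6)),
    cmro2_mean         = per_group(c(124.8, 130.9, 117.6)),
    cmro2_sd           = per_group(c(20.5, 32.8, 23.4)),
    lactate_mean       = per_group(c(0.53, 0.48, 0.42)),
    lactate_sd         = per_group(c(0.12, 0.10, 0.09)),
    bpf_mean           = per_group(c(0.78, 0.78, 0.75)),
    bpf_sd             = per_group(c(0.02, 0.03, 0.03)),
    sao2_normoxia_mean = 98, sao2_normoxia_sd = 1,
    sao2_hypoxia_mean  = 78, sao2_hypoxia_sd  = 4,
    # true response slopes, units of the variable per % SaO2 (negative slope
    # means the variable rises as saturation falls)
    response_slopes = list(
      lactate = per_group(c(-0.012, -0.010, -0.004)),
      cbf     = per_group(c(-0.75, -0.75, -0.55)),
      cmro2   = per_group(c(0, 0, 0))),
    response_slope_sd = c(lactate = 0.008, cbf = 0.25, cmro2 = 0.3),
    noise_sd          = c(lactate = 0.015, cbf = 1.5, cmro2 = 8),
    volume_model = list(
      tbv = list(intercept = 1139, age = -5.094, sex_male = 110,
                 lactate_link = 3812, sd = 42),
      gm  = list(intercept = 632, age = -3.264, sex_male = 30,
                 lactate_link = 1405, sd = 17),
      ref_age = 45, ref_male_prop = 12 / 19, ref_lactate_ratio = 0.012),
    mrs_gm_fraction_mean = 0.55,
    mrs_gm_fraction_sd   = 0.05
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop_bad("unknown cohort_config field '%s'", nm)
    cfg[[nm]] <- dots[[nm]]
  }
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (any(cfg$group_sizes < 1)) {
    stop_bad("group_sizes must all be >= 1 (got %s)",
             paste(cfg$group_sizes, collapse = ", "))
  }
  for (nm in grep("_sd$", names(cfg), value = TRUE)) {
    if (any(cfg[[nm]] < 0)) stop_bad("field '%s' must be non-negative", nm)
  }
  if (any(cfg$response_slope_sd < 0)) {
    stop_bad("field 'response_slope_sd' must be non-negative")
  }
  if (any(cfg$noise_sd < 0)) stop_bad("field 'noise_sd' must be non-negative")
  if (any(cfg$female_prop < 0 | cfg$female_prop > 1)) {
    stop_bad("field 'female_prop' must lie in [0, 1]")
  }
  invisible(cfg)
}

#' Configuration with all random variation switched off
#'
#' Convenience wrapper setting every standard deviation and noise term of a
#' cohort configuration to zero, so each generated value equals its configured
#' mean. Useful for degenerate-case testing of downstream stages.
#'
#' @param cfg A \code{cohort_config}.
#' @return The configuration with all sd fields zeroed.
#' @export
zero_noise_config <- function(cfg = cohort_config()) {
  for (nm in grep("_sd$", names(cfg), value = TRUE)) {
    cfg[[nm]] <- cfg[[nm]] * 0
  }
  cfg$response_slope_sd <- cfg$response_slope_sd * 0
  cfg$noise_sd <- cfg$noise_sd * 0
  cfg$volume_model$tbv$sd <- 0
  cfg$volume_model$gm$sd <- 0
  cfg
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws one row per subject: demographics, hemoglobin, brain volumes, voxel
#' gray-matter fraction, and paired normoxia/hypoxia values of arterial
#' saturation, CBF, CMRO2 and lactate. Hypoxia values are the normoxia values
#' plus the subject's true slope times the individual desaturation plus
#' measurement noise; brain volumes are linked to the subject's true lactate
#' response ratio through the configured volume-response slope.
#'
#' @param config A \code{cohort_config}.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A data frame with one row per subject, ground-truth slope columns
#'   prefixed \code{true_}.
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  validate_cohort_config(config)
  if (!is.null(seed)) set.seed(seed)
  groups <- names(config$group_sizes)
  vm <- config$volume_model
  out <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    n <- config$group_sizes[[g]]
    age <- stats::rnorm(n, config$age_mean[[g]], config$age_sd[[g]])
    male <- stats::rbinom(n, 1L, 1 - config$female_prop[[g]])
    hgb <- rnorm_trunc(n, config$hgb_mean[[g]], config$hgb_sd[[g]], 3, 15)
    sao2_n <- rnorm_trunc(n, config$sao2_normoxia_mean,
                          config$sao2_normoxia_sd, 90, 100)
    sao2_h <- rnorm_trunc(n, config$sao2_hypoxia_mean,
                          config$sao2_hypoxia_sd, 55, sao2_n - 5)

    slope <- lapply(c(lactate = "lactate", cbf = "cbf", cmro2 = "cmro2"),
                    function(v) {
      config$response_slopes[[v]][[g]] +
        stats::rnorm(n, 0, config$response_slope_sd[[v]])
    })
    ratio_true <- -slope$lactate  # Eq.-3 style ratio: rise per % desaturation

    lin <- function(m) {
      m$intercept + m$age * (age - vm$ref_age) +
        m$sex_male * (male - vm$ref_male_prop) +
        m$lactate_link * (ratio_true - vm$ref_lactate_ratio) +
        stats::rnorm(n, 0, m$sd)
    }
    tbv <- lin(vm$tbv)
    gm <- lin(vm$gm)
    gm <- pmin(gm, tbv - 50)  # keep white matter physically positive
    wm <- tbv - gm
    bpf <- rnorm_trunc(n, config$bpf_mean[[g]], config$bpf_sd[[g]], 0.5, 0.95)
    icv <- tbv / bpf

    base <- list(
      cbf = rnorm_trunc(n, config$cbf_mean[[g]], config$cbf_sd[[g]], 5, Inf),
      cmro2 = rnorm_trunc(n, config$cmro2_mean[[g]], config$cmro2_sd[[g]],
                          20, Inf),
      lactate = rnorm_trunc(n, config$lactate_mean[[g]],
                            config$lactate_sd[[g]], 0.01, Inf))
    hyp <- lapply(names(base), function(v) {
      pmax(base[[v]] + slope[[v]] * (sao2_h - sao2_n) +
             stats::rnorm(n, 0, config$noise_sd[[v]]), 0.01)
    })
    names(hyp) <- names(base)

    out[[gi]] <- data.frame(
      group = g, age = age, sex = ifelse(male == 1, "M", "F"),
      hgb = hgb, icv = icv, tbv = tbv, gm = gm, wm = wm, bpf = bpf,
      mrs_gm_fraction = rnorm_trunc(n, config$mrs_gm_fraction_mean,
                                    config$mrs_gm_fraction_sd, 0.2, 0.9),
      sao2_normoxia = sao2_n, sao2_hypoxia = sao2_h,
      cbf_normoxia = base$cbf, cbf_hypoxia = hyp$cbf,
      cmro2_normoxia = base$cmro2, cmro2_hypoxia = hyp$cmro2,
      lactate_normoxia = base$lactate, lactate_hypoxia = hyp$lactate,
      true_lactate_slope = slope$lactate, true_cbf_slope = slope$cbf,
      true_cmro2_slope = slope$cmro2, true_lactate_ratio = ratio_true,
      stringsAsFactors = FALSE)
  }
  cohort <- do.call(rbind, out)
  cohort$subject_id <- sprintf("S%03d", seq_len(nrow(cohort)))
  cohort$group <- factor(cohort$group, levels = groups)
  cohort$sex <- factor(cohort$sex, levels = c("F", "M"))
  rownames(cohort) <- NULL
  cohort[, c("subject_id", setdiff(names(cohort), "subject_id"))]
}

#' Reshape a cohort to one row per subject and condition
#'
#' Long format used by the mixed-effects response models: two rows per subject
#' (normoxia, hypoxia) carrying the measured saturation and the requested
#' response variable alongside the modeling covariates.
#'
#' @param cohort Data frame from \code{\link{generate_cohort}}.
#' @param response One of \code{"lactate"}, \code{"cbf"}, \code{"cmro2"}.
#' @return Long-format data frame with columns \code{subject_id}, \code{group},
#'   \code{condition}, \code{sao2}, \code{value}, \code{sex}, \code{age},
#'   \code{mrs_gm_fraction}.
#' @export
cohort_long <- function(cohort, response = c("lactate", "cbf", "cmro2")) {
  response <- match.arg(response)
  mk <- function(cond) {
    data.frame(subject_id = cohort$subject_id, group = cohort$group,
               condition = cond,
               sao2 = cohort[[paste0("sao2_", cond)]],
               value = cohort[[paste0(response, "_", cond)]],
               sex = cohort$sex, age = cohort$age,
               mrs_gm_fraction = cohort$mrs_gm_fraction,
               stringsAsFactors = FALSE)
  }
  long <- rbind(mk("normoxia"), mk("hypoxia"))
  long$condition <- factor(long$condition, levels = c("normoxia", "hypoxia"))
  long <- long[order(long$subject_id, long$condition), ]
  rownames(long) <- NULL
  attr(long, "response") <- response
  long
}
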
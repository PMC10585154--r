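# Shared fixtures for the synthetic-cohort tests.

# Null-hypothesis configuration: identical lactate slopes in all groups
# (CBF/CMRO2 slopes unchanged), used for type-I error simulations.
null_lactate_config <- function() {
  gp <- c("healthy", "T1D_no_alb", "T1D_alb")
  cohort_config(response_slopes = list(
    lactate = stats::setNames(rep(-0.012, 3), gp),
    cbf     = stats::setNames(c(-0.75, -0.75, -0.55), gp),
    cmro2   = stats::setNames(rep(0, 3), gp)))
}

# Small cohort for fast pipeline/model smoke tests.
small_config <- function() {
  cohort_config(group_sizes = c(healthy = 6L, T1D_no_alb = 6L, T1D_alb = 5L))
}

fit_lactate <- function(cohort, ...) {
  suppressWarnings(fit_mixed_response(cohort_long(cohort, "lactate"),
                                      include_gm_covariate = TRUE, ...))
}

interaction_est <- function(fit, term = "groupT1D_alb:sao2") {
  fit$interactions[fit$interactions$term == term, , drop = FALSE]
}
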
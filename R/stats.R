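#' Per-subject response ratio to desaturation
#'
#' Change in a physiologic variable between normoxia and hypoxia divided by
#' the drop in arterial saturation, in variable units per percentage point of
#' desaturation; positive when the variable rises as saturation falls.
#'
#' @param normoxia,hypoxia Measured values in the two conditions.
#' @param sao2_normoxia,sao2_hypoxia Arterial saturations, percent;
#'   normoxia must exceed hypoxia.
#' @return Ratio(s) in variable units per percent desaturation.
#' @export
response_ratio <- function(normoxia, hypoxia, sao2_normoxia, sao2_hypoxia) {
  desat <- sao2_normoxia - sao2_hypoxia
  if (any(desat <= 0)) {
    stop_bad("desaturation must be positive (normoxia SaO2 above hypoxia)")
  }
  (hypoxia - normoxia) / desat
}

#' Response ratios for every subject of a cohort
#'
#' @param cohort Data frame from \code{\link{generate_cohort}}.
#' @param response One of \code{"lactate"}, \code{"cbf"}, \code{"cmro2"}.
#' @return Data frame with \code{subject_id}, \code{group} and \code{ratio}.
#' @export
response_ratios <- function(cohort, response = c("lactate", "cbf", "cmro2")) {
  response <- match.arg(response)
  data.frame(subject_id = cohort$subject_id, group = cohort$group,
             ratio = response_ratio(cohort[[paste0(response, "_normoxia")]],
                                    cohort[[paste0(response, "_hypoxia")]],
                                    cohort$sao2_normoxia,
                                    cohort$sao2_hypoxia),
             stringsAsFactors = FALSE)
}

wald_table <- function(est, se, level = 0.95, df = Inf) {
  q <- stats::qt(1 - (1 - level) / 2, df)
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             ci_lower = unname(est - q * se), ci_upper = unname(est + q * se),
             p = unname(2 * stats::pt(-abs(est / se), df)),
             stringsAsFactors = FALSE)
}

# symmetric inverse square root, guarded against null eigenvalues
msqrt_inv <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), nrow(M)) %*%
    t(e$vectors)
}

# CR2 (bias-reduced) cluster-robust covariance of the fixed effects of a
# random-intercept lmer fit, clustering on subject. Valid when per-subject
# response-slope heterogeneity makes the model residual variance
# heteroscedastic across subjects.
cluster_robust_vcov <- function(fit, ids) {
  X <- lme4::getME(fit, "X")
  y <- lme4::getME(fit, "y")
  beta <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2u <- vc$vcov[vc$grp == "subject_id"][1]
  s2 <- stats::sigma(fit)^2
  p <- ncol(X)
  uid <- unique(ids)
  Xt <- vector("list", length(uid))
  rt <- vector("list", length(uid))
  bread <- matrix(0, p, p)
  for (gi in seq_along(uid)) {
    ix <- which(ids == uid[gi])
    Vi <- matrix(s2u, length(ix), length(ix))
    diag(Vi) <- s2u + s2
    Wh <- msqrt_inv(Vi)
    Xt[[gi]] <- Wh %*% X[ix, , drop = FALSE]
    rt[[gi]] <- Wh %*% (y[ix] - X[ix, , drop = FALSE] %*% beta)
    bread <- bread + crossprod(Xt[[gi]])
  }
  Minv <- solve(bread)
  meat <- matrix(0, p, p)
  for (gi in seq_along(uid)) {
    Hi <- Xt[[gi]] %*% Minv %*% t(Xt[[gi]])
    ri <- msqrt_inv(diag(nrow(Hi)) - Hi) %*% rt[[gi]]
    meat <- meat + t(Xt[[gi]]) %*% ri %*% t(ri) %*% Xt[[gi]]
  }
  V <- Minv %*% meat %*% Minv
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

#' Mixed-effects model of a physiologic response to desaturation
#'
#' Fits, by REML, the random-intercept model
#' \deqn{Y = \beta_1 group + \beta_2 SaO_2 + \beta_3 group \times SaO_2 +
#' \beta_4 Sex + \beta_5 Age + u}
#' with one random intercept per subject, treatment contrasts against the
#' healthy-control group, and saturation in percentage points (slopes are per
#' percent). The random intercept absorbs baseline differences so the fixed
#' part tests the response to the challenge, not baseline offsets. With a
#' single group in the data the group terms are dropped and only the common
#' slope is estimated.
#'
#' Inference is Wald-type. The default \code{"robust"} flavor uses a CR2
#' bias-reduced cluster-robust covariance (clustered on subject) with
#' t quantiles on clusters-minus-one degrees of freedom: individual response
#' slopes vary between subjects, which a random-intercept model cannot
#' represent, and the model-based standard errors are anticonservative under
#' that heterogeneity. \code{"model"} gives the plain model-based normal
#' Wald intervals.
#'
#' @param data Long-format data from \code{\link{cohort_long}} (columns
#'   \code{subject_id}, \code{group}, \code{sao2}, \code{value}, \code{sex},
#'   \code{age}, \code{mrs_gm_fraction}).
#' @param include_gm_covariate Add the MRS-voxel gray-matter fraction as a
#'   covariate (used for the lactate model).
#' @param covariates Character vector of additional fixed covariates.
#' @param level Confidence level for the Wald intervals.
#' @param inference \code{"robust"} (CR2 cluster-robust, t on clusters - 1
#'   degrees of freedom) or \code{"model"} (model-based, normal).
#' @return Object of class \code{mixed_fit_result}: coefficient table,
#'   interaction contrasts versus the healthy group, variance components,
#'   sizes, and a singular-fit flag.
#' @export
fit_mixed_response <- function(data, include_gm_covariate = FALSE,
                               covariates = c("sex", "age"), level = 0.95,
                               inference = c("robust", "model")) {
  inference <- match.arg(inference)
  if (include_gm_covariate) covariates <- c(covariates, "mrs_gm_fraction")
  data$group <- droplevels(factor(data$group))
  multi_group <- nlevels(data$group) >= 2
  rhs <- if (multi_group) "group * sao2" else "sao2"
  rhs <- paste(c(rhs, covariates), collapse = " + ")
  form <- stats::as.formula(paste("value ~", rhs, "+ (1 | subject_id)"))
  fit <- lme4::lmer(form, data = data, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                calc.derivs = FALSE))
  singular <- lme4::isSingular(fit)
  est <- lme4::fixef(fit)
  if (inference == "robust") {
    ids <- fit@frame$subject_id
    V <- cluster_robust_vcov(fit, ids)
    se <- sqrt(diag(V))[names(est)]
    df <- length(unique(ids)) - 1
  } else {
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    df <- Inf
  }
  coefs <- wald_table(est, se, level, df)
  interactions <- coefs[grepl(":sao2$|^sao2:", coefs$term) &
                          grepl("group", coefs$term), , drop = FALSE]
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(coefficients = coefs, interactions = interactions,
                 random_intercept_sd = vc$sdcor[vc$grp == "subject_id"][1],
                 residual_sd = stats::sigma(fit),
                 n_obs = nrow(data),
                 n_subjects = length(unique(data$subject_id)),
                 inference = inference, df = df,
                 singular = singular, model = fit),
            class = "mixed_fit_result")
}

#' @export
print.mixed_fit_result <- function(x, ...) {
  cat(sprintf("Mixed response model: %d observations, %d subjects%s\n",
              x$n_obs, x$n_subjects,
              if (x$singular) " (singular fit)" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Covariate-adjusted group differences in a cohort outcome
#'
#' Ordinary linear model with group as a categorical regressor (healthy
#' controls as reference) and sex and age as covariates; the patients-only
#' contrast (albuminuria versus no albuminuria) is obtained by releveling.
#'
#' @param cohort Data frame from \code{\link{generate_cohort}}.
#' @param outcome Column name of the outcome (e.g. \code{"tbv"},
#'   \code{"lactate_normoxia"}).
#' @param covariates Fixed covariates.
#' @param level Confidence level.
#' @return Data frame with one row per pairwise contrast: estimate, Wald CI
#'   and two-sided p-value.
#' @export
fit_group_differences <- function(cohort, outcome,
                                  covariates = c("sex", "age"),
                                  level = 0.95) {
  y <- cohort[[outcome]]
  if (is.null(y)) stop_bad("outcome '%s' not found", outcome)
  if (stats::var(y) == 0) {
    stop_bad("outcome '%s' is constant: degenerate model", outcome)
  }
  d <- cohort
  d$.y <- y
  form <- stats::as.formula(paste(".y ~ group +",
                                  paste(covariates, collapse = " + ")))
  pull <- function(ref, lab) {
    d$group <- stats::relevel(factor(d$group), ref = ref)
    fit <- stats::lm(form, data = d)
    sm <- summary(fit)$coefficients
    rows <- grep("^group", rownames(sm), value = TRUE)
    out <- wald_table(stats::setNames(sm[rows, 1], rows),
                      stats::setNames(sm[rows, 2], rows), level)
    out$contrast <- paste(sub("^group", "", out$term), "vs", ref)
    out
  }
  res <- pull("healthy", "healthy")
  pats <- pull("T1D_no_alb", "T1D_no_alb")
  res <- rbind(res, pats[grepl("^T1D_alb vs", pats$contrast), , drop = FALSE])
  rownames(res) <- NULL
  res[, c("contrast", "estimate", "se", "ci_lower", "ci_upper", "p")]
}

#' Regression of a brain volume on a desaturation response ratio
#'
#' Linear model of total brain volume or gray matter volume on the
#' per-subject response ratio, adjusted for sex, age and the MRS-voxel
#' gray-matter fraction, with an optional patients-only subset. The returned
#' partial-regression frame holds the covariate-residualized volume and ratio
#' (added-variable values) for plotting.
#'
#' @param cohort Data frame from \code{\link{generate_cohort}}.
#' @param volume \code{"tbv"} or \code{"gm"}.
#' @param response Response variable whose ratio is the regressor.
#' @param patients_only Drop the healthy-control group first.
#' @param covariates Fixed covariates.
#' @param level Confidence level.
#' @return List of class \code{volume_response_fit}: \code{slope} (ml per
#'   ratio unit), \code{se}, \code{ci_lower}, \code{ci_upper}, \code{p},
#'   \code{n}, and \code{partial} (data frame with \code{ratio_resid},
#'   \code{volume_resid}).
#' @export
fit_volume_response_assoc <- function(cohort, volume = c("tbv", "gm"),
                                      response = c("lactate", "cbf"),
                                      patients_only = FALSE,
                                      covariates = c("sex", "age",
                                                     "mrs_gm_fraction"),
                                      level = 0.95) {
  volume <- match.arg(volume)
  response <- match.arg(response)
  d <- cohort
  if (patients_only) d <- d[d$group != "healthy", , drop = FALSE]
  rr <- response_ratios(d, response)
  d$.ratio <- rr$ratio
  d$.vol <- d[[volume]]
  if (stats::var(d$.ratio) == 0) {
    stop_bad("response ratio has zero variance")
  }
  cov_rhs <- paste(covariates, collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste(".vol ~ .ratio +", cov_rhs)),
                   data = d)
  sm <- summary(fit)$coefficients
  tab <- wald_table(c(.ratio = sm[".ratio", 1]), c(.ratio = sm[".ratio", 2]),
                    level)
  partial <- data.frame(
    ratio_resid = stats::resid(stats::lm(
      stats::as.formula(paste(".ratio ~", cov_rhs)), data = d)),
    volume_resid = stats::resid(stats::lm(
      stats::as.formula(paste(".vol ~", cov_rhs)), data = d)))
  structure(list(slope = tab$estimate, se = tab$se,
                 ci_lower = tab$ci_lower, ci_upper = tab$ci_upper,
                 p = tab$p, n = nrow(d), volume = volume,
                 response = response, partial = partial, model = fit),
            class = "volume_response_fit")
}

#' Two-sample normal-approximation sample size
#'
#' \deqn{n = \lceil 2\sigma^2 (z_{1-\alpha/2} + z_{1-\beta})^2 / \delta^2
#' \rceil} per group, floored at 2.
#'
#' @param sd_pct Standard deviation of the response, percent.
#' @param alpha Two-sided significance level.
#' @param power Target power in (0, 1).
#' @param effect_pct Detectable difference, percent.
#' @return Required subjects per group.
#' @export
power_sample_size <- function(sd_pct, alpha = 0.05, power = 0.80,
                              effect_pct) {
  if (sd_pct <= 0 || alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop_bad("sd, alpha and power must be positive (alpha, power in (0,1))")
  }
  if (effect_pct <= 0) stop_bad("effect size must be positive")
  n_raw <- 2 * sd_pct^2 *
    (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 / effect_pct^2
  max(2L, as.integer(ceiling(n_raw - 1e-8)))
}

#' Minimal detectable difference implied by a sample size
#'
#' Inverse of \code{\link{power_sample_size}}: the effect, in percent, that a
#' given per-group size resolves at the stated level and power.
#'
#' @param n_per_group Subjects per group.
#' @param sd_pct Standard deviation of the response, percent.
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @return Detectable difference, percent.
#' @export
detectable_effect <- function(n_per_group, sd_pct, alpha = 0.05,
                              power = 0.80) {
  if (n_per_group <= 0) stop_bad("n_per_group must be positive")
  sqrt(2 * sd_pct^2 *
         (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 / n_per_group)
}
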
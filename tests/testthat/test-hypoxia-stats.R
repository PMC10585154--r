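test_that("response ratio arithmetic and its two-point regression identity", {
  expect_equal(response_ratio(0.53, 0.62, 98, 78), 0.0045)
  expect_equal(response_ratio(5, 5, 98, 78), 0)
  expect_equal(response_ratio(42, 50, 98, 78), 0.40)
  expect_error(response_ratio(1, 2, 78, 98), "desaturation")
  # Eq.-3 ratio equals minus the per-subject two-point regression slope
  co <- generate_cohort(seed = 21)
  rr <- response_ratios(co, "lactate")
  for (i in c(1, 20, 52)) {
    sl <- stats::coef(stats::lm(
      c(co$lactate_normoxia[i], co$lactate_hypoxia[i]) ~
        c(co$sao2_normoxia[i], co$sao2_hypoxia[i])))[2]
    expect_equal(rr$ratio[i], -unname(sl))
  }
})

test_that("deterministic single-group data yields the exact fixed slope", {
  subj <- sprintf("P%02d", 1:8)
  d <- data.frame(subject_id = rep(subj, each = 2), group = "healthy",
                  condition = rep(c("normoxia", "hypoxia"), 8),
                  sao2 = rep(c(98, 78), 8) + rep(seq(0, 3.5, 0.5), each = 2),
                  sex = "F", age = 50)
  intercepts <- rep(seq(5, 5.7, 0.1), each = 2)
  d$value <- intercepts - 0.01 * d$sao2
  fit <- suppressWarnings(fit_mixed_response(d, covariates = character(0)))
  expect_equal(fit$coefficients$estimate[fit$coefficients$term == "sao2"],
               -0.01, tolerance = 1e-8)
  expect_lt(fit$residual_sd, 1e-6)
})

test_that("mixed-model estimates ignore row order and baseline shifts", {
  co <- generate_cohort(seed = 31)
  d <- cohort_long(co, "lactate")
  f1 <- suppressWarnings(fit_mixed_response(d, include_gm_covariate = TRUE))
  shuffled <- d[sample.int(nrow(d)), ]
  f2 <- suppressWarnings(fit_mixed_response(shuffled,
                                            include_gm_covariate = TRUE))
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-8)
  # constant per-subject offsets are absorbed by the random intercept
  offs <- stats::setNames(stats::rnorm(52, 0, 0.5), unique(d$subject_id))
  d3 <- d
  d3$value <- d3$value + offs[d3$subject_id]
  f3 <- suppressWarnings(fit_mixed_response(d3, include_gm_covariate = TRUE))
  keep <- grepl("sao2", f1$coefficients$term)
  expect_equal(f1$coefficients$estimate[keep],
               f3$coefficients$estimate[keep], tolerance = 0.02)
})

test_that("unit rescaling rescales the matching coefficients", {
  co <- generate_cohort(seed = 41)
  d <- cohort_long(co, "lactate")
  f1 <- suppressWarnings(fit_mixed_response(d))
  d2 <- d
  d2$value <- d2$value * 1000  # mmol/l -> umol/l
  f2 <- suppressWarnings(fit_mixed_response(d2))
  expect_equal(f2$interactions$estimate, 1000 * f1$interactions$estimate,
               tolerance = 1e-6)
})

test_that("group-difference model: null contrast and covariate adjustment", {
  base <- data.frame(
    subject_id = sprintf("S%02d", 1:40),
    group = factor(rep(c("healthy", "T1D_no_alb"), each = 20)),
    sex = factor(rep(c("F", "M"), 20)), age = rep(seq(30, 68, 2), 2))
  set.seed(5)
  base$y <- rep(stats::rnorm(20, 100, 5), 2)  # the two groups are identical
  res <- fit_group_differences(base, "y")
  expect_equal(res$estimate[1], 0, tolerance = 1e-10)
  expect_gt(res$p[1], 0.999)
  # a pure age effect does not bias the group contrast when adjusted
  set.seed(6)
  est <- replicate(60, {
    b <- base
    b$age <- b$age + (b$group == "T1D_no_alb") * 10
    b$y <- 100 + 2 * b$age + stats::rnorm(40, 0, 3)
    fit_group_differences(b, "y")$estimate[1]
  })
  expect_lt(abs(mean(est)), 3 * stats::sd(est) / sqrt(60))
  expect_error(fit_group_differences(transform(base, y = 1), "y"),
               "constant")
})

test_that("volume-response regression finds a null when the link is absent", {
  vm <- cohort_config()$volume_model
  vm$tbv$lactate_link <- 0
  vm$gm$lactate_link <- 0
  cfg <- cohort_config(volume_model = vm)
  set.seed(8)
  sl <- replicate(80, fit_volume_response_assoc(generate_cohort(cfg),
                                                "tbv", "lactate")$slope)
  expect_lt(abs(mean(sl)), 3 * stats::sd(sl) / sqrt(80))
  # patients-only subset drops the healthy group
  co <- generate_cohort(seed = 9)
  f <- fit_volume_response_assoc(co, "tbv", "lactate", patients_only = TRUE)
  expect_equal(f$n, 33)
  expect_equal(nrow(f$partial), 33)
  # a constant ratio regressor is degenerate
  co$sao2_hypoxia <- co$sao2_normoxia - 20
  co$lactate_normoxia <- 0.5
  co$lactate_hypoxia <- 0.5 + 0.01 * 20
  expect_error(fit_volume_response_assoc(co, "tbv", "lactate"),
               "zero variance")
})

test_that("normal-approximation power formula and its limits", {
  delta <- detectable_effect(10, 10.8, 0.05, 0.80)
  expect_equal(delta, 13.53, tolerance = 1e-3)
  expect_equal(power_sample_size(10.8, 0.05, 0.80, delta), 10)
  expect_equal(power_sample_size(10.8, 0.05, 0.80, 1e6), 2)
  expect_equal(power_sample_size(5, 0.05, 0.80, 5), 16)
  expect_equal(power_sample_size(10, 0.05, 0.80, 5), 63)  # 4x before ceiling
  expect_error(power_sample_size(10.8, 0.05, 0.80, 0), "effect")
  expect_error(power_sample_size(-1, 0.05, 0.80, 10), "positive")
})
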
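test_that("default cohort has the study's group sizes and obeys invariants", {
  co <- generate_cohort(seed = 11)
  expect_equal(nrow(co), 52L)
  expect_equal(as.vector(table(co$group)), c(19L, 22L, 11L))
  expect_equal(anyDuplicated(co$subject_id), 0L)
  expect_equal(co$tbv, co$gm + co$wm)
  expect_true(all(co$tbv <= co$icv))
  expect_true(all(co$sao2_normoxia > 50 & co$sao2_normoxia <= 100))
  expect_true(all(co$sao2_hypoxia < co$sao2_normoxia))
  phys <- c("cbf_normoxia", "cbf_hypoxia", "cmro2_normoxia", "cmro2_hypoxia",
            "lactate_normoxia", "lactate_hypoxia", "hgb")
  for (v in phys) expect_true(all(co[[v]] > 0), label = v)
  expect_true(all(co$mrs_gm_fraction > 0 & co$mrs_gm_fraction < 1))
})

test_that("same seed reproduces the cohort bit for bit", {
  expect_identical(generate_cohort(seed = 3), generate_cohort(seed = 3))
  a <- generate_cohort(seed = 3)
  b <- generate_cohort(seed = 4)
  expect_false(identical(a$tbv, b$tbv))
})

test_that("zero-noise configuration collapses each value onto its mean", {
  co <- generate_cohort(zero_noise_config(), seed = 1)
  h <- co[co$group == "healthy", ]
  expect_equal(h$cbf_normoxia, rep(42.0, nrow(h)))
  expect_equal(h$lactate_normoxia, rep(0.53, nrow(h)))
  expect_equal(h$sao2_normoxia, rep(98, nrow(h)))
  # hypoxia value is then exactly baseline + group slope x desaturation
  expect_equal(h$lactate_hypoxia,
               h$lactate_normoxia + 0.012 * (h$sao2_normoxia - h$sao2_hypoxia))
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(cohort_config(group_sizes = c(healthy = 0L, T1D_no_alb = 2L,
                                             T1D_alb = 2L)),
               "group_sizes")
  expect_error(cohort_config(hgb_sd = c(healthy = -1, T1D_no_alb = 0.7,
                                        T1D_alb = 0.7)),
               "hgb_sd")
  expect_error(cohort_config(female_prop = c(healthy = 1.5, T1D_no_alb = 0.5,
                                             T1D_alb = 0.5)),
               "female_prop")
  expect_error(cohort_config(nonsense = 1), "unknown")
})

test_that("noise-free desaturation trace reaches its plateau and is seeded", {
  tr <- generate_physio_trace(baseline_sao2 = 98, plateau_sao2 = 78,
                              noise_sd = 0)
  expect_equal(min(tr$sao2), 78, tolerance = 0.05 / 78)
  expect_equal(tr$sao2[tr$time < attr(tr, "hypoxia_onset")][1], 98)
  # end-tidal CO2 declines, heart rate rises after onset
  pre <- tr$time < attr(tr, "hypoxia_onset")
  expect_lt(mean(tr$petco2[!pre][-(1:120)]), mean(tr$petco2[pre]))
  expect_gt(mean(tr$heart_rate[!pre][-(1:120)]), mean(tr$heart_rate[pre]))
  expect_identical(generate_physio_trace(seed = 9),
                   generate_physio_trace(seed = 9))
  expect_error(generate_physio_trace(baseline_sao2 = 90, plateau_sao2 = 95),
               "below")
  expect_error(generate_physio_trace(onset = 500, duration = 400), "onset")
})

test_that("phase-contrast phantom stores the analytic vessel flow", {
  r <- sqrt(56.25 / pi)  # 56.25 mm^2 cross-section
  ph <- generate_pcm_phantom(list(list(center = c(32, 32), radius_mm = r,
                                       peak_velocity = 20,
                                       profile = "uniform")))
  expect_equal(unname(ph$true_flow_ml_min), 675)
  zero <- generate_pcm_phantom(list(list(center = c(32, 32), radius_mm = 3,
                                         peak_velocity = 0,
                                         profile = "uniform")))
  expect_true(all(zero$phase == 0))
  expect_equal(unname(zero$true_flow_ml_min), 0)
  # above-venc parabolic vessel: wrapped center phase, mean-velocity truth
  par <- generate_pcm_phantom(list(list(center = c(32, 32), radius_mm = 3,
                                        peak_velocity = 120,
                                        profile = "parabolic")),
                              venc = 100)
  expect_equal(unname(par$true_flow_ml_min), pi * 9 * 60 * 0.6)
  expect_equal(par$phase[32, 32], -0.8 * pi)
  expect_error(generate_pcm_phantom(list(list(center = c(2, 2),
                                              radius_mm = 1,
                                              peak_velocity = 1,
                                              profile = "uniform")),
                                    venc = 0),
               "venc")
})

test_that("oximetry phantom follows the forward cylinder model", {
  # fully oxygenated blood: no sinus-tissue offset
  full <- generate_sbo_phantom(svo2_true = 1)
  expect_equal(full$truth$dphi, 0)
  expect_equal(interecho_phase_difference(full$phase_te1, full$phase_te2,
                                          full$sinus_roi, full$tissue_roi),
               0, tolerance = 1e-12)
  # reference numeric case for the forward model
  ph <- generate_sbo_phantom(svo2_true = 0.64, hct = 0.42, theta_deg = 0,
                             b0 = 3, te1 = 8, te2 = 17.7)
  expect_equal(ph$truth$dphi, 1.331196, tolerance = 1e-5)
  # phase offset is linear in the inter-echo time
  ph2 <- generate_sbo_phantom(svo2_true = 0.64, hct = 0.42, te1 = 8,
                              te2 = 27.4)
  expect_equal(ph2$truth$dphi / ph$truth$dphi, 2)
  expect_error(generate_sbo_phantom(0.6, te1 = 10, te2 = 9), "exceed")
  expect_error(generate_sbo_phantom(1.2), "svo2")
})

test_that("spectroscopy observation forward model is exact and seeded", {
  zero <- generate_mrs_observation(0, 0.6, 0.3, 0.1)
  expect_equal(zero$lactate_amplitude, 0)
  expect_gt(zero$water_amplitude, 0)
  expect_identical(generate_mrs_observation(0.5, 0.6, 0.3, 0.1,
                                            noise_sd = 0.1, seed = 2),
                   generate_mrs_observation(0.5, 0.6, 0.3, 0.1,
                                            noise_sd = 0.1, seed = 2))
  expect_error(generate_mrs_observation(0.5, 0.6, 0.3, 0.3), "sum to 1")
})

test_that("label map voxel counts match requested volumes", {
  one_ml <- generate_label_map(1, 0, 0, voxel_mm = 0.70)
  expect_equal(sum(one_ml == 1L), 2915L)
  expect_error(generate_label_map(-1, 0, 0), "non-negative")
  empty <- generate_label_map(0, 0, 0)
  expect_error(volumes_from_labels(empty), "empty")
})
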
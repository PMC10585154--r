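test_that("cylinder-model inversion matches the reference numeric case", {
  acq <- sbo_acquisition(b0 = 3, te1 = 8, te2 = 17.7, theta_deg = 0)
  blood <- blood_model(hct = 0.42, dchi_do_ppm = 3.39)
  expect_equal(as.numeric(svo2_from_phase(0, acq, blood)), 1)
  expect_equal(as.numeric(svo2_from_phase(1.33005, acq, blood)), 0.64,
               tolerance = 1e-4)
  expect_warning(clipped <- svo2_from_phase(100, acq, blood), "clipped")
  expect_equal(as.numeric(clipped), 0)
  expect_true(attr(clipped, "clipped"))
})

test_that("forward and inverse oximetry round-trip to 1e-10", {
  acq <- sbo_acquisition()
  blood <- blood_model(hct = 0.38)
  for (s in c(0.3, 0.5, 0.64, 0.8, 0.95)) {
    expect_equal(as.numeric(svo2_from_phase(phase_from_svo2(s, acq, blood),
                                            acq, blood)),
                 s, tolerance = 1e-10)
  }
  # strictly decreasing in the phase offset
  dphis <- seq(0, 1.5, by = 0.25)
  s <- vapply(dphis, function(d) as.numeric(svo2_from_phase(d, acq, blood)),
              numeric(1))
  expect_true(all(diff(s) < 0))
})

test_that("inter-echo ROI difference handles wrapping and bad ROIs", {
  base <- matrix(0.1, 16, 16)
  sinus <- matrix(FALSE, 16, 16); sinus[7:9, 7:9] <- TRUE
  tissue <- matrix(FALSE, 16, 16); tissue[1:3, 1:3] <- TRUE
  mk2 <- function(d_sinus, wrapped = TRUE) {
    p2 <- base + 0.4          # common tissue evolution
    p2[sinus] <- base[sinus] + d_sinus
    if (wrapped) wrap_phase(p2) else p2
  }
  expect_equal(interecho_phase_difference(base, mk2(0.4), sinus, tissue), 0)
  expect_equal(interecho_phase_difference(base, mk2(0.4 + 1.33), sinus,
                                          tissue), 1.33)
  # a full extra turn is removed by the single-wrap correction
  expect_equal(interecho_phase_difference(base, mk2(0.4 + 1.33 + 2 * pi),
                                          sinus, tissue), 1.33)
  expect_error(
    interecho_phase_difference(base, mk2(0.4 + 1.33 + 4 * pi, wrapped = FALSE),
                               sinus, tissue),
    "multi-wrap")
  expect_error(interecho_phase_difference(base, mk2(1), sinus, sinus),
               "disjoint")
  expect_error(interecho_phase_difference(base, mk2(1),
                                          matrix(FALSE, 16, 16), tissue),
               "empty")
})

test_that("noise-free phantom offset is recovered exactly and inverts", {
  ph <- generate_sbo_phantom(svo2_true = 0.64, hct = 0.42, te1 = 8,
                             te2 = 17.7)
  dphi <- interecho_phase_difference(ph$phase_te1, ph$phase_te2,
                                     ph$sinus_roi, ph$tissue_roi)
  expect_equal(dphi, ph$truth$dphi, tolerance = 1e-10)
  expect_equal(as.numeric(svo2_from_phase(dphi, ph$acq, ph$blood)), 0.64,
               tolerance = 1e-10)
})

test_that("hemoglobin-to-hematocrit conversion chain", {
  expect_equal(hct_from_hgb(8.9), 0.430, tolerance = 1e-3)
  expect_equal(hct_from_hgb(8.6), 0.416, tolerance = 1e-3)
  expect_equal(hct_from_hgb(14.34, from_gdl = TRUE), 0.4302)
  expect_equal(hct_from_hgb(1e-9), 0, tolerance = 1e-10)
  expect_error(hct_from_hgb(0), "positive")
})

test_that("Fick CMRO2 arithmetic, monotonicity and unit safety", {
  expect_equal(cmro2_fick(8.9, 42.0, 0.98, 0.98 - 0.334), 124.8,
               tolerance = 1e-3)
  expect_equal(cmro2_fick(8.6, 39.3, 0.97, 0.97 - 0.348), 117.6,
               tolerance = 1e-3)
  expect_equal(cmro2_fick(8.9, 42.0, 0.8, 0.8), 0)
  expect_error(cmro2_fick(8.9, 42.0, 0.6, 0.7), "inconsistent")
  # strictly increasing in each argument
  base <- cmro2_fick(8.9, 42.0, 0.98, 0.65)
  expect_gt(cmro2_fick(9.5, 42.0, 0.98, 0.65), base)
  expect_gt(cmro2_fick(8.9, 45.0, 0.98, 0.65), base)
  expect_gt(cmro2_fick(8.9, 42.0, 0.99, 0.65), base)
  # g/dl route with the matching Huefner capacity agrees within 0.5%
  gdl <- 8.9 * blood_model()$hgb_mw_monomer / 1e4
  expect_equal(cmro2_fick(gdl, 42.0, 0.98, 0.65, hgb_units = "g_dl"),
               base, tolerance = 0.005)
})
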
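Package: cerebroquant
Title: Quantitative MRI of Cerebral Blood Flow, Oxygen Metabolism and Lactate
    Under Hypoxic Challenge
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measurement chain and statistical analysis for a hypoxic-challenge
    quantitative MRI study design: vessel blood flow and global cerebral blood
    flow from velocity-encoded phase-contrast images, venous oxygen saturation
    from susceptibility-based oximetry of the sagittal sinus with Fick-principle
    cerebral metabolic rate of oxygen, absolute lactate concentration from
    water-referenced long-echo-time spectroscopy with partial-volume and T2
    corrections, and brain volumetry from segmentation label maps. Includes
    linear mixed-effects analysis of desaturation responses with group
    interactions, per-subject response ratios, covariate-adjusted group
    differences and volume-response regressions, and a synthetic cohort and
    image-phantom generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    tools,
    jsonlite,
    RNifti
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
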
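Package: cvftools
Title: Cortical Venous Filling Assessment from Dynamic CT Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the timing and extent of cortical venous filling (CVF)
    from per-vessel time-attenuation curves obtained with dynamic CT
    angiography in patients with severe unilateral middle cerebral artery
    stenosis or occlusion. Implements venous-phase time-point detection
    (first appearance, peak opacification, clearance), affected-minus-
    contralateral relative scores with a median-split velocity
    classification, per-vein presence scoring with ipsilateral absence
    counts, antegrade-flow and collateral-status decision rules, a
    cohort-level statistical layer (Woolf odds ratios with Haldane-Anscombe
    correction, 2x2 association tests, Mann-Whitney and t comparisons,
    logistic models), and a seeded synthetic-cohort generator with
    ground-truth recovery reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
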
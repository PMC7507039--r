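Package: vesselperm
Title: DCE-MRI Permeability Mapping and Vessel-Wall Morphometry for
    Intracranial Artery Stenosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis pipeline for blood-brain-barrier
    permeability and vessel-wall morphometry in middle cerebral artery
    stenosis. Implements variable-flip-angle (VFA) T1 mapping from spoiled
    gradient-echo (SPGR) signals, conversion of dynamic contrast-enhanced
    (DCE) signal to gadolinium concentration, arterial input function
    extraction from a sagittal-sinus mask or a population model, linear and
    nonlinear fitting of the extended Tofts model (Ktrans, Ve, Vp), vessel
    cross-section morphometry with stenosis grading and lesion-extent
    classification, and the cohort statistics used to compare aetiology
    groups (summary and raw two-sample t tests, Levene, Wilcoxon rank-sum,
    chi-square, Fisher exact, Spearman). A fully seeded synthetic-data
    module generates phantom image series with known kinetic ground truth,
    annular vessel cross-sections with known areas, and a patient cohort
    table, so every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    minpack.lm,
    pracma,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
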
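Package: adbpiv
Title: Instrumental-Variable Triangulation of Pre-Clinical Alzheimer's
    Liability and Blood Pressure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for one-sample instrumental-variable analyses of the
    effect of pre-clinical Alzheimer's disease liability on blood
    pressure, triangulating two instruments with different bias
    structures: an age-weighted parental dementia instrument score
    (PDIS) and a weighted allele score built from Alzheimer's GWAS
    variants (PGIS).  Includes derivation of medication-corrected
    systolic and diastolic blood pressure and a composite hypertension
    indicator, eligibility filtering with complete-case samples, a
    configurable crude-to-fully-adjusted model ladder, sensitivity
    analyses (leave-one-variant-out, extended confounder adjustment,
    complete-case comparison), and a synthetic two-generation cohort
    generator with switchable confounding, survivor-bias and
    horizontal-pleiotropy mechanisms for validating every stage against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR
Config/testthat/edition: 3
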
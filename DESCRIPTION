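Package: thyrodose
Title: Quantitative Small-Animal PET/CT Thyroid Dosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Combined PET/CT quantification and internal dosimetry of
    radioiodine (124-I) in the rodent thyroid. Provides a digital
    thyroid phantom simulator (contrast/activity-filled sphere pairs
    around an air tube), CT-based thyroid volume measurement,
    spillover- and background-compensated PET activity quantification
    using enclosing/background/anatomical regions of interest,
    two-phase time-activity-curve fitting with closed-form cumulated
    activity, and MIRD-style absorbed-dose calculation from tabulated
    thyroid self-dose S-values, together with an end-to-end pipeline
    for phantom validation and cohort dosimetry.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    minpack.lm,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
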
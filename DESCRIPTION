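Package: dfcvar
Title: Temporal Variability of Dynamic Functional Connectivity in Longitudinal fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sliding-window dynamic functional connectivity analysis for
    longitudinal two-group resting-state fMRI studies. Computes voxel-wise and
    region-wise maps of the functional connectivity temporal variability
    statistic (the mean squared successive difference of windowed Pearson
    correlations), provides minimal temporal preprocessing (band-pass
    filtering, nuisance regression, motion quality control), group-by-time
    interaction inference with Gaussian random field cluster-extent
    correction, symptom remission ratios and brain-behaviour correlation,
    and leave-one-out support vector regression prediction of treatment
    response. Includes a synthetic longitudinal cohort generator with
    covariance-state-switching BOLD dynamics and linked clinical scores so
    the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
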
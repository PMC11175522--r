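Package: aspectscta
Title: Threshold-Based ASPECTS Scoring from CT Angiography Source Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated detection of early irreversible ischemic change on CT
    angiography (CTA) source images in large vessel occlusion stroke. Measures
    the relative Hounsfield unit (rHU) attenuation of the ten ASPECTS regions
    against their contralateral mirrors using an atlas of binary region masks,
    labels regions as infarcted from a follow-up DWI lesion mask by a 30
    percent voxel-overlap rule, learns per-region Youden-optimal rHU cut
    points, and scores a threshold-based ASPECTS. Includes k-fold
    cross-validation, Mann-Whitney AUC, DeLong paired AUC comparison,
    bootstrap Spearman confidence intervals, a percentile-bootstrap test for
    dependent correlations, and a synthetic phantom generator (paired CTA/DWI
    volumes and tabular rHU cohorts with known ground truth) so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    readxl,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
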
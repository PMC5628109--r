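Package: cacscore
Title: Automatic Coronary Artery Calcium Scoring from CT Attenuation-Correction Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic coronary artery calcium (CAC) scoring in non-gated,
    low-dose CT attenuation-correction (CTAC) volumes acquired during hybrid
    PET/CT. Candidate calcifications are extracted by 130 HU thresholding and
    3D connected-component labeling, described by volume, shape, intensity and
    coronary-tree location features, and separated from aortic calcium, bone
    and noise by an ensemble of extremely randomized trees under patient-level
    cross-validation. Detected lesions are quantified with Agatston and volume
    scores and mapped to the five cardiovascular risk categories. The package
    also provides the agreement statistics used to evaluate such pipelines
    (linearly weighted Cohen's kappa, accuracy with Wilson intervals, two-way
    absolute-agreement ICC, Wilcoxon signed-rank, z-comparison of kappas,
    per-scan detection metrics), a rank-based risk-category assignment for
    comparing scan types, and a synthetic thorax phantom generator producing
    paired gated/non-gated scans with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    ranger,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
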
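Package: atelect
Title: Quantifying Atelectasis Change and Its Dosimetric Impact on Thoracic CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying re-aeration of collapsed lung (atelectasis)
    between a baseline and a midtreatment thoracic CT scan, and for assessing
    how that anatomical change perturbs a radiotherapy plan. Implements
    two-point air/blood density calibration of CT intensities, exterior-only
    morphological erosion of lung lobe masks, per-lobe relative mass, density
    and volume change measurement, rule-based classification of atelectasis
    resolution (full, partial, none), rigid bone- and carina-based plan
    transfer, a deliberately simple radiological-depth dose engine for
    relative dose comparisons, dose-volume-histogram constraint evaluation
    under several lung definitions, and cohort-level rank-sum and
    variance-ratio statistics. A synthetic thorax phantom generator with
    analytic ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
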
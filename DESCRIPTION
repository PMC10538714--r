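Package: myoflow
Title: Resting Myocardial Blood Flow from Dynamic PET and Dual-Bolus DCE-MRI
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification of resting myocardial blood flow (MBF) from
    dynamic ammonia-13 PET time-activity curves via a one-tissue-compartment
    model with Renkin-Crone conversion, and from dual-bolus dynamic
    contrast-enhanced MRI via Tofts-model deconvolution with an
    extraction-fraction conversion. Includes list-mode frame binning, a
    16-segment canine heart model with coronary-territory aggregation,
    dual-bolus quality-control detectors, a late-gadolinium-enhancement
    threshold, linear-quadratic dose equivalence, rate-pressure product, a
    longitudinal nonparametric statistics battery, and a synthetic-data
    generator emulating a five-animal six-timepoint study design so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'convolution.R'
    'curves.R'
    'pet-kinetics.R'
    'dce-tofts.R'
    'lge.R'
    'radbio.R'
    'synth-cohort.R'
    'stats-longitudinal.R'
    'qc.R'
    'synth-aif.R'
    'synth-acquisitions.R'
    'pipeline.R'
    'segments.R'
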
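Package: devsource
Title: Source-Resolved Auditory Deviance Response Analysis for Oddball EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for source-resolved analysis of the
    auditory deviance response (the MMN-P3a-RON complex) in duration-deviant
    oddball EEG. Provides EDF+ input/output with sidecar event tables,
    band-pass filtering and two-stage windowed artifact rejection (amplitude
    threshold plus a data-improbability test), extended-Infomax independent
    component analysis with an early-iteration sample-rejection schedule and a
    mutual-information-reduction diagnostic, single equivalent-dipole fitting
    in a three-shell spherical head model with dipolarity screening,
    across-subject IC clustering in a weighted multi-measure feature space,
    cluster back-projection with percent-variance-accounted-for accounting,
    automated MMN/P3a/RON peak scoring, and a Spearman correlation audit with
    Bonferroni critical-r-squared inversion and chance-expectation counts.
    A forward-model synthetic oddball-EEG cohort generator with planted
    dipolar sources, artifact processes, group effects, and clinical-score
    couplings makes every stage verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
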
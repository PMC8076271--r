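Package: amylir
Title: Infrared Adjudication of Amyloid Hexapeptide Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for auditing amyloid/non-amyloid annotations of hexapeptides
    against Amide I infrared spectroscopy. Implements second-derivative
    (Savitzky-Golay) preprocessing of ATR-FTIR and IR-microscopy spectra with
    rubberband baseline correction, band picking with aromatic-residue
    exclusion, position-based fibril/oligomer/non-amyloid decision rules, PCA
    chemometrics on derivative spectra, confidence-based outlier selection over
    a reduced amino-acid alphabet with an n-gram tree-ensemble predictor, and a
    concordance audit (accuracy, sensitivity, specificity, per-peptide
    consensus, misannotation counts) of sequence-based amyloid predictors
    against spectroscopic ground truth. Ships machine-readable band annotations
    and predictor calls for a 34-hexapeptide reference/test panel, plus a
    synthetic-data module generating class-conditional Amide I spectra and
    label-noise peptide datasets with planted ground truth for end-to-end
    weak-supervision filtering experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    pracma,
    ranger,
    seqinr,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
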
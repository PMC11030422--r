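Package: tddemux
Title: Demultiplexing Top-Down DIA Mass Spectrometry Data into Pseudo MS/MS Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts multiplexed top-down data-independent-acquisition (TD-DIA)
    tandem mass spectrometry data into pseudo non-multiplexed MS/MS spectra.
    Single-charge proteoform features (SCPFs) assigned to each isolation window
    are matched to deconvoluted fragment features by a three-round filtering
    cascade: an apex-cycle-distance gate, a trainable logistic pair-scoring
    model on three chromatographic attributes (normalized intensity rank,
    normalized cycle number, shared extracted-ion-chromatogram area), and
    mass-group quotas derived from an Averagine length estimate. Includes
    spectrum-level noise filtering, msalign-style output for downstream
    database search, intensity-ranked duplicate-proteoform removal with a
    +/- 1.00235 Da deconvolution-error rule, cross-run merging for gas-phase
    fractionated experiments, and a synthetic TD-DIA run generator with full
    ground truth so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pROC,
    stats,
    utils
Suggests:
    mzR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
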
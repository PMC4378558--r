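Package: ldeconv
Title: Top-Down Spectral Deconvolution with the L-Score
Version: 0.1.0
Authors@R:
    person("ldeconv", "maintainers", email = "ldeconv@example.org",
           role = c("aut", "cre"))
Description: Converts centroided top-down tandem mass spectra into ranked
    monoisotopic mass lists. Candidate isotopomer envelopes are enumerated
    from signal peaks and valid charge states with the averagine model,
    matched and scaled against the spectrum, filtered on missing-peak rules,
    and evaluated with a five-feature linear score (L-score) calibrated to
    local false discovery rates via per-group lookup tables. Includes the
    training procedure (fragment-ion labeling, per-group logistic
    regression, FDR table construction), comparison scorers (dot product,
    Kullback-Leibler divergence), a ground-truthed synthetic spectrum
    simulator, an ROC/AUC evaluation harness, mzXML/mzML/peak-list readers
    and an msalign-style mass-list writer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
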
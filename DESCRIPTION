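Package: pepstruct
Title: Postprandial Free Amino Acid, Dipeptide and Tripeptide Structure
    from Ninhydrin Amine-Group Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the composition of protein-digestion end products
    (free amino acids, dipeptides, tripeptides) appearing in blood after a
    meal, from paired ninhydrin readings of a 10 kD plasma filtrate taken
    before (F) and after (T) acidic hydrolysis of peptide bonds. Implements
    the amine-group accounting model, the feasible-composition set for a
    given ratio W = T/F, the uniform-average "mean structure" estimator
    (deterministic quadrature and Monte-Carlo rejection sampling), a
    baseline-adjusted AUC decomposition pipeline for mixed meal tolerance
    test (MMTT) time series, and a synthetic MMTT generator for
    parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
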
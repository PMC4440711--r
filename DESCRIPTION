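Package: cleavescan
Title: Position Weight Matrix Prediction of Matrix Metalloproteinase Cleavage Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives matrix metalloproteinase (MMP) specific position weight
    matrices (PWMs) from cleavage-annotated phage-display substrate peptides,
    scores every peptide bond of a protein with a log2 likelihood-ratio window
    over the P3-P2' subsites, and selects enzyme-specific offset and threshold
    parameters by F1-maximising grid search under 10-fold cross-validation.
    Includes a virtual mass spectrometry module that enumerates digest fragments
    with monoisotopic masses and score-derived intensities, evaluation machinery
    (confusion metrics, ROC/AUC, two-sample Kolmogorov-Smirnov separation,
    cleavage-position refinement), a phage-display substrate simulator with a
    planted cleavage motif, and a command-line workflow for training,
    prediction, evaluation and virtual digestion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
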
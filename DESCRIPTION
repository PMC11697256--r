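Package: covscreen
Title: Analysis of Competitive Cysteine-Profiling Chemoproteomic Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data analysis for high-throughput label-free competitive
    cysteine-profiling (activity-based protein profiling) screens of covalent
    fragments. Reads precursor-level quantification reports from
    data-independent-acquisition search engines, collapses precursors to
    cysteine-site peptide intensities, computes competition ratios with
    Welch's t-tests and a filter cascade for hit calling, fits bounded
    four-parameter logistic concentration-response curves to derive pTE50
    values, scores interaction selectivity, enumerates the detectable
    cysteinome by in-silico tryptic digestion, classifies cysteines as
    pocket-proximal from structure files and Fpocket alpha-sphere output,
    and simulates whole screens with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    stringr,
    rlang,
    yaml,
    jsonlite,
    minpack.lm,
    Biostrings,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
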
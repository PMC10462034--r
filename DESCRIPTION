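Package: squigmatch
Title: Basecalling-Free Nanopore Read Classification with a Run-Length
    BWT Index over Quantized Signal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies raw nanopore current traces without basecalling.
    Raw picoamp signal is segmented into events, normalized, and quantized
    into a small alphabet of picoamp ranges; references are rendered into
    the same alphabet through a pore model. Matching uses a run-length
    Burrows-Wheeler transform index that computes pseudo-matching lengths
    (truncated matching statistics) in a single streaming pass, localizes
    matches with a shredded sampled document array, and classifies reads
    by a complexity-weighted document vote, in batch or in adaptive-sampling
    style signal chunks. Includes a signal simulator with ground-truth
    labels so the full pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'poreModel.R'
    'signal.R'
    'reference.R'
    'classify.R'
    'index.R'
    'pml.R'
    'simulate.R'
    'evaluate.R'
    'cli.R'
    'squigmatch-package.R'
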
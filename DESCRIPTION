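Package: optsne
Title: Optimized t-SNE Embedding with Real-Time KLD-Guided Parameter Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Barnes-Hut t-SNE for large single-cell cytometry and
    transcriptomics matrices with automated, dataset-tailored parameter
    selection ("opt-SNE"): the gradient-descent learning rate is scaled to
    the dataset size (eta = n/alpha), the Kullback-Leibler divergence (KLD)
    is monitored at every iteration, early exaggeration is removed at the
    local maximum of the relative rate of KLD change (maxKLDRC), and the
    run terminates when per-iteration relative KLD improvement falls below
    a configurable fraction. Includes the 1-nearest-neighbor embedding
    quality protocol, arcsinh/log cytometry preprocessing, CSV/TSV and
    basic FCS readers, a labeled synthetic cytometry mixture generator for
    end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    FNN
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
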
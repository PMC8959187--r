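Package: offcnv
Title: Genome-Wide Copy Number Variant Calling from Binned Read Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls germline deletions and duplications genome-wide from the
    read depth of targeted-capture or exome sequencing experiments, using the
    sparse off-target reads that such assays produce as a by-product. Read
    counts in fixed-width genomic bins are normalised to a relative dosage,
    denoised by truncated singular value decomposition of the log dosage,
    assigned per-cell error estimates from a multiplicative model with a
    Poisson floor, and segmented into copy-number states by a three-state
    hidden Markov model. Includes a cohort simulator with planted CNVs and a
    precision/recall benchmarking harness with quality-threshold sweeps and
    boundary-error metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
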
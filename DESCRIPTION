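Package: paleometh
Title: Ancient-DNA Methylation Inference and Coverage Sufficiency Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates ancient-DNA read sets with methylation-dependent
    cytosine deamination, estimates per-CpG methylation levels from C-to-T
    damage signals by windowed binomial maximum likelihood, and runs a
    coverage down-sampling experiment (Delta-f precision, SD trendlines,
    2xSD threshold) that yields a minimum sequencing-coverage
    recommendation for paleoepigenomic studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    withr,
    minpack.lm,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
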
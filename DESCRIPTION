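Package: xodosage
Title: Dosage-Compensation Analysis for XX/XO Species from Coverage and
    RNA-seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies X-linked chromosomes from male:female windowed DNA
    read-depth ratios, computes X-to-autosome and female-to-male expression
    ratio statistics from TMM-scaled FPKM matrices, calls sex-biased genes
    with negative-binomial two-group tests (replicated or fixed-BCV
    unreplicated designs), and tests chromosomal enrichment of sex-biased
    genes with Fisher's exact test. Ships a negative-binomial/Poisson
    synthetic-data generator emulating an XX/XO genome under named
    compensation regimes, so the full pipeline is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    edgeR,
    ggplot2,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
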
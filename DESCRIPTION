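Package: rpcascade
Title: Staged Variant Prioritization for Small Retinitis Pigmentosa Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate causal variants in small retinitis
    pigmentosa (RP) families from annotated exome calls. Implements a staged
    filter cascade (call quality, multi-source allele-frequency thresholds
    that depend on the inheritance model, consequence class, and in-silico
    predictor consensus), an inheritance-pattern engine with explicit
    compound-heterozygote trans-phasing, de novo detection and segregation
    exclusion over PED pedigrees, gene-panel tiering with novelty
    classification against a known-mutation catalog, and cohort-level
    diagnostic-yield summaries. Ships a synthetic family-cohort generator
    with a ground-truth manifest so every stage is testable without external
    data, and command-line entry points for end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
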
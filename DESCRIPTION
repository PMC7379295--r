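Package: bilqtl
Title: Introgression Mapping and Metabolite QTL Analysis for Backcross
    Inbred Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for backcross inbred line (BIL)
    populations genotyped with genome-anchored SNP markers: donor
    introgression segment calling with midpoint border rules, bin-based
    genetic map construction from co-segregating markers, recombination
    fraction estimation with Haldane/Kosambi map functions, metabolite
    normalisation to the recurrent parent, and metabolite QTL scanning by
    single-bin ANOVA and Haley-Knott regression with LOD support
    intervals and cross-experiment conservation calls.  Includes a
    forward simulator of the BC3 + selfing breeding scheme (meiosis with
    Poisson crossovers, single-seed descent) so every stage can be
    validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
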
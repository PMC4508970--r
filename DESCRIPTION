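Package: rohscape
Title: Runs of Homozygosity and the Distribution of Functional Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects runs of homozygosity (ROH) from binned heterozygous-SNP
    counts with read-depth correction, classifies them into size classes,
    and studies how predicted deleterious, non-deleterious, synonymous and
    nonsense homozygotes distribute inside and outside ROH. Includes the
    genotype-partition tensor and proportion tables, interaction
    regressions testing slope and intercept differences between functional
    classes, worked count predictions from fitted lines, ROH sharing
    across individuals with a length-preserving randomization null, binned
    Weir-Cockerham Fst and its correlation with sharing, and a diploid
    cohort simulator with planted identity-by-descent tracts for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
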
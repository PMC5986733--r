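Package: founderhap
Title: Founder-Haplotype Mapping and Dating from Runs of Homozygosity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for homozygosity mapping around an index variant in
    multi-sample VCFs: per-carrier run-of-homozygosity (ROH) delimitation,
    trimming to shared homozygous markers, cross-carrier intersection into a
    shared founder haplotype, conversion of physical to genetic length via a
    recombination map, and estimation of the number of generations to the
    most recent common ancestor from the shared-haplotype length. Includes
    recessive-model trio variant filtering with reference-panel homozygote
    count exclusion, and a founder-descent simulator (exponential haplotype
    erosion under the Haldane crossover model) that emits exome-like VCFs
    with full truth records for validation and parametric bootstrap
    confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    generics,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    rtracklayer,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
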
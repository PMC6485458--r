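Package: recombias
Title: Recombination Rates and Biased Gene Conversion at Meiotic Hotspots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of single-molecule crossover (CO) and non-crossover (NCO)
    products collected by pooled sperm typing at human recombination hotspots
    that carry heterozygous poly-A microsatellites. Provides a synthetic-data
    generator emulating the pooled assay design (amplifiable-genome correction,
    reciprocal products, conversion tracts, transmission biases), classification
    of recombinant molecules into crossover breakpoints and simple-, co- and
    complex conversions, exact Poisson rate estimation and group comparison,
    hotspot-center fitting from cumulative frequency curves, stratified
    Mantel-Haenszel rate ratios for GC-biased and insertion-biased gene
    conversion with the transmission-fraction and selection-coefficient chain
    and the Li-Bulmer equilibrium, a perfect mononucleotide-run scanner with
    hotspot/flank zone enrichment tests, and STR population-diversity
    summaries.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    Biostrings,
    IRanges
Suggests:
    metafor,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
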
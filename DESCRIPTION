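Package: resectr
Title: Meiotic DNA Double-Strand-Break Resection Analysis from
    Strand-Specific Endpoint Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of meiotic DNA double-strand-break (DSB) end
    resection from strand-specific nuclease-protection endpoint maps
    (S1-seq) and related assays in budding yeast. Provides 1-bp genomic
    signal-track handling (bedGraph input/output, interval masking,
    reads-per-million normalization, replicate averaging, binning),
    hotspot-anchored co-oriented resection profiles with censored
    weighted-median tract-length estimation, nucleosome-anchored
    metaprofiles and k-means++ clustering of per-hotspot resection
    profiles with MNase-seq overlays, spike-in calibrated ChIP-seq
    normalization with ratio and difference maps, and a mixture model of
    tetrad spore viability that decomposes spore death into random spore
    death and meiosis-I nondisjunction, plus Perkins genetic distances
    from fluorescent-marker tetrads. Seeded synthetic-data generators
    with known ground truth make every stage testable without external
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
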
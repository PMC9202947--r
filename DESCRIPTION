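Package: refstab
Title: Reference Gene Stability Ranking and Relative Quantification for
    RT-qPCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Validation of RT-qPCR reference genes and relative
    quantification of transcripts between two sample groups, as used to
    measure cortex-enrichment of maternal transcripts in sea urchin eggs.
    Implements five expression-stability estimators (BestKeeper-style
    SD/CV on raw Ct, coefficient of variation of relative quantities,
    pairwise delta-Ct, geNorm with stepwise exclusion and pairwise
    variation V(n/n+1), and a NormFinder-style intra-/intergroup variance
    decomposition), amplification-efficiency calibration from dilution
    series with a 90-110 percent acceptance window, FPKM-based screening
    of candidate reference genes and genes of interest, 2^-ddCt relative
    quantification with a t-test between groups, consensus ranking across
    methods, and seeded simulators for Ct tables, dilution series and
    FPKM tables.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
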
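Package: sortscreen
Title: Analysis of FACS-Sorted Pooled CRISPR Knockout Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for pooled CRISPR knockout screens read out by
    fluorescence-activated cell sorting into marker-high and marker-low bins,
    as used to map regulators of the macrophage interferon-gamma response.
    Provides strict readers for guide libraries, count tables, GMT gene sets
    and module definitions; median-of-ratios count normalization; per-guide
    high/low log2 fold changes with a non-targeting-control null; gene-level
    selection coefficients (beta scores) by negative-binomial maximum
    likelihood under marker-blind or marker-aware design matrices; cross-screen
    integration by Stouffer's method into a single ranked gene score with
    k-means clustering of the most selected genes; preranked gene-set
    enrichment with the weighted running-sum statistic and permutation FDR;
    binomial depletion/enrichment tests for genes and protein-complex modules;
    a complex I N-module stability score with its correlation to beta; and a
    seeded generator of synthetic sorting-screen counts with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite
Config/testthat/edition: 3
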
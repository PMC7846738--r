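Package: methevo
Title: Methylation Evolution and Intra-Tumor Heterogeneity Analysis for
    Staged Tumor Precursors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying DNA methylation evolution across staged tumor
    precursor lesions profiled by reduced representation bisulfite sequencing.
    Implements epiallele-based intra-tumor heterogeneity metrics (combinatorial
    entropy, entropy shifts and eloci, epipolymorphism), paired-sample
    differentially methylated region calling with triangular-kernel count
    smoothing and hyper-/hypomethylation classification, methylation and
    mutation distance matrices with neighbor-joining phylogenies rooted at
    matched normal tissue, a LINE-1 surrogate for global methylation, region-set
    enrichment with Benjamini-Yekutieli adjustment, and a synthetic staged
    cohort generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
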
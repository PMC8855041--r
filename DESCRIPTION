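Package: phyloconcord
Title: Multi-Locus Species-Tree Concordance Pipeline for Target-Capture Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for building and comparing species trees from
    multi-locus nucleotide alignments such as those produced by target-capture
    (Hyb-Seq) sequencing. Provides locus-level quality control (gap-threshold
    trimming, matched-pairs symmetry filtering, parsimony-informative-site
    summaries), gene-tree and species-tree inference under both concatenation
    and the multispecies coalescent (quartet-score optimisation with exact
    enumeration or NNI hill-climbing), gene and site concordance factors,
    Robinson-Foulds and Kendall-Colijn tree-landscape ordination with grove
    detection, and RELL-based Shimodaira-Hasegawa and approximately-unbiased
    topology tests. Includes a coalescent simulator that emulates the locus
    structure of exon, intron and plastid target-capture datasets for
    validation and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    pheatmap
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
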
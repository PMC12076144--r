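Package: medseqr
Title: MeD-Seq Methylation Analysis of Cell-Free DNA and Placental Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Count-based analysis of methylation-dependent restriction enzyme
    sequencing (MeD-seq) data, aimed at maternal cell-free DNA and placental
    tissues across gestation. Implements the positional LpnPI read filter,
    reads-per-million normalization, sliding-window chi-squared calling of
    differentially methylated regions (DMRs) with Bonferroni correction and
    fold-change selection, ROC-derived binary methylation thresholds with
    cumulative tissue-of-origin scores, gestational-age-associated placental
    marker selection (buffy-coat hypomethylation filter plus Pearson
    correlation with gestational age), and z-score hierarchical clustering.
    Ships a synthetic-data generator that plants DMRs of known location and
    effect in toy genomes and simulates cell-free DNA as leukocyte/placenta
    mixtures with a gestation-dependent placental fraction, so the whole
    pipeline is testable against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
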
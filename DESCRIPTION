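Package: mirprog
Title: Integrative miRNA-mRNA Screening for Premalignant Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative small-RNA and mRNA screening pipeline for
    premalignant disease progression (normal tissue to chronic
    inflammatory lesion to carcinoma). Provides RPKM and per-million
    expression normalization, a replicate-free exact count test for
    differential expression with false discovery rate control, a
    monotone-progression filter with cross-patient consensus, consensus
    miRNA target prediction over multiple tool exports, de-novo canonical
    seed-site scanning of 3'-UTR sequences (6mer, 7mer-A1, 7mer-m8 and
    8mer site classes), candidate ranking by abundance and
    anti-correlation, regulator-target intersection, and validation-side
    statistics (2^-ddCt relative quantification, weighted
    immunohistochemistry scoring, Spearman correlation, Mann-Whitney U).
    A synthetic-data generator with planted ground truth makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
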
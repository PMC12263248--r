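Package: hetchron
Title: Heterochronic Gene-Expression Shifts from Binary Transcriptome
    Phylogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects heterochronic changes in follicular gene expression
    (neoteny and hypermorphosis) between placental and non-placental fish
    species pairs. Provides one-to-one orthologue identification by
    reciprocal best hits with a synteny filter, FPKM computation and
    median-of-ratios normalization, binary encoding of transcriptomes,
    a two-state reversible phylogenetic likelihood engine with invariant-site,
    discrete-gamma and free-rate mixtures (model fitting, AICc selection,
    tree search, bootstrap support, marginal ancestral state reconstruction),
    threshold-based candidate-gene classification, logistic PCA of binary
    matrices, and a synthetic-data generator with planted ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
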
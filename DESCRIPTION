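Package: crgwas
Title: Composite Resequencing-Based Association Mapping with
    Function-Aided Rare-Variant Collapsing Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Association mapping for resequenced gene fragments in
    structured inbred panels. Implements a unified mixed model with
    kinship (variance structure V = 2K*sigma_g^2 + I*sigma_e^2), BIC
    model selection over population-structure covariates, and GRAMMAR
    phenotype adjustment; single-SNP and multiple-common-variant
    likelihood-ratio tests; three rare-variant collapsing statistics
    (sum, weighted sum, and a function-aided sum test whose per-SNP
    weights combine predicted protein-damage scores with a fitted
    power law linking minor allele frequency to the proportion of
    functional variants); permutation-based experiment-wise thresholds
    (LR/LR99 scaling) and genomic-control deflation; a candidate-gene
    decision layer (a priori confirmation, top-k triage, functional-SNP
    evidence rule, cross-method consistency); and guilt-by-association
    interrogation of a probabilistic gene network with leave-one-out
    ROC seed pruning. Includes synthetic-data generators that emulate
    the allele-frequency spectrum, functional-prediction decay,
    polygenic phenotype structure, and clustered seed networks the
    pipeline assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
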
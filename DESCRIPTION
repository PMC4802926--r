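Package: assocPanel
Title: Design and Power Assessment of Structured Germplasm Association Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising germplasm diversity panels and designing
    association (GWAS) panels from large structured collections. Implements
    per-locus and per-group diversity statistics and Weir-Cockerham
    differentiation; five marker-based coancestry estimators (alikeness in
    state, group-corrected variants, Loiselle's correlation estimator, and a
    maximum-likelihood IBD-coefficient estimator) with selection of the best
    estimator by minimising corrected inter-chromosomal linkage
    disequilibrium; kinship- and structure-corrected LD (r2, r2_V, r2_VS)
    with sliding-window summaries; Hill-Weir expected-r2 decay fitting with
    LD-extent and marker-density derivations; effective-number-of-tests
    multiple-testing correction and analytic mixed-model association power at
    causal loci and linked markers; a structure-aware maximin panel-design
    workflow with iterative first-degree relatedness pruning; and a synthetic
    structured-panel generator (Balding-Nichols differentiation, haplotype-
    pool copying LD, injected relatives, mixed-model phenotypes) used to
    validate the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'assocPanel-package.R'
    'methods-GenotypePanel.R'
    'genotypes-io.R'
    'diversity.R'
    'synthetic-panel.R'
    'kinship.R'
    'corrected-ld.R'
    'ld-decay.R'
    'gwas-power.R'
    'panel-design.R'
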
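Package: cnvmetabo
Title: Copy-Number Dosage Metabolomic QTL Analysis from SNP-Array Intensities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for studying the dosage effect of copy-number
    variants (CNVs) on metabolomic phenotypes from SNP-array intensity data.
    Simulates probe maps, log R ratio (LRR) and B allele frequency (BAF)
    matrices with GC and genomic-wave artifacts and planted CNV regions,
    together with block-correlated metabolite panels carrying linear dosage
    effects. Normalises LRR (GC regression, windowed local-regression wave
    correction, principal-component covariates), genotypes copy number 0-4
    along each sample with a distance-aware hidden Markov model
    (forward-backward posteriors, Viterbi segments, expected-genotype
    "countAll" dosages), associates dosage with metabolites by univariate and
    multivariate reverse regression with backward-selection metabolomic
    signatures and an effective-number-of-tests (Sidak-Nyholt) correction,
    combines cohorts by fixed-effect meta-analysis and pooled regression, and
    builds a beacon annotation table matching external GWAS summary
    statistics to probes by genomic position.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
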
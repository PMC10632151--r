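Package: polybias
Title: Homoeolog Expression Bias and Subgenome-Aware Genetic Analysis in Allopolyploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the genetic regulation of duplicated
    (homoeologous) gene expression in allotetraploid species. Computes
    homoeolog expression-bias scores and per-accession bias calls, assigns
    temporal bias classes and clusters gene pairs into switched,
    time-dependent and dominant groups; maps cis-, trans- and bias-eQTLs
    with a permutation-based linear-model scan, clusters significant SNPs
    into loci and detects trans-eQTL hotspots; builds the bipartite
    locus-gene regulatory network with modularity-based modules,
    module-trait profiles and Haseman-Elston heritability; classifies
    homoeolog pairs into four subgenome coordination models; and supports
    genomic design through a favorable-allele library, ridge-regression
    breeding values and a donor-parent improvement matrix. Includes a
    synthetic-cohort generator with a machine-readable truth set so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    rlang,
    vcfR
Suggests:
    glmnet,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
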
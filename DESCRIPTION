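Package: tetradose
Title: Subgenome Dosage Dynamics and Homoeologous Exchange in Neoallotetraploids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying genome composition in newly synthesized
    allotetraploids such as the peanut neoallotetraploid derived from
    Arachis duranensis (A subgenome) and Arachis ipaensis (B subgenome).
    Provides a tetrasomic-segregation forward simulator of selfing lineages
    undergoing homoeologous exchange, discovery of subgenome-diagnostic
    AB sites from parental fragment and read consensus, normalized
    subgenome allele-count profiles with windowed euploid and aneuploid
    dosage-state classification, tetraploid (0-4) array dosage calling
    with a control-mixture marker filter cascade, chromosome-set
    composition matrices with generation-to-generation transition
    statistics and flower-color prediction, and selection-response
    statistics comparing tetraploid and diploid populations under
    divergent seed-weight selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
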
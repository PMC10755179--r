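Package: dictyvar
Title: Variant Filtration and Cheater-Mutation Association for Experimentally
    Evolved Dictyostelium discoideum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect selection-driven mutations in low-relatedness
    experimental evolution of the social amoeba Dictyostelium discoideum.
    Implements the full single-nucleotide variant filtration cascade used on
    haploid pooled and clonal sequencing data (ancestral-polymorphism masking
    by major allele frequency, per-caller hard filters, custom quality and
    missingness filters, cross-caller intersection, and read-support
    validation), structural-variant quality filtering, toy-genome consequence
    annotation, per-gene parallelism summaries, and a clone-genotype
    association screen linking variants to the loss of fruiting body
    formation (Fisher's exact test computed from first principles, exact
    binomial prevalence intervals). A synthetic-data module simulates serial
    passage evolution of selected mutations, mapped-depth read counts, and
    emulated caller output with injected false positives so that the whole
    pipeline can be validated against a known truth set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
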
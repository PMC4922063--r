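Package: semiRecMap
Title: Mapping and Prioritizing Semi-Recessive Trait Mutations in Case/Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for mapping an autosomal semi-recessive
    trait locus in a case/control cohort and prioritizing the causal variant.
    Provides Mendelian segregation-ratio testing and penetrance estimation,
    marker quality-control filters with max-T permutation genome-wide
    empirical significance, haplotype-concordance block discovery with
    recombinant-bounded candidate-interval definition, a co-segregation plus
    population-panel variant-filter cascade with coding-effect annotation,
    exon-level RPKM quantification that resolves isoform-specific expression
    loss, and allele-aware scanning for transcription-factor binding sites
    gained de novo by insertions, with indel-aware coordinate projection.
    A synthetic-data module generates cohorts, litters, variant calls, exon
    counts and promoter allele pairs with planted truth for end-to-end
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    withr,
    yaml,
    vcfR,
    Biostrings,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
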
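Package: clonediv
Title: Clonal Intra-Varietal Diversity Analysis from Codominant, Dominant
    and Morphological Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify intra-varietal (clonal) diversity in
    vegetatively propagated crops such as grapevine. Implements per-locus
    microsatellite diversity indices (allele counts, observed and expected
    heterozygosity, Shannon index, Wright's fixation index, Stoddart-Taylor
    evenness), multilocus genotype identification, Prevosti distances for
    codominant SSR profiles, Jaccard distances for dominant band profiles,
    Gower distances for quantitative traits, UPGMA clustering with Newick
    export and cophenetic analysis, Mantel permutation tests for concordance
    between marker systems, and a quantitative-morphology stage with one-way
    ANOVA, Duncan's multiple range test, coefficients of variation and
    correlation-matrix PCA. Includes a seeded simulator of clonal populations
    (shared founder genotype, rare somatic stepwise SSR mutations, band
    gain/loss, clone-level trait effects) so the full pipeline can be
    exercised without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    ape,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
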
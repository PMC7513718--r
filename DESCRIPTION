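Package: wildmix
Title: Genomic and Morphological Assessment of Domestic Introgression in
    Wild Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for quantifying domestic introgression in wild
    populations of domesticated species' progenitors, developed around the
    red junglefowl (Gallus gallus) system.  Provides genotype quality
    control (locus presence and minor-allele-frequency filters, windowed
    linkage-disequilibrium pruning, maximum-likelihood kinship screening),
    a K-component maximum-likelihood admixture model with anchor-based
    label orientation, genotype principal component analysis on the
    domestic-wild continuum, a sex-specific categorical trait scoring
    scheme normalised to a 0-100 morphology score, regression and
    AIC-based subset selection linking morphology to genomic ancestry,
    and threshold classifiers with false-positive/false-negative
    accounting for management decisions.  Includes a synthetic-data
    generator emulating the study design (divergent ancestral allele
    pools, an admixture gradient, sparse historic anchor samples, and
    ancestry-linked categorical traits) so that every stage can be tested
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    VariantAnnotation,
    SummarizedExperiment,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
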
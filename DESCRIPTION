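Package: ssrmut
Title: Property-Grouped Filtering and Mutation-Rate Modeling for Simple
    Sequence Repeats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating simple sequence repeat (SSR) mutation rates
    from mutation-accumulation sequencing experiments. Builds a genome-wide
    SSR catalog by exhaustive string search with merging of external
    repeat-finder loci, filters per-strain allele calls using
    property-grouped quantile thresholds on the genotype-likelihood gap
    (deltaGL) between the two best alleles, fits a binomial model of per-bp
    mutation odds with a log-length exposure offset and profile-likelihood
    confidence intervals (robust to complete separation), and computes
    insertion/deletion spectrum and genic-enrichment statistics. A bundled
    simulator generates catalogs, cohorts and noisy call sets with
    stutter-like false positives so the whole pipeline can be exercised and
    validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    MASS,
    yaml
Config/testthat/edition: 3
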
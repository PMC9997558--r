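#' Assemble a pipeline run configuration
#'
#' Collects every tunable of the analysis with defaults matching the
#' method's published constants: 100-bp mask padding, 10x minimum depth,
#' +/-2.5-copy grouping window, >25-locus group minimum, 35% threshold
#' quantile, a 0-0.95 scan grid in steps of 0.05, 8-bp long-SSR cutoff,
#' 50-bp recurrent-SNM clustering window, 25% alternate-read-support
#' artifact rule and a deltaGL-of-20 confidence floor for repetitive-context
#' non-SSR calls. Every tunable is echoed into the run report.
#'
#' @param ... overrides of any default, plus optional input elements:
#'   `simulate` (a [SimulationConfig-class]; default a fresh one seeded
#'   with `seed`) or `catalog` / `calls` / `mask` / `genotypes` objects.
#' @return a `list` of class `RunConfig`.
#' @export
runConfig <- function(...) {
    cfg <- list(pad = 100L, min_depth = 10L, window = 2.5,
                min_group_loci = 26L, quantile = 0.35,
                grid = seq(0, 0.95, by = 0.05), long_cutoff_bp = 8L,
                snm_cluster_window = 50L, alt_support = 0.25,
                non_ssr_confidence = 20, generations = 200, seed = 1L,
                simulate = NULL, catalog = NULL, calls = NULL, mask = NULL,
                genotypes = NULL)
    over <- list(...)
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
    class(cfg) <- "RunConfig"
    cfg
}

#' Read a RunConfig from a YAML file
#'
#' Scalar tunables only; object-valued inputs (catalog, calls, ...) are
#' given as file paths under `paths:` and loaded with the package readers.
#'
#' @param path YAML file.
#' @return a `RunConfig`.
#' @export
readRunConfig <- function(path) {
    if (!requireNamespace("yaml", quietly = TRUE))
        stop("readRunConfig requires the yaml package")
    y <- yaml::read_yaml(path)
    paths <- y$paths; y$paths <- NULL
    cfg <- do.call(runConfig, y)
    if (!is.null(paths$catalog)) cfg$catalog <- readCatalog(paths$catalog)
    if (!is.null(paths$calls)) cfg$calls <- readCallTable(paths$calls)
    if (!is.null(paths$genotypes))
        cfg$genotypes <- read.table(paths$genotypes, header = TRUE,
                                    sep = "\t", stringsAsFactors = FALSE)
    cfg
}

#' Run the full analysis pipeline
#'
#' Executes catalog acquisition (simulated or supplied), masking and depth
#' filtering, SSR threshold scanning and mutation selection, the odds-model
#' fits with profile intervals, and the spectrum / enrichment statistics,
#' returning a structured report with per-stage counts (every removal
#' attributed to exactly one reason).
#'
#' @param config a `RunConfig` from [runConfig()].
#' @return a `list` report; see elements `counts`, `thresholds`, `scan`,
#'   `events`, `odds`, `spectrum`, `config_echo`.
#' @export
runPipeline <- function(config = runConfig()) {
    stopifnot(inherits(config, "RunConfig"))
    if (is.null(config$catalog) || is.null(config$calls)) {
        simcfg <- config$simulate
        if (is.null(simcfg)) simcfg <- simulationConfig(seed = config$seed)
        sim <- simulateCallSet(simcfg)
        catalog <- sim$catalog
        calls <- sim$calls
        genotypes <- sim$cohort$strains
    } else {
        catalog <- config$catalog
        calls <- config$calls
        genotypes <- config$genotypes
        if (is.null(genotypes))
            stop("genotypes are required when supplying calls directly")
    }
    counts <- list(input_calls = nrow(calls),
                   uncalled = sum(!calls$called))
    masked <- applyMasks(calls, config$mask, min_depth = config$min_depth,
                         pad = config$pad)
    counts$removed_region_depth <- unname(sum(attr(masked, "removed")))

    scan <- stabilityScan(masked, catalog, quantile_grid = config$grid,
                          window = config$window,
                          min_loci = config$min_group_loci)
    events <- selectMutations(masked, catalog, quantile = config$quantile,
                              window = config$window,
                              min_loci = config$min_group_loci)
    passing <- attr(events, "passing")
    counts$ssr_calls_pass <- nrow(passing)
    counts$ssr_calls_dropped_unthresholdable <- attr(passing, "dropped")
    counts$ssr_calls_failed_threshold <- attr(passing, "failed")
    counts$ssr_mutations <- nrow(events)

    outcomes <- assembleOutcomes(passing, catalog, genotypes,
                                 long_cutoff_bp = config$long_cutoff_bp)
    mut_only <- outcomes[outcomes$genotype ==
                         levels(factor(outcomes$genotype))[
                             nlevels(factor(outcomes$genotype))], ,
                         drop = FALSE]
    odds <- NULL
    if (any(mut_only$mutated) && !all(mut_only$mutated)) {
        fit_full <- fitOddsModel(mut_only,
                                 terms = c("long", "motif_length",
                                           "at_proportion"))
        fit_long <- fitOddsModel(mut_only, terms = "long")
        fit_len <- fitOddsModel(mut_only, terms = character(0))
        odds <- list(
            estimates = oddsEstimates(fit_full),
            ci_long = profileCI(fit_long, "long"),
            p_long = lrTest(fit_long, fit_len)$p,
            p_motif = lrTest(fitOddsModel(mut_only, c("long", "motif_length")),
                             fit_long)$p,
            p_at = lrTest(fitOddsModel(mut_only, c("long", "at_proportion")),
                          fit_long)$p)
        if (length(unique(outcomes$genotype)) == 2L) {
            fit_gt <- fitOddsModel(outcomes, terms = c("long", "genotype"))
            odds$genotype_estimate <- oddsEstimates(fit_gt)[["genotype"]]
            odds$ci_genotype <- profileCI(fit_gt, "genotype")
            odds$genotype_separated <- !fit_gt@converged[["genotype"]]
        }
    }
    spectrum <- list(table = spectrumTable(events),
                     deletion_bias = lapply(setNames(1:4, paste0("motif_", 1:4)),
                                            function(k) deletionBiasTest(events, k)),
                     genic = if (!all(is.na(catalog$genic)))
                         genicEnrichment(events, catalog) else NULL)
    report <- list(counts = counts, thresholds = NULL, scan = scan,
                   events = events, odds = odds, spectrum = spectrum,
                   config_echo = config[c("pad", "min_depth", "window",
                                          "min_group_loci", "quantile",
                                          "long_cutoff_bp",
                                          "snm_cluster_window", "alt_support",
                                          "non_ssr_confidence", "generations",
                                          "seed")])
    report
}

#' Write a pipeline report to JSON
#'
#' @param report result of [runPipeline()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
    slim <- report
    slim$events <- NULL
    slim$scan <- as.list(report$scan)
    jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                         force = TRUE, pretty = TRUE)
    invisible(path)
}
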
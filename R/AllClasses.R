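#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols
#' @importFrom stats pchisq qchisq rbinom rgeom rlnorm rnbinom runif rbeta
#'   binom.test fisher.test setNames lm.wfit aggregate
#' @importFrom utils read.table write.table
NULL

#' SsrCatalog: a genome-wide list of simple sequence repeat loci
#'
#' An `SsrCatalog` is a [GenomicRanges::GRanges] with mandatory metadata
#' columns describing each repeat locus: `motif` (uppercase primitive motif,
#' usually 1-4 bp), `copy_number` (possibly fractional number of motif
#' copies), `at_proportion` (fraction of locus bases that are A or T),
#' `genic` (logical; midpoint falls inside a gene body) and `source`
#' (`"string-search"`, `"external"` or `"merged"`). Locus length in bp equals
#' `width(x)` and always equals `copy_number * nchar(motif)`.
#'
#' Coordinates follow the GRanges convention (1-based, closed); all TSV/BED
#' interchange performed by [writeCatalog()] / [readCatalog()] is 0-based
#' half-open.
#'
#' @slot .Data see [GenomicRanges::GRanges]
#' @seealso [findSSRs()], [mergeCatalogs()], [annotateGenic()]
#' @export
setClass("SsrCatalog", contains = "GRanges")

.validSsrCatalog <- function(object) {
    msg <- character()
    mc <- S4Vectors::mcols(object)
    need <- c("motif", "copy_number", "at_proportion", "source")
    miss <- setdiff(need, colnames(mc))
    if (length(miss))
        return(paste("missing metadata column(s):", paste(miss, collapse = ", ")))
    if (length(object)) {
        if (any(is.na(mc$motif)) || any(!grepl("^[ACGT]+$", mc$motif)))
            msg <- c(msg, "motif must be an uppercase ACGT string")
        k <- nchar(mc$motif)
        bad <- abs(mc$copy_number * k - GenomicRanges::width(object)) > 1e-6
        if (any(bad))
            msg <- c(msg, sprintf("%d locus/loci violate copy_number * motif length == width",
                                  sum(bad)))
        if (any(mc$at_proportion < -1e-9 | mc$at_proportion > 1 + 1e-9))
            msg <- c(msg, "at_proportion must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
}
setValidity("SsrCatalog", .validSsrCatalog)

#' Construct an SsrCatalog from a GRanges
#'
#' @param gr a `GRanges` carrying metadata columns `motif`, `copy_number`,
#'   `at_proportion`, `source` (and optionally `genic`).
#' @return an [SsrCatalog-class] object.
#' @export
SsrCatalog <- function(gr) {
    if (is.null(gr$genic)) gr$genic <- rep(NA, length(gr))
    new("SsrCatalog", gr)
}

setMethod("show", "SsrCatalog", function(object) {
    cat(sprintf("SsrCatalog with %d loci on %d sequence(s)\n",
                length(object), length(GenomeInfoDb::seqlevels(object))))
    if (length(object)) {
        k <- nchar(object$motif)
        tab <- table(factor(k, levels = sort(unique(k))))
        cat("  motif lengths:",
            paste(sprintf("%s bp: %d", names(tab), as.integer(tab)), collapse = ", "),
            "\n")
        if (!all(is.na(object$genic)))
            cat(sprintf("  genic: %.1f%%\n", 100 * mean(object$genic, na.rm = TRUE)))
    }
    invisible(NULL)
})

#' Locus identifiers for an SsrCatalog
#'
#' Identifiers are `"chrom:start-end"` with 0-based half-open coordinates,
#' stable across serialization round trips.
#'
#' @param x an `SsrCatalog`.
#' @return character vector of locus ids.
#' @export
locusIds <- function(x) {
    sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(x)),
            GenomicRanges::start(x) - 1L, GenomicRanges::end(x))
}

#' ThresholdTable: per-group deltaGL cutoffs
#'
#' One row per (motif_length, at_bin, copy_number) group holding the deltaGL
#' cutoff at the chosen quantile, plus the number of distinct loci and calls
#' the cutoff was computed from. Groups spanning fewer than `min_loci`
#' distinct loci are absent: calls at their loci are unthresholdable and are
#' dropped by [applyThresholds()].
#'
#' @slot table data.frame with columns `motif_length`, `at_bin`,
#'   `copy_number`, `cutoff`, `n_loci`, `n_calls`.
#' @slot quantile the quantile used (0 to 0.95).
#' @slot window half-width, in motif copies, of the grouping window.
#' @slot min_loci minimum distinct loci per group (strictly more than 25 by
#'   default, i.e. 26).
#' @export
setClass("ThresholdTable",
         representation(table = "data.frame", quantile = "numeric",
                        window = "numeric", min_loci = "integer"))

setValidity("ThresholdTable", function(object) {
    msg <- character()
    if (length(object@quantile) != 1 || object@quantile < 0 || object@quantile > 0.95)
        msg <- c(msg, "quantile must be a single value in [0, 0.95]")
    need <- c("motif_length", "at_bin", "copy_number", "cutoff", "n_loci", "n_calls")
    if (!all(need %in% colnames(object@table)))
        msg <- c(msg, "table lacks required columns")
    else if (nrow(object@table) && any(object@table$n_loci < object@min_loci))
        msg <- c(msg, "table contains groups below the locus minimum")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ThresholdTable", function(object) {
    cat(sprintf("ThresholdTable: %d group(s) at quantile %.2f (window +/-%.1f copies, >=%d loci/group)\n",
                nrow(object@table), object@quantile, object@window, object@min_loci))
    invisible(NULL)
})

#' Accessor for the threshold data.frame
#' @param x a `ThresholdTable`.
#' @return the underlying data.frame of per-group cutoffs.
#' @export
thresholdTable <- function(x) x@table

#' RateEstimate: a mutation rate with exact Poisson confidence bounds
#'
#' @slot n_mutations integer count of mutations.
#' @slot exposure callable bp x strains x generations.
#' @slot rate mutations per bp per generation.
#' @slot ci_low,ci_high exact (Garwood) 95% bounds on the rate.
#' @slot conf_level the confidence level.
#' @export
setClass("RateEstimate",
         representation(n_mutations = "integer", exposure = "numeric",
                        rate = "numeric", ci_low = "numeric",
                        ci_high = "numeric", conf_level = "numeric"))

setValidity("RateEstimate", function(object) {
    msg <- character()
    if (object@exposure <= 0) msg <- c(msg, "exposure must be positive")
    if (object@n_mutations < 0) msg <- c(msg, "count must be non-negative")
    if (object@ci_low > object@rate + 1e-12 || object@ci_high < object@rate - 1e-12)
        msg <- c(msg, "confidence interval must contain the point estimate")
    if (length(msg)) msg else TRUE
})

setMethod("show", "RateEstimate", function(object) {
    cat(sprintf("RateEstimate: %d mutations over %.3g bp*generations\n",
                object@n_mutations, object@exposure))
    cat(sprintf("  rate = %.3g (%.0f%% CI %.3g-%.3g) mutations/bp/generation\n",
                object@rate, 100 * object@conf_level, object@ci_low, object@ci_high))
    invisible(NULL)
})

#' OddsModelFit: a fitted per-bp mutation-odds model
#'
#' Represents the model odds(mutation) = n * O_base * prod(theta_i), fitted
#' as a binomial GLM on the logit scale with a log(length) offset. The
#' intercept is log(O_base); every other coefficient is log(theta) for its
#' term. Complete separation (e.g. zero mutations in one genotype) is flagged
#' per term: the estimate is +/-Inf on the odds scale and profiling yields a
#' one-sided interval.
#'
#' @slot coefficients named numeric, log-odds scale (`"(baseline)"` first).
#' @slot terms character vector of model terms (excluding the baseline).
#' @slot loglik maximized binomial log-likelihood (Bernoulli form, no
#'   combinatorial constant).
#' @slot converged named logical per coefficient; FALSE marks separation.
#' @slot n number of locus-strain outcome records fitted.
#' @slot n_mutated number of mutated records.
#' @slot data internal list (aggregated design) retained for likelihood
#'   profiling and nested tests.
#' @export
setClass("OddsModelFit",
         representation(coefficients = "numeric", terms = "character",
                        loglik = "numeric", converged = "logical",
                        n = "integer", n_mutated = "integer", data = "list"))

setMethod("show", "OddsModelFit", function(object) {
    cat(sprintf("OddsModelFit on %d locus-strain outcomes (%d mutated)\n",
                object@n, object@n_mutated))
    est <- exp(object@coefficients)
    lab <- names(object@coefficients)
    for (i in seq_along(est)) {
        note <- if (!object@converged[i]) "  [separated]" else ""
        cat(sprintf("  %-18s %0.4g%s\n", lab[i], est[i], note))
    }
    cat(sprintf("  log-likelihood: %.4f\n", object@loglik))
    invisible(NULL)
})

#' Odds-scale estimates from a fit
#'
#' @param fit an `OddsModelFit`.
#' @return named numeric of fold-odds estimates: baseline per-bp odds
#'   `O_base` followed by the theta multipliers.
#' @export
oddsEstimates <- function(fit) exp(fit@coefficients)

#' Maximized log-likelihood of a fit
#' @param fit an `OddsModelFit`.
#' @return numeric scalar.
#' @export
modelLogLik <- function(fit) fit@loglik
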
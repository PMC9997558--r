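#' Cluster substitution calls across strains to flag recurrent artifacts
#'
#' Because independently derived mutation-accumulation lines almost never
#' share a true mutation, positions mutated in multiple strains — or mutated
#' within a short distance of a mutation in another strain — indicate
#' systematic miscalls. Calls are single-linkage clustered within
#' `window_bp` (inclusive) per chromosome; any cluster represented by two or
#' more distinct strains is recurrent and all its members are removed by
#' [filterSnm()].
#'
#' @param calls data.frame of substitution calls with columns `strain`,
#'   `chrom`, `pos`.
#' @param window_bp clustering distance in bp (default 50, inclusive).
#' @return data.frame with one row per cluster: `cluster`, `chrom`, `span`,
#'   `n_strains`, `n_calls`, `recurrent`, plus a list-column `members` of
#'   row indices into `calls`.
#' @export
clusterRecurrent <- function(calls, window_bp = 50L) {
    if (!nrow(calls)) {
        return(data.frame(cluster = integer(0), chrom = character(0),
                          span = integer(0), n_strains = integer(0),
                          n_calls = integer(0), recurrent = logical(0)))
    }
    ord <- order(calls$chrom, calls$pos)
    chrom <- calls$chrom[ord]; pos <- calls$pos[ord]
    new_cluster <- c(TRUE, chrom[-1] != chrom[-length(chrom)] |
                           diff(pos) > window_bp)
    cl <- cumsum(new_cluster)
    out <- lapply(split(seq_along(cl), cl), function(ii) {
        orig <- ord[ii]
        data.frame(chrom = chrom[ii[1]],
                   span = max(pos[ii]) - min(pos[ii]),
                   n_strains = length(unique(calls$strain[orig])),
                   n_calls = length(orig), stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, out)
    df$cluster <- seq_len(nrow(df))
    df$recurrent <- df$n_strains >= 2L
    df$members <- I(split(ord, cl))
    rownames(df) <- NULL
    df[, c("cluster", "chrom", "span", "n_strains", "n_calls", "recurrent",
           "members")]
}

#' Flag calls with excessive support for the non-called allele
#'
#' Loci at which more than `threshold` of mapped reads support an allele
#' other than the called one behave like systematic artifacts (the same
#' pattern seen at recurrently "mutated" loci). The inequality is strict:
#' exactly 25% is clean.
#'
#' @param alt_support numeric in `[0, 1]`.
#' @param threshold default 0.25.
#' @return logical: `TRUE` means unreliable.
#' @export
alleleSupportFlag <- function(alt_support, threshold = 0.25) {
    alt_support > threshold
}

#' Mutation rate with exact Poisson confidence bounds
#'
#' Treats the mutation count as Poisson with exposure
#' `sum(callable_bp_per_strain) * generations` and reports the rate with a
#' Garwood (exact chi-square) confidence interval. For zero counts the lower
#' bound is 0 and the upper bound is `qchisq(0.975, 2) / 2 = 3.689` counts.
#'
#' @param n_mutations integer count.
#' @param callable_bp_per_strain numeric vector, callable bp per strain.
#' @param generations generations of mutation accumulation.
#' @param conf_level confidence level (default 0.95).
#' @return a [RateEstimate-class].
#' @export
estimateRate <- function(n_mutations, callable_bp_per_strain, generations,
                         conf_level = 0.95) {
    exposure <- sum(callable_bp_per_strain) * generations
    if (!is.finite(exposure) || exposure <= 0) stop("exposure must be positive")
    n <- as.integer(n_mutations)
    a <- 1 - conf_level
    lo <- if (n == 0) 0 else qchisq(a / 2, 2 * n) / 2
    hi <- qchisq(1 - a / 2, 2 * (n + 1)) / 2
    new("RateEstimate", n_mutations = n, exposure = exposure,
        rate = n / exposure, ci_low = lo / exposure, ci_high = hi / exposure,
        conf_level = conf_level)
}

#' Compare two mutation rates by an exact conditional binomial test
#'
#' Conditional on the total count, the count in group A is binomial with
#' success probability equal to A's share of the total exposure; the
#' two-sided p-value uses the minimum-likelihood convention of
#' [stats::binom.test()]. With zero total count the split carries no
#' information and p = 1.
#'
#' @param n_a,n_b mutation counts.
#' @param exposure_a,exposure_b exposures (bp x strains x generations).
#' @return two-sided p-value.
#' @export
compareRates <- function(n_a, exposure_a, n_b, exposure_b) {
    stopifnot(exposure_a > 0, exposure_b > 0)
    total <- n_a + n_b
    if (total == 0) return(1)
    binom.test(n_a, total, p = exposure_a / (exposure_a + exposure_b))$p.value
}

#' Filter non-SSR single-nucleotide mutation calls
#'
#' Applies the full substitution filtration chain: restrict to mutant
#' substitution calls outside SSR catalog loci, region/depth masking,
#' low-confidence removal in repetitive context (deltaGL below
#' `non_ssr_confidence` when the call is flagged `repetitive`), and removal
#' of recurrent clusters ([clusterRecurrent()]).
#'
#' @param calls normalized call table; an optional logical column
#'   `repetitive` marks calls in non-SSR repetitive context.
#' @param catalog an [SsrCatalog-class] used to exclude SSR-overlapping
#'   calls (may be `NULL`).
#' @param mask optional region mask `GRanges` (see [applyMasks()]).
#' @param min_depth minimum depth (default 10).
#' @param pad mask padding in bp (default 100).
#' @param window_bp recurrent-cluster window (default 50).
#' @param non_ssr_confidence minimum deltaGL for repetitive-context calls
#'   (default 20; the call is removed when deltaGL < 20).
#' @return data.frame of retained mutation calls, with attribute `audit`
#'   (counts removed per step).
#' @export
filterSnm <- function(calls, catalog = NULL, mask = NULL, min_depth = 10L,
                      pad = 100L, window_bp = 50L, non_ssr_confidence = 20) {
    checkCallTable(calls)
    audit <- c(input = nrow(calls))
    x <- calls[calls$called & !is.na(calls$is_mutant) & calls$is_mutant &
               nchar(calls$ancestral_allele) == nchar(calls$best_allele), ,
               drop = FALSE]
    audit["non_mutant_or_indel"] <- audit[["input"]] - nrow(x)
    if (!is.null(catalog) && length(catalog) && nrow(x)) {
        pts <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$pos, x$pos))
        GenomeInfoDb::seqlevels(pts) <-
            union(GenomeInfoDb::seqlevels(pts), GenomeInfoDb::seqlevels(catalog))
        inside <- GenomicRanges::countOverlaps(pts, catalog,
                                               ignore.strand = TRUE) > 0
        audit["in_ssr"] <- sum(inside)
        x <- x[!inside, , drop = FALSE]
    } else audit["in_ssr"] <- 0L
    n0 <- nrow(x)
    x <- applyMasks(x, mask, min_depth = min_depth, pad = pad)
    audit["region_or_depth"] <- n0 - nrow(x)
    if (!is.null(x$repetitive) && nrow(x)) {
        lowconf <- x$repetitive & !is.na(x$delta_gl) &
            x$delta_gl < non_ssr_confidence
        audit["low_confidence_repetitive"] <- sum(lowconf)
        x <- x[!lowconf, , drop = FALSE]
    } else audit["low_confidence_repetitive"] <- 0L
    cl <- clusterRecurrent(x, window_bp = window_bp)
    if (nrow(cl)) {
        bad <- unlist(cl$members[cl$recurrent])
        audit["recurrent"] <- length(bad)
        if (length(bad)) x <- x[-bad, , drop = FALSE]
    } else audit["recurrent"] <- 0L
    audit["retained"] <- nrow(x)
    rownames(x) <- NULL
    attr(x, "audit") <- audit
    x
}
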
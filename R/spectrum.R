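#' Classify an SSR mutation from its ancestral and derived alleles
#'
#' Length changes are insertions/deletions; the motif-copy change is the
#' length change divided by the motif length (signed, possibly fractional
#' for non-motif-multiple indels). Length-preserving changes are
#' substitutions, shown with a motif-copy change of 0.
#'
#' @param ancestral,derived allele strings at the same locus.
#' @param motif the locus motif.
#' @return list with `kind` (`"deletion"`, `"insertion"` or
#'   `"substitution"`), `delta_copies` and `delta_bp`.
#' @examples
#' classifyMutation(strrep("AC", 6), strrep("AC", 5), "AC")
#' @export
classifyMutation <- function(ancestral, derived, motif) {
    stopifnot(nzchar(ancestral), nzchar(derived), nzchar(motif))
    if (ancestral == derived)
        stop("ancestral and derived alleles are identical: not a mutation")
    delta_bp <- nchar(derived) - nchar(ancestral)
    if (delta_bp == 0L)
        return(list(kind = "substitution", delta_copies = 0, delta_bp = 0L))
    list(kind = if (delta_bp < 0) "deletion" else "insertion",
         delta_copies = delta_bp / nchar(motif), delta_bp = delta_bp)
}

#' Spectrum table of mutation events
#'
#' Counts events by kind x motif-copy change x motif length. The counts
#' partition the event set.
#'
#' @param events mutation-event data.frame (see [selectMutations()]).
#' @return data.frame with columns `motif_length`, `kind`, `delta_copies`,
#'   `n`.
#' @export
spectrumTable <- function(events) {
    if (!nrow(events))
        return(data.frame(motif_length = integer(0), kind = character(0),
                          delta_copies = numeric(0), n = integer(0)))
    agg <- aggregate(list(n = rep(1L, nrow(events))),
                     by = list(motif_length = events$motif_length,
                               kind = events$kind,
                               delta_copies = events$delta_copies),
                     FUN = sum)
    agg <- agg[order(agg$motif_length, agg$kind, agg$delta_copies), ,
               drop = FALSE]
    rownames(agg) <- NULL
    agg[, c("motif_length", "kind", "delta_copies", "n")]
}

#' Exact binomial test of deletion bias
#'
#' Two-sided exact binomial test of deletions versus insertions against an
#' even split, within one motif-length class.
#'
#' @param events mutation-event data.frame.
#' @param motif_length motif-length class to test (1-4); `NULL` pools all.
#' @return list with `n_deletions`, `n_insertions`, `p` (`NA` when the
#'   class has no indels).
#' @export
deletionBiasTest <- function(events, motif_length = NULL) {
    x <- events
    if (!is.null(motif_length)) x <- x[x$motif_length == motif_length, , drop = FALSE]
    n_del <- sum(x$kind == "deletion")
    n_ins <- sum(x$kind == "insertion")
    p <- if (n_del + n_ins == 0) NA_real_
         else binom.test(n_del, n_del + n_ins, p = 0.5)$p.value
    list(n_deletions = n_del, n_insertions = n_ins, p = p)
}

#' Genic enrichment of mutated loci
#'
#' Fisher's exact test (two-sided, minimum-likelihood convention) on the
#' 2x2 table of catalog loci: mutated vs not x genic vs not. Also reports
#' the same test restricted to trinucleotide / non-trinucleotide loci, and
#' within the non-trinucleotide class the comparison of loci with at least
#' `long_copy_threshold` copies versus shorter ones.
#'
#' @param events mutation-event data.frame (distinct mutated loci are
#'   counted once).
#' @param catalog an [SsrCatalog-class] with genic flags.
#' @param long_copy_threshold copy-number threshold for the length stratum
#'   (default 10).
#' @return list with elements `all`, `trinucleotide`, `non_trinucleotide`
#'   (each `proportion_genic`, `odds_ratio`, `p`, `n_mutated`) and
#'   `long_locus_genic_depletion` (genic odds of >= threshold-copy loci vs
#'   shorter, within non-trinucleotides).
#' @export
genicEnrichment <- function(events, catalog, long_copy_threshold = 10) {
    if (any(is.na(catalog$genic)))
        stop("catalog lacks genic annotation; run annotateGenic() first")
    ids <- locusIds(catalog)
    mutated <- ids %in% unique(events$locus_id)
    genic <- catalog$genic
    tri <- nchar(catalog$motif) == 3L

    one <- function(sel) {
        m <- mutated[sel]; g <- genic[sel]
        if (!any(m))
            return(list(proportion_genic = NA_real_, odds_ratio = NA_real_,
                        p = NA_real_, n_mutated = 0L))
        tab <- matrix(c(sum(m & g), sum(m & !g),
                        sum(!m & g), sum(!m & !g)), nrow = 2, byrow = TRUE)
        ft <- fisher.test(tab)
        list(proportion_genic = mean(g[m]),
             odds_ratio = unname(ft$estimate), p = ft$p.value,
             n_mutated = sum(m))
    }
    long <- catalog$copy_number >= long_copy_threshold
    depl <- {
        sel <- !tri
        tab <- matrix(c(sum(sel & long & genic), sum(sel & long & !genic),
                        sum(sel & !long & genic), sum(sel & !long & !genic)),
                      nrow = 2, byrow = TRUE)
        if (any(rowSums(tab) == 0)) list(odds_ratio = NA_real_, p = NA_real_)
        else {
            ft <- fisher.test(tab)
            list(odds_ratio = unname(ft$estimate), p = ft$p.value)
        }
    }
    list(all = one(rep(TRUE, length(catalog))),
         trinucleotide = one(tri),
         non_trinucleotide = one(!tri),
         long_locus_genic_depletion = depl)
}

#' False-negative-corrected mutation yield per strain
#'
#' Converts an observed (threshold-passing) mutation count into the
#' expected true per-strain yield given an estimated false-negative rate:
#' `n_observed / (n_strains * (1 - fn_rate))`.
#'
#' @param n_observed observed mutation count after filtering.
#' @param n_strains number of strains.
#' @param fn_rate false-negative rate of the filter (fraction of true
#'   mutations removed).
#' @return corrected mutations per strain.
#' @export
fnCorrectedYield <- function(n_observed, n_strains, fn_rate) {
    stopifnot(n_strains > 0, fn_rate >= 0, fn_rate < 1)
    n_observed / (n_strains * (1 - fn_rate))
}

#' Generations per mutation
#'
#' @param yield_per_strain mutations per strain over the experiment.
#' @param generations generations of mutation accumulation.
#' @return expected generations per mutation per haploid genome.
#' @export
generationsPerMutation <- function(yield_per_strain, generations) {
    stopifnot(yield_per_strain > 0)
    generations / yield_per_strain
}
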
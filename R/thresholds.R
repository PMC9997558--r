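# Join SSR calls to the locus properties used for grouping. Only called
# records with a defined deltaGL at cataloged loci participate.
.joinCalls <- function(calls, catalog) {
    checkCallTable(calls)
    ids <- locusIds(catalog)
    idx <- match(calls$locus_id, ids)
    ok <- !is.na(idx) & calls$called & !is.na(calls$delta_gl)
    df <- calls[ok, , drop = FALSE]
    idx <- idx[ok]
    df$motif_length <- nchar(catalog$motif)[idx]
    df$copy_number <- catalog$copy_number[idx]
    df$at_bin <- atBin(catalog$at_proportion[idx])
    df$length_bp <- GenomicRanges::width(catalog)[idx]
    df$at_proportion <- catalog$at_proportion[idx]
    df$genic <- catalog$genic[idx]
    df
}

#' Build property-grouped deltaGL thresholds
#'
#' Implements the property-dependent filtering strategy: calls are grouped
#' by motif length, A/T-proportion bin (<25%, 25-75%, >75%) and a copy
#' number window of +/- `window` motif copies around each focal copy number
#' present in the data. For every group spanning strictly more than
#' `min_loci - 1` distinct loci (default: >25, i.e. at least 26), the cutoff
#' is the lower empirical `quantile` of the pooled deltaGL values of all
#' calls in the group — mutant and non-mutant alike, pooled across strains.
#' Loci whose group is too small are unthresholdable and their calls are
#' dropped at application time.
#'
#' @param calls normalized call table (SSR calls carry `locus_id`).
#' @param catalog an [SsrCatalog-class].
#' @param quantile quantile in `[0, 0.95]` of deltaGL values to remove
#'   below (0 = keep everything).
#' @param window copy-number window half-width (default 2.5).
#' @param min_loci minimum distinct loci per group (default 26).
#' @return a [ThresholdTable-class].
#' @export
buildThresholds <- function(calls, catalog, quantile, window = 2.5,
                            min_loci = 26L) {
    stopifnot(quantile >= 0, quantile <= 0.95)
    df <- .joinCalls(calls, catalog)
    empty <- data.frame(motif_length = integer(0), at_bin = character(0),
                        copy_number = numeric(0), cutoff = numeric(0),
                        n_loci = integer(0), n_calls = integer(0))
    if (!nrow(df))
        return(new("ThresholdTable", table = empty, quantile = quantile,
                   window = window, min_loci = as.integer(min_loci)))
    rows <- list()
    for (sub in split(df, list(df$motif_length, df$at_bin), drop = TRUE)) {
        ord <- order(sub$copy_number)
        cn <- sub$copy_number[ord]
        dgl <- sub$delta_gl[ord]
        lid <- sub$locus_id[ord]
        for (c0 in unique(sub$copy_number)) {
            lo <- findInterval(c0 - window, cn, left.open = TRUE) + 1L
            hi <- findInterval(c0 + window, cn)
            n_loci <- length(unique(lid[lo:hi]))
            if (n_loci < min_loci) next
            rows[[length(rows) + 1L]] <- data.frame(
                motif_length = sub$motif_length[1],
                at_bin = as.character(sub$at_bin[1]),
                copy_number = c0,
                cutoff = lowerQuantile(dgl[lo:hi], quantile),
                n_loci = n_loci, n_calls = hi - lo + 1L,
                stringsAsFactors = FALSE)
        }
    }
    tab <- if (length(rows)) do.call(rbind, rows) else empty
    tab <- tab[order(tab$motif_length, tab$at_bin, tab$copy_number), ,
               drop = FALSE]
    rownames(tab) <- NULL
    new("ThresholdTable", table = tab, quantile = quantile, window = window,
        min_loci = as.integer(min_loci))
}

#' Apply a threshold table to SSR calls
#'
#' A call passes when its deltaGL is greater than or equal to the cutoff of
#' its own locus's group (motif length, A/T bin, focal copy number).
#' Thresholding is mutation-agnostic: the `is_mutant` label plays no role.
#' Calls at loci without a threshold (group too small) are dropped; their
#' count is reported in the `dropped` attribute.
#'
#' @param calls normalized call table.
#' @param catalog an [SsrCatalog-class] (the one thresholds were built on).
#' @param table a [ThresholdTable-class].
#' @return the passing calls (joined with locus properties), with attributes
#'   `dropped` (calls at unthresholdable loci) and `failed` (calls below
#'   cutoff).
#' @export
applyThresholds <- function(calls, catalog, table) {
    df <- .joinCalls(calls, catalog)
    tab <- thresholdTable(table)
    key <- paste(df$motif_length, as.character(df$at_bin), df$copy_number)
    tkey <- paste(tab$motif_length, tab$at_bin, tab$copy_number)
    cut <- tab$cutoff[match(key, tkey)]
    dropped <- sum(is.na(cut))
    pass <- !is.na(cut) & df$delta_gl >= cut
    out <- df[pass, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "dropped") <- dropped
    attr(out, "failed") <- sum(!pass, na.rm = TRUE) - dropped
    out
}

#' Stability scan over threshold quantiles
#'
#' Rebuilds and applies thresholds at each quantile of a grid, reporting the
#' apparent mutation rate (mutant fraction among passing calls). With
#' stutter-like false positives concentrated at low deltaGL, the curve
#' starts inflated at quantile 0 and flattens onto the true rate; the
#' reported `plateau` attribute is the longest run of consecutive grid
#' points whose rates all agree within 10% relative.
#'
#' @param calls normalized call table.
#' @param catalog an [SsrCatalog-class].
#' @param quantile_grid ascending quantiles (default 0 to 0.95 by 0.05).
#' @param window,min_loci see [buildThresholds()].
#' @return data.frame with columns `quantile`, `n_calls_pass`,
#'   `n_loci_pass`, `n_mutant_pass`, `mutant_rate`; attribute `plateau`
#'   gives the row indices of the detected plateau.
#' @export
stabilityScan <- function(calls, catalog,
                          quantile_grid = seq(0, 0.95, by = 0.05),
                          window = 2.5, min_loci = 26L) {
    stopifnot(!is.unsorted(quantile_grid))
    rows <- lapply(quantile_grid, function(q) {
        tab <- buildThresholds(calls, catalog, q, window = window,
                               min_loci = min_loci)
        pass <- applyThresholds(calls, catalog, tab)
        data.frame(quantile = q, n_calls_pass = nrow(pass),
                   n_loci_pass = length(unique(pass$locus_id)),
                   n_mutant_pass = sum(pass$is_mutant),
                   mutant_rate = if (nrow(pass)) mean(pass$is_mutant) else NA_real_)
    })
    out <- do.call(rbind, rows)
    attr(out, "plateau") <- .plateauRun(out$mutant_rate, rel_tol = 0.10)
    out
}

# Longest run of consecutive indices whose values pairwise agree within
# rel_tol relative difference (max/min - 1 < rel_tol). Ties -> earliest run.
.plateauRun <- function(x, rel_tol = 0.10) {
    n <- length(x)
    best <- integer(0)
    i <- 1L
    while (i <= n) {
        if (is.na(x[i])) { i <- i + 1L; next }
        j <- i
        mx <- x[i]; mn <- x[i]
        while (j < n && !is.na(x[j + 1L])) {
            mx2 <- max(mx, x[j + 1L]); mn2 <- min(mn, x[j + 1L])
            if (mn2 <= 0 || mx2 / mn2 - 1 >= rel_tol) break
            mx <- mx2; mn <- mn2; j <- j + 1L
        }
        if (j - i + 1L > length(best)) best <- i:j
        i <- i + 1L
    }
    best
}

#' Select threshold-passing SSR mutations
#'
#' Builds thresholds at the chosen quantile (default 35%, the low end of the
#' stable range, which preserves the most called loci), applies them, and
#' materializes the passing mutant calls as classified mutation events.
#'
#' @param calls normalized call table.
#' @param catalog an [SsrCatalog-class].
#' @param quantile threshold quantile (default 0.35).
#' @param window,min_loci see [buildThresholds()].
#' @return data.frame of mutation events: `strain`, `locus_id`, `kind`,
#'   `delta_copies`, `delta_bp`, `motif_length`, `genic`, plus the passing
#'   non-mutant call count in attribute `n_nonmutant_pass` and all passing
#'   calls in attribute `passing`.
#' @export
selectMutations <- function(calls, catalog, quantile = 0.35, window = 2.5,
                            min_loci = 26L) {
    tab <- buildThresholds(calls, catalog, quantile, window = window,
                           min_loci = min_loci)
    pass <- applyThresholds(calls, catalog, tab)
    mut <- pass[pass$is_mutant, , drop = FALSE]
    ids <- locusIds(catalog)
    events <- if (nrow(mut)) {
        cls <- mapply(function(a, d, m) classifyMutation(a, d, m),
                      mut$ancestral_allele, mut$best_allele,
                      catalog$motif[match(mut$locus_id, ids)],
                      SIMPLIFY = FALSE)
        data.frame(strain = mut$strain, locus_id = mut$locus_id,
                   kind = vapply(cls, `[[`, character(1), "kind"),
                   delta_copies = vapply(cls, `[[`, numeric(1), "delta_copies"),
                   delta_bp = vapply(cls, `[[`, numeric(1), "delta_bp"),
                   motif_length = mut$motif_length, genic = mut$genic,
                   stringsAsFactors = FALSE)
    } else {
        data.frame(strain = character(0), locus_id = character(0),
                   kind = character(0), delta_copies = numeric(0),
                   delta_bp = numeric(0), motif_length = integer(0),
                   genic = logical(0))
    }
    rownames(events) <- NULL
    attr(events, "n_nonmutant_pass") <- nrow(pass) - nrow(mut)
    attr(events, "passing") <- pass
    events
}
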
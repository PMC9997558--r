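# Shared internal helpers.

# Lower empirical quantile (inverse ECDF): smallest x with F(x) >= q.
# q == 0 is the degenerate no-filtering cutoff (-Inf): every call passes.
lowerQuantile <- function(x, q) {
    stopifnot(q >= 0, q <= 1)
    if (q == 0 || !length(x)) return(-Inf)
    xs <- sort(x)
    xs[max(1L, ceiling(q * length(xs)))]
}

# A/T-proportion bins: <25%, 25-75% (inclusive), >75%.
atBin <- function(at) {
    stopifnot(all(at >= -1e-9 & at <= 1 + 1e-9, na.rm = TRUE))
    out <- ifelse(at < 0.25, "low", ifelse(at <= 0.75, "mid", "high"))
    factor(out, levels = c("low", "mid", "high"))
}

# Is a motif primitive, i.e. not itself a repeat of a shorter motif?
isPrimitiveMotif <- function(motif) {
    vapply(motif, function(m) {
        k <- nchar(m)
        if (k == 1L) return(TRUE)
        for (d in seq_len(k - 1L)) {
            if (k %% d == 0L &&
                strrep(substr(m, 1L, d), k %/% d) == m) return(FALSE)
        }
        TRUE
    }, logical(1), USE.NAMES = FALSE)
}

# Rotate a motif so that it reads from `offset` bases into the original phase.
rotateMotif <- function(motif, offset) {
    k <- nchar(motif)
    off <- ((offset %% k) + k) %% k
    if (off == 0) return(motif)
    paste0(substr(motif, off + 1L, k), substr(motif, 1L, off))
}

# Bases of a perfect repeat of `motif` anchored (phase 0) at 0-based position
# `anchor`, over the 0-based half-open interval [from, to).
patternBases <- function(motif, anchor, from, to) {
    if (to <= from) return(character(0))
    pos <- seq.int(from, to - 1L)
    idx <- ((pos - anchor) %% nchar(motif)) + 1L
    strsplit(motif, "")[[1]][idx]
}

atFraction <- function(bases) {
    if (!length(bases)) return(NA_real_)
    mean(bases %in% c("A", "T"))
}

# Columns required in a normalized call table.
.callCols <- c("strain", "chrom", "pos", "locus_id", "ancestral_allele",
               "best_allele", "second_allele", "delta_gl", "depth",
               "alt_support", "is_mutant", "called")

checkCallTable <- function(calls) {
    miss <- setdiff(.callCols, colnames(calls))
    if (length(miss))
        stop("call table lacks column(s): ", paste(miss, collapse = ", "))
    invisible(calls)
}
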
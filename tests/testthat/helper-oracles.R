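# Independent oracles and small fixture builders shared across tests.
suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
})

# Brute-force maximal-perfect-repeat enumeration: test every (start, end,
# motif length) triple directly against the definition. Quadratic; for
# short sequences only.
bruteForceSSRs <- function(seq, min_copies = c(`1` = 4, `2` = 3, `3` = 3, `4` = 3)) {
    chars <- strsplit(seq, "")[[1]]
    n <- length(chars)
    is_rep <- function(s, e, k) {          # 0-based [s, e), period k
        if (e - s <= k) return(FALSE)
        all(chars[(s + k + 1):e] == chars[(s + 1):(e - k)]) &&
            !any(chars[(s + 1):e] == "N")
    }
    primitive <- function(s, k) {          # motif at s not a shorter repeat
        m <- paste(chars[(s + 1):(s + k)], collapse = "")
        for (d in seq_len(k - 1)) {
            if (k %% d == 0 && strrep(substr(m, 1, d), k / d) == m) return(FALSE)
        }
        TRUE
    }
    out <- list()
    for (k in as.integer(names(min_copies))) {
        for (s in 0:(n - k - 1)) {
            # extend to the maximal e with period k from this start
            e <- s + k
            while (e < n && chars[e + 1] == chars[e + 1 - k] &&
                   chars[e + 1] != "N" && chars[e + 1 - k] != "N") e <- e + 1
            if (e == s + k) next                       # no repetition at all
            if (!is_rep(s, e, k)) next                 # (N inside start copy)
            if (s > 0 && is_rep(s - 1, e, k)) next     # not left-maximal
            if ((e - s) / k < min_copies[[as.character(k)]]) next
            if (!primitive(s, k)) next
            out[[length(out) + 1L]] <- data.frame(
                start0 = s, end0 = e,
                motif = paste(chars[(s + 1):(s + k)], collapse = ""),
                copy_number = (e - s) / k)
        }
    }
    if (!length(out))
        return(data.frame(start0 = integer(0), end0 = integer(0),
                          motif = character(0), copy_number = numeric(0)))
    df <- unique(do.call(rbind, out))
    df <- df[order(df$start0, df$end0, df$motif), , drop = FALSE]
    rownames(df) <- NULL
    df
}

catalogToDf <- function(cat) {
    df <- data.frame(start0 = start(cat) - 1L, end0 = end(cat),
                     motif = cat$motif, copy_number = cat$copy_number)
    rownames(df) <- NULL
    df
}

randomSeq <- function(n, p_n = 0) {
    paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
                 prob = c(rep((1 - p_n) / 4, 4), p_n)), collapse = "")
}

# Minimal catalog: one locus per row of the given spec.
makeCatalog <- function(chrom, start0, motif, copies, genic = NA) {
    len <- round(copies * nchar(motif))
    gr <- GRanges(chrom, IRanges(start0 + 1L, start0 + len))
    gr$motif <- motif
    gr$copy_number <- len / nchar(motif)
    gr$at_proportion <- vapply(seq_along(motif), function(i)
        mean(strsplit(motif[i], "")[[1]] %in% c("A", "T")), numeric(1))
    gr$source <- "string-search"
    gr$genic <- genic
    SsrCatalog(gr)
}

# Minimal normalized call table with sensible defaults.
makeCalls <- function(strain, locus_id = NA_character_, chrom = "c",
                      pos = 1L, delta_gl = 5, depth = 50L,
                      alt_support = 0.05, is_mutant = FALSE, called = TRUE,
                      ancestral = "AAAA", best = NULL, second = "AAA") {
    if (is.null(best)) best <- ifelse(is_mutant, "AAA", ancestral)
    data.frame(strain = strain, chrom = chrom, pos = pos,
               locus_id = locus_id, ancestral_allele = ancestral,
               best_allele = best, second_allele = second,
               delta_gl = delta_gl, depth = depth, alt_support = alt_support,
               is_mutant = is_mutant, called = called,
               stringsAsFactors = FALSE)
}

# Exact two-sided Fisher p by full enumeration over tables with the
# observed margins (minimum-likelihood convention).
enumFisherP <- function(tab) {
    a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
    lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
    probs <- vapply(lo:hi, function(x) dhyper(x, c1, n - c1, r1), numeric(1))
    p_obs <- dhyper(a, c1, n - c1, r1)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided binomial p (minimum-likelihood convention) by enumeration.
enumBinomP <- function(x, n, p) {
    probs <- dbinom(0:n, n, p)
    sum(probs[probs <= probs[x + 1] * (1 + 1e-7)])
}
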
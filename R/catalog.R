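#' Find simple sequence repeats by exhaustive string search
#'
#' Scans a nucleotide sequence for all maximal perfect tandem repeats of
#' primitive motifs of length 1-4 bp, including a trailing partial motif copy
#' (so copy numbers may be fractional). A run qualifies when its copy number
#' reaches the per-motif-length minimum; by default homopolymers need 4
#' copies and di-/tri-/tetranucleotides 3. Runs touching an `N` base are
#' excluded. Hits of different motifs may overlap one another; overlap
#' resolution is the job of [mergeCatalogs()].
#'
#' @param sequence a single nucleotide string (or `DNAString`); only
#'   A/C/G/T/N are accepted.
#' @param min_copies named numeric, minimum copy number per motif length
#'   (names `"1"` to `"4"`).
#' @param max_copies optional cap on copy number (default `Inf`: no cap).
#' @param chrom sequence name used in the returned ranges.
#' @return an [SsrCatalog-class], sorted by start; `source` is
#'   `"string-search"`.
#' @examples
#' findSSRs("GAAAATC")            # one A homopolymer, 4 copies
#' findSSRs("ACACACA")            # motif AC, 3.5 copies
#' @export
findSSRs <- function(sequence,
                     min_copies = c(`1` = 4, `2` = 3, `3` = 3, `4` = 3),
                     max_copies = Inf, chrom = "seq") {
    if (methods::is(sequence, "XString")) sequence <- as.character(sequence)
    stopifnot(is.character(sequence), length(sequence) == 1L)
    sequence <- toupper(sequence)
    if (nzchar(sequence) && grepl("[^ACGTN]", sequence))
        stop("sequence contains characters other than A/C/G/T/N")
    n <- nchar(sequence)
    hits <- list()
    if (n >= 2L) {
        chars <- strsplit(sequence, "")[[1]]
        isN <- chars == "N"
        for (k in as.integer(names(min_copies))) {
            if (n < k + 1L) next
            m <- chars[seq_len(n - k)] == chars[seq.int(k + 1L, n)]
            m <- m & !isN[seq_len(n - k)] & !isN[seq.int(k + 1L, n)]
            r <- rle(m)
            run_end <- cumsum(r$lengths)
            run_start <- run_end - r$lengths + 1L
            for (j in which(r$values)) {
                i <- run_start[j]; L <- r$lengths[j]
                copies <- (L + k) / k
                if (copies < min_copies[[as.character(k)]] || copies > max_copies)
                    next
                motif <- substr(sequence, i, i + k - 1L)
                if (!isPrimitiveMotif(motif)) next
                bases <- chars[seq.int(i, i + L + k - 1L)]
                hits[[length(hits) + 1L]] <- data.frame(
                    start0 = i - 1L, end0 = i - 1L + L + k, motif = motif,
                    copy_number = copies, at_proportion = atFraction(bases),
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(hits)) {
        gr <- GenomicRanges::GRanges()
        gr$motif <- character(0); gr$copy_number <- numeric(0)
        gr$at_proportion <- numeric(0); gr$source <- character(0)
        return(SsrCatalog(gr))
    }
    df <- do.call(rbind, hits)
    df <- df[order(df$start0, df$end0, df$motif), , drop = FALSE]
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(df$start0 + 1L, df$end0))
    gr$motif <- df$motif
    gr$copy_number <- df$copy_number
    gr$at_proportion <- df$at_proportion
    gr$source <- "string-search"
    SsrCatalog(gr)
}

#' A/T proportion of catalog loci
#'
#' Fraction of locus bases that are A or T, recomputed from the reference
#' sequence (rather than the motif) so partial trailing copies are counted
#' exactly.
#'
#' @param catalog an [SsrCatalog-class].
#' @param sequences a named `DNAStringSet` (or named character vector of
#'   sequences) covering the catalog's chromosomes.
#' @return numeric vector in `[0, 1]`, parallel to `catalog`.
#' @export
atProportion <- function(catalog, sequences) {
    if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
    chroms <- as.character(GenomicRanges::seqnames(catalog))
    miss <- setdiff(unique(chroms), names(sequences))
    if (length(miss)) stop("sequence(s) missing: ", paste(miss, collapse = ", "))
    vapply(seq_along(catalog), function(i) {
        sub <- Biostrings::subseq(sequences[[chroms[i]]],
                                  GenomicRanges::start(catalog)[i],
                                  GenomicRanges::end(catalog)[i])
        f <- Biostrings::letterFrequency(sub, c("A", "T"))
        sum(f) / length(sub)
    }, numeric(1))
}

# Alignment score of assigning 0-based [from, to) to a perfect repeat of
# `motif` anchored at `anchor`: +2 per base belonging to a complete,
# in-phase motif copy inside the interval; partial-copy bases score 0
# (TRF default match weight).
.assignScore <- function(motif, anchor, from, to) {
    if (to <= from) return(0)
    k <- nchar(motif)
    n_full <- floor((to - anchor) / k) - ceiling((from - anchor) / k)
    2 * k * max(0, n_full)
}

# One resolved locus record from an anchored pattern piece.
.pieceRecord <- function(chrom, motif, anchor, from, to, source) {
    k <- nchar(motif)
    bases <- patternBases(motif, anchor, from, to)
    data.frame(chrom = chrom, start0 = from, end0 = to,
               motif = rotateMotif(motif, from - anchor),
               copy_number = (to - from) / k,
               at_proportion = atFraction(bases),
               source = source, stringsAsFactors = FALSE)
}

#' Merge string-search and external repeat catalogs
#'
#' Joins two locus lists into a single non-overlapping catalog. Identical
#' intervals with identical motifs collapse to one locus (`source =
#' "merged"` when both sources contributed). Overlapping loci with identical
#' motifs are unioned. Overlapping loci with different motifs are split at
#' the boundary that maximizes the summed alignment score of the two loci
#' (+2 per base in a complete motif copy, 0 for partial-copy bases; ties
#' break toward the longer left locus). Loci on different sequences never
#' interact.
#'
#' @param string_hits,external_hits [SsrCatalog-class] objects (either may be
#'   empty); each must be sorted by position within chromosome.
#' @return a non-overlapping [SsrCatalog-class].
#' @export
mergeCatalogs <- function(string_hits, external_hits = NULL) {
    toDf <- function(cat, default_source) {
        if (is.null(cat) || !length(cat)) return(NULL)
        df <- data.frame(chrom = as.character(GenomicRanges::seqnames(cat)),
                         start0 = GenomicRanges::start(cat) - 1L,
                         end0 = GenomicRanges::end(cat),
                         motif = cat$motif, copy_number = cat$copy_number,
                         at_proportion = cat$at_proportion,
                         source = if (!is.null(cat$source)) cat$source
                                  else default_source,
                         stringsAsFactors = FALSE)
        for (ch in unique(df$chrom)) {
            s <- df$start0[df$chrom == ch]
            if (is.unsorted(s)) stop("input catalog is not sorted by start")
        }
        df
    }
    df <- rbind(toDf(string_hits, "string-search"), toDf(external_hits, "external"))
    if (is.null(df) || !nrow(df)) {
        gr <- GenomicRanges::GRanges()
        gr$motif <- character(0); gr$copy_number <- numeric(0)
        gr$at_proportion <- numeric(0); gr$source <- character(0)
        return(SsrCatalog(gr))
    }
    # collapse identical (interval, motif) duplicates
    key <- paste(df$chrom, df$start0, df$end0, df$motif)
    dup_of_both <- key %in% key[duplicated(key)]
    df$source[dup_of_both] <- "merged"
    df <- df[!duplicated(key), , drop = FALSE]

    out <- lapply(split(df, df$chrom), .resolveChromOverlaps)
    df <- do.call(rbind, out)
    df <- df[order(df$chrom, df$start0, df$end0), , drop = FALSE]
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start0 + 1L, df$end0))
    gr$motif <- df$motif
    gr$copy_number <- df$copy_number
    gr$at_proportion <- df$at_proportion
    gr$source <- df$source
    SsrCatalog(gr)
}

# Sweep one chromosome's loci left to right, resolving overlaps pairwise.
.resolveChromOverlaps <- function(df) {
    df <- df[order(df$start0, df$end0), , drop = FALSE]
    # anchors remember the original phase of each locus through splits
    df$anchor <- df$start0
    acc <- df[1, , drop = FALSE]
    for (i in seq_len(nrow(df))[-1]) {
        cur <- df[i, , drop = FALSE]
        repeat {
            last <- acc[nrow(acc), , drop = FALSE]
            if (cur$start0 >= last$end0) { acc <- rbind(acc, cur); break }
            if (cur$motif == last$motif &&
                ((cur$anchor - last$anchor) %% nchar(cur$motif)) == 0) {
                # same motif, compatible phase: union
                acc$end0[nrow(acc)] <- max(last$end0, cur$end0)
                k <- nchar(last$motif)
                acc$copy_number[nrow(acc)] <- (acc$end0[nrow(acc)] - last$start0) / k
                acc$at_proportion[nrow(acc)] <-
                    atFraction(patternBases(last$motif, last$anchor,
                                            last$start0, acc$end0[nrow(acc)]))
                acc$source[nrow(acc)] <-
                    if (last$source == cur$source) last$source else "merged"
                break
            }
            pieces <- .splitOverlap(last, cur)
            acc <- acc[-nrow(acc), , drop = FALSE]
            if (nrow(pieces) == 1L) {
                if (nrow(acc)) { cur <- pieces[1, , drop = FALSE]; next }
                acc <- pieces; break
            }
            if (nrow(acc)) {
                acc <- rbind(acc, pieces[-nrow(pieces), , drop = FALSE])
                cur <- pieces[nrow(pieces), , drop = FALSE]
                # re-check: the new tail piece cannot overlap acc by construction
                acc <- rbind(acc, cur); break
            }
            acc <- pieces; break
        }
    }
    acc$anchor <- NULL
    acc
}

# Split two overlapping loci with different motifs; exhaustive search over
# every admissible boundary for the score-maximizing assignment.
.splitOverlap <- function(a, b) {
    stopifnot(a$start0 <= b$start0, b$start0 < a$end0)
    hi <- min(a$end0, b$end0)
    cand <- seq.int(b$start0, hi)
    score <- vapply(cand, function(s) {
        .assignScore(a$motif, a$anchor, a$start0, s) +
            .assignScore(b$motif, b$anchor, s, b$end0) +
            .assignScore(a$motif, a$anchor, max(s, b$end0), a$end0)
    }, numeric(1))
    split_at <- cand[max(which(score == max(score)))]  # tie -> longer left
    pieces <- list()
    if (split_at > a$start0)
        pieces <- c(pieces, list(.pieceRecordRow(a, a$start0, split_at)))
    if (b$end0 > split_at)
        pieces <- c(pieces, list(.pieceRecordRow(b, split_at, b$end0)))
    if (a$end0 > b$end0 && b$end0 > split_at)
        pieces <- c(pieces, list(.pieceRecordRow(a, b$end0, a$end0)))
    do.call(rbind, pieces)
}

.pieceRecordRow <- function(row, from, to) {
    rec <- .pieceRecord(row$chrom, row$motif, row$anchor, from, to, row$source)
    rec$anchor <- row$anchor
    rec
}

#' Annotate catalog loci as genic or intergenic
#'
#' A locus is genic when its midpoint lies inside any gene interval.
#' Chromosomes absent from the annotation yield `genic = FALSE` with a
#' warning.
#'
#' @param catalog an [SsrCatalog-class].
#' @param genes a `GRanges` of gene bodies (e.g. from
#'   `rtracklayer::import()` of a BED or GFF3 file).
#' @return the catalog with its `genic` column filled in.
#' @export
annotateGenic <- function(catalog, genes) {
    if (!length(catalog)) return(catalog)
    miss <- setdiff(unique(as.character(GenomicRanges::seqnames(catalog))),
                    GenomeInfoDb::seqlevels(genes))
    if (length(miss))
        warning("no gene annotation for sequence(s): ",
                paste(miss, collapse = ", "), "; loci there marked non-genic")
    # midpoint of 0-based [s0, e0) is floor((s0 + e0) / 2); +1 for 1-based
    s0 <- GenomicRanges::start(catalog) - 1L
    mid1 <- floor((s0 + GenomicRanges::end(catalog)) / 2) + 1L
    pts <- GenomicRanges::GRanges(GenomicRanges::seqnames(catalog),
                                  IRanges::IRanges(mid1, mid1))
    GenomeInfoDb::seqlevels(pts) <-
        union(GenomeInfoDb::seqlevels(pts), GenomeInfoDb::seqlevels(genes))
    hit <- GenomicRanges::countOverlaps(pts, genes, ignore.strand = TRUE) > 0
    catalog$genic <- hit
    catalog
}

#' Read a Tandem Repeats Finder .dat-style table
#'
#' Parses the whitespace-delimited locus rows of a TRF `.dat` file
#' (`Sequence:` headers give the chromosome; data rows are
#' `start end period copies consensus_size pct_match pct_indel score
#' pctA pctC pctG pctT entropy motif sequence`). TRF start/end are 1-based
#' inclusive. A/T proportion is taken from the composition columns. Motifs
#' are kept as given (lengths above 4 bp are allowed for external loci).
#'
#' @param path path to the `.dat` file.
#' @return an [SsrCatalog-class] with `source = "external"`.
#' @export
readTrfDat <- function(path) {
    lines <- readLines(path)
    chrom <- NA_character_
    rows <- list()
    for (ln in lines) {
        if (grepl("^Sequence:", ln)) {
            chrom <- sub("^Sequence:\\s*(\\S+).*$", "\\1", ln)
            next
        }
        if (!grepl("^[0-9]+\\s+[0-9]+\\s", ln)) next
        f <- strsplit(trimws(ln), "\\s+")[[1]]
        if (length(f) < 14L) next
        if (is.na(chrom)) stop("locus row before any 'Sequence:' header")
        rows[[length(rows) + 1L]] <- data.frame(
            chrom = chrom, start = as.integer(f[1]), end = as.integer(f[2]),
            motif = toupper(f[14]),
            at_proportion = (as.numeric(f[9]) + as.numeric(f[12])) / 100,
            stringsAsFactors = FALSE)
    }
    if (!length(rows)) {
        gr <- GenomicRanges::GRanges()
        gr$motif <- character(0); gr$copy_number <- numeric(0)
        gr$at_proportion <- numeric(0); gr$source <- character(0)
        return(SsrCatalog(gr))
    }
    df <- do.call(rbind, rows)
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
    gr$motif <- df$motif
    gr$copy_number <- GenomicRanges::width(gr) / nchar(df$motif)
    gr$at_proportion <- df$at_proportion
    gr$source <- "external"
    SsrCatalog(gr)
}

#' Build a catalog from reference sequences
#'
#' Convenience wrapper: string search on every sequence, merge with optional
#' external loci, annotate genic status.
#'
#' @param sequences named `DNAStringSet`, named character vector, or a path
#'   to a FASTA file.
#' @param external optional [SsrCatalog-class] of external loci.
#' @param genes optional `GRanges` of gene bodies.
#' @inheritParams findSSRs
#' @return an [SsrCatalog-class].
#' @export
buildCatalog <- function(sequences,
                         min_copies = c(`1` = 4, `2` = 3, `3` = 3, `4` = 3),
                         external = NULL, genes = NULL) {
    if (is.character(sequences) && length(sequences) == 1L &&
        file.exists(sequences))
        sequences <- Biostrings::readDNAStringSet(sequences)
    if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
    if (is.null(names(sequences)))
        stop("sequences must be named")
    names(sequences) <- sub("\\s.*$", "", names(sequences))
    hits <- lapply(names(sequences), function(ch)
        findSSRs(as.character(sequences[[ch]]), min_copies = min_copies,
                 chrom = ch))
    gr <- do.call(c, lapply(hits, function(h) methods::as(h, "GRanges")))
    cat <- mergeCatalogs(SsrCatalog(gr), external)
    if (!is.null(genes)) cat <- annotateGenic(cat, genes)
    cat
}

#' Write / read the catalog as BED-compatible TSV
#'
#' Columns: `chrom`, `start` (0-based), `end` (half-open), `motif`,
#' `copy_number`, `at_proportion`, `genic`, `source`.
#'
#' @param catalog an [SsrCatalog-class].
#' @param path output (or input) file path.
#' @return `writeCatalog` returns `path` invisibly; `readCatalog` returns an
#'   [SsrCatalog-class].
#' @export
writeCatalog <- function(catalog, path) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(catalog)),
                     start = GenomicRanges::start(catalog) - 1L,
                     end = GenomicRanges::end(catalog),
                     motif = catalog$motif,
                     copy_number = catalog$copy_number,
                     at_proportion = catalog$at_proportion,
                     genic = catalog$genic,
                     source = catalog$source, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeCatalog
#' @export
readCatalog <- function(path) {
    df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
    gr$motif <- df$motif
    gr$copy_number <- df$copy_number
    gr$at_proportion <- df$at_proportion
    gr$source <- df$source
    gr$genic <- df$genic
    SsrCatalog(gr)
}
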
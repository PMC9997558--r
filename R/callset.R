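#' Confidence gap between the two most likely alleles
#'
#' Computes deltaGL, the difference between the largest and second-largest
#' per-allele log10-scaled genotype likelihoods. This is the call-confidence
#' statistic thresholded per locus group by [buildThresholds()]. Phred-scaled
#' PL values must be converted to the log10 axis first (divide by -10; see
#' [readCallsVcf()]).
#'
#' @param likelihoods numeric vector of log10-scaled likelihoods, one per
#'   candidate allele. Order is irrelevant.
#' @return non-negative numeric; `NA` (with a warning) when fewer than two
#'   likelihoods are supplied, marking the call's confidence undefined so it
#'   is excluded from thresholding.
#' @examples
#' computeDeltaGL(c(-10, -13.2, -40.1))  # 3.2
#' @export
computeDeltaGL <- function(likelihoods) {
    likelihoods <- likelihoods[!is.na(likelihoods)]
    if (length(likelihoods) < 2L) {
        warning("fewer than two allele likelihoods; confidence undefined")
        return(NA_real_)
    }
    top <- sort(likelihoods, decreasing = TRUE)[1:2]
    max(0, top[1] - top[2])
}

#' Region and depth masking of calls
#'
#' Removes calls that fall (i) within `pad` bp (inclusive) of a telomere,
#' centromere or LTR interval, (ii) inside an rDNA or mitochondrial
#' interval, or (iii) below the minimum read depth. Uncalled records
#' (`called == FALSE`) are depth-filtered only if they carry a depth.
#'
#' @param calls a normalized call table (see [simulateCallSet()] /
#'   [readCallsVcf()] for the column contract).
#' @param mask `GRanges` with a `category` metadata column using values
#'   `telomere`, `centromere`, `LTR`, `rDNA`, `mitochondrion`; may be empty
#'   or `NULL`.
#' @param min_depth minimum read depth (default 10; calls at exactly 10 are
#'   kept).
#' @param pad buffer in bp around telomere/centromere/LTR intervals
#'   (default 100, inclusive).
#' @return the filtered call table, with an attribute `removed` giving
#'   counts per removal reason.
#' @export
applyMasks <- function(calls, mask = NULL, min_depth = 10L, pad = 100L) {
    checkCallTable(calls)
    removed <- c(region = 0L, depth = 0L)
    keep <- rep(TRUE, nrow(calls))
    if (!is.null(mask) && length(mask)) {
        if (is.null(mask$category)) stop("mask lacks a 'category' column")
        padded <- ifelse(mask$category %in% c("telomere", "centromere", "LTR"),
                         pad, 0L)
        mgr <- GenomicRanges::resize(mask,
                                     GenomicRanges::width(mask) + 2L * padded,
                                     fix = "center")
        pts <- GenomicRanges::GRanges(calls$chrom,
                                      IRanges::IRanges(calls$pos, calls$pos))
        GenomeInfoDb::seqlevels(pts) <-
            union(GenomeInfoDb::seqlevels(pts), GenomeInfoDb::seqlevels(mgr))
        hit <- GenomicRanges::countOverlaps(pts, mgr, ignore.strand = TRUE) > 0
        removed["region"] <- sum(hit)
        keep <- keep & !hit
    }
    shallow <- keep & !is.na(calls$depth) & calls$depth < min_depth
    removed["depth"] <- sum(shallow)
    keep <- keep & !shallow
    out <- calls[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "removed") <- removed
    out
}

#' Read per-strain calls from a multi-sample VCF
#'
#' Extracts a normalized call table from a VCF carrying per-sample genotype
#' likelihoods. `GL` (log10 scale) is used when present; otherwise `PL`
#' (phred scale) is converted to log10 by dividing by -10. The best allele
#' is the one with the highest likelihood; `delta_gl` is the gap to the
#' runner-up. `depth` comes from per-sample `DP`; `alt_support` is
#' `1 - AD[best]/sum(AD)` when allele depths are available, `NA` otherwise.
#' When `ancestor` names a sample, `is_mutant` flags samples whose best
#' allele differs from the ancestor's; the ancestor itself is dropped from
#' the table.
#'
#' @param path VCF file path.
#' @param ancestor optional ancestor sample name; default compares to REF.
#' @return a normalized call table (one row per sample x site).
#' @export
readCallsVcf <- function(path, ancestor = NULL) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
        stop("readCallsVcf requires the VariantAnnotation package")
    vcf <- VariantAnnotation::readVcf(path)
    gen <- VariantAnnotation::geno(vcf)
    samples <- colnames(vcf)
    n_site <- nrow(vcf)
    rr <- SummarizedExperiment::rowRanges(vcf)
    ref <- as.character(rr$REF)
    altL <- lapply(seq_len(n_site), function(i)
        as.character(rr$ALT[[i]]))
    glmat <- if ("GL" %in% names(gen)) gen$GL
             else if ("PL" %in% names(gen)) gen$PL else NULL
    phred <- !("GL" %in% names(gen)) && ("PL" %in% names(gen))
    if (is.null(glmat)) stop("VCF has neither GL nor PL genotype likelihoods")
    dp <- if ("DP" %in% names(gen)) gen$DP else NULL
    ad <- if ("AD" %in% names(gen)) gen$AD else NULL
    # genotype fields arrive as a 3D array (fixed Number) or list-matrix
    cell <- function(mat, i, s) {
        if (length(dim(mat)) == 3L) mat[i, s, ] else mat[i, s][[1]]
    }

    rows <- list()
    for (i in seq_len(n_site)) {
        alleles <- c(ref[i], altL[[i]])
        per_sample <- lapply(samples, function(s) {
            gl <- cell(glmat, i, s)
            if (phred) gl <- gl / -10
            gl <- suppressWarnings(as.numeric(gl))
            if (all(is.na(gl))) return(NULL)
            best <- which.max(gl)
            dgl <- if (sum(!is.na(gl)) >= 2L)
                suppressWarnings(computeDeltaGL(gl)) else NA_real_
            second <- if (sum(!is.na(gl)) >= 2L)
                order(gl, decreasing = TRUE)[2L] else NA_integer_
            support <- NA_real_
            if (!is.null(ad)) {
                adv <- suppressWarnings(as.numeric(cell(ad, i, s)))
                if (!all(is.na(adv)) && sum(adv, na.rm = TRUE) > 0)
                    support <- 1 - adv[best] / sum(adv, na.rm = TRUE)
            }
            list(best = best, second = second, dgl = dgl, support = support,
                 depth = if (!is.null(dp)) dp[i, s] else NA_integer_)
        })
        names(per_sample) <- samples
        anc_allele <- if (!is.null(ancestor) && !is.null(per_sample[[ancestor]]))
            alleles[per_sample[[ancestor]]$best] else ref[i]
        for (s in samples) {
            if (!is.null(ancestor) && s == ancestor) next
            ps <- per_sample[[s]]
            called <- !is.null(ps)
            rows[[length(rows) + 1L]] <- data.frame(
                strain = s,
                chrom = as.character(GenomicRanges::seqnames(rr))[i],
                pos = GenomicRanges::start(rr)[i],
                locus_id = NA_character_,
                ancestral_allele = anc_allele,
                best_allele = if (called) alleles[ps$best] else NA_character_,
                second_allele = if (called && !is.na(ps$second))
                    alleles[ps$second] else NA_character_,
                delta_gl = if (called) ps$dgl else NA_real_,
                depth = if (called) as.integer(ps$depth) else NA_integer_,
                alt_support = if (called) ps$support else NA_real_,
                is_mutant = if (called) alleles[ps$best] != anc_allele else NA,
                called = called, stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, rows)
}

#' Attach catalog locus ids to calls by position
#'
#' A call belongs to a locus when its position falls inside the locus
#' interval; `locus_id` is set accordingly (calls outside every locus keep
#' `NA`, marking them non-SSR).
#'
#' @param calls normalized call table.
#' @param catalog an [SsrCatalog-class].
#' @return the call table with `locus_id` filled in.
#' @export
assignLoci <- function(calls, catalog) {
    checkCallTable(calls)
    if (!length(catalog) || !nrow(calls)) return(calls)
    pts <- GenomicRanges::GRanges(calls$chrom,
                                  IRanges::IRanges(calls$pos, calls$pos))
    GenomeInfoDb::seqlevels(pts) <-
        union(GenomeInfoDb::seqlevels(pts), GenomeInfoDb::seqlevels(catalog))
    ov <- GenomicRanges::findOverlaps(pts, catalog, select = "first",
                                      ignore.strand = TRUE)
    ids <- locusIds(catalog)
    calls$locus_id <- ifelse(is.na(ov), calls$locus_id, ids[ov])
    calls
}

#' Read a category mask from BED files
#'
#' @param paths named character vector of BED file paths; names are the mask
#'   categories (`telomere`, `centromere`, `LTR`, `rDNA`, `mitochondrion`).
#' @return a `GRanges` with a `category` column.
#' @export
readMaskBed <- function(paths) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
        stop("readMaskBed requires the rtracklayer package")
    stopifnot(!is.null(names(paths)), all(nzchar(names(paths))))
    grs <- lapply(names(paths), function(cat) {
        gr <- rtracklayer::import(paths[[cat]], format = "BED")
        S4Vectors::mcols(gr) <- NULL
        gr$category <- cat
        gr
    })
    do.call(c, grs)
}

#' Write / read the normalized call table
#'
#' @param calls normalized call table.
#' @param path TSV file path.
#' @return `writeCallTable` returns `path` invisibly; `readCallTable`
#'   returns the table.
#' @export
writeCallTable <- function(calls, path) {
    checkCallTable(calls)
    write.table(calls[, .callCols], path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' @rdname writeCallTable
#' @export
readCallTable <- function(path) {
    df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                     na.strings = "NA")
    checkCallTable(df)
    df
}
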
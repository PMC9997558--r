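test_that("string search reproduces the worked examples", {
    g <- findSSRs("GAAAATC")
    expect_equal(length(g), 1L)
    expect_equal(start(g) - 1L, 1L)
    expect_equal(end(g), 5L)
    expect_equal(g$motif, "A")
    expect_equal(g$copy_number, 4)

    g2 <- findSSRs("ACACACA")
    expect_equal(length(g2), 1L)
    expect_equal(g2$motif, "AC")
    expect_equal(width(g2), 7L)
    expect_equal(g2$copy_number, 3.5)

    expect_equal(length(findSSRs("GAAAT")), 0L)   # 3 copies < 4
    expect_equal(length(findSSRs("")), 0L)
    expect_error(findSSRs("ACGU"), "A/C/G/T/N")
})

test_that("string search equals brute-force enumeration on random sequences", {
    set.seed(421)
    for (rep in 1:25) {
        s <- randomSeq(sample(80:400, 1), p_n = ifelse(rep %% 5 == 0, 0.02, 0))
        expect_equal(catalogToDf(findSSRs(s)), bruteForceSSRs(s), info = s)
    }
    # a couple of longer ones near the 2 kb scale
    for (rep in 1:2) {
        s <- randomSeq(2000)
        expect_equal(catalogToDf(findSSRs(s)), bruteForceSSRs(s))
    }
})

test_that("runs containing N are excluded and motifs are primitive", {
    expect_equal(length(findSSRs("AANAAA")), 0L)
    g <- findSSRs("ATATATAT")        # AT primitive; ATAT is not reported
    expect_equal(g$motif, "AT")
    expect_equal(length(g), 1L)
})

test_that("merging splits overlapping different-motif loci at the best-scoring boundary", {
    a <- makeCatalog("c", 0L, "A", 6)
    b <- makeCatalog("c", 4L, "AG", 3)
    m <- mergeCatalogs(a, b)
    df <- catalogToDf(m)
    # brute force over split points 4..6 with the same score
    score <- function(s) {
        left <- 2 * 1 * floor(s - 0)
        right <- 2 * 2 * max(0, floor((10 - 4) / 2) - ceiling((s - 4) / 2))
        left + right
    }
    best <- max(vapply(4:6, score, numeric(1)))
    split_at <- max((4:6)[vapply(4:6, score, numeric(1)) == best])
    expect_equal(df$end0[1], split_at)
    expect_equal(df$start0[2], split_at)
    # result is non-overlapping and phases are preserved
    expect_true(all(df$end0[-nrow(df)] <= df$start0[-1]))
    expect_equal(df$motif, c("A", "AG"))
})

test_that("merging is identity on disjoint loci and idempotent on duplicates", {
    a <- makeCatalog("c", c(0L, 50L), c("A", "AC"), c(5, 4))
    m <- mergeCatalogs(a, NULL)
    expect_equal(catalogToDf(m), catalogToDf(a))

    dup <- makeCatalog("c", 0L, "A", 5)
    m2 <- mergeCatalogs(a[1], dup)
    expect_equal(length(m2), 1L)
    expect_equal(m2$source, "merged")

    # loci on different chromosomes never interact
    x <- makeCatalog(c("c1", "c2"), c(0L, 0L), c("A", "A"), c(5, 5))
    expect_equal(length(mergeCatalogs(x, NULL)), 2L)
})

test_that("merged catalogs never contain overlapping loci (property)", {
    set.seed(99)
    for (rep in 1:20) {
        s <- randomSeq(600)
        raw <- findSSRs(s)
        # fabricate external loci overlapping the string hits
        n_ext <- 4
        st <- sample(0:560, n_ext)
        ext <- makeCatalog("seq", sort(st),
                           sample(c("A", "T", "AG", "AT", "CAA"), n_ext,
                                  replace = TRUE),
                           sample(3:6, n_ext, replace = TRUE))
        GenomeInfoDb::seqlevels(ext) <- "seq"
        m <- mergeCatalogs(raw, ext)
        df <- catalogToDf(m)
        ok <- !nrow(df) || all(df$end0[-nrow(df)] <= df$start0[-1])
        expect_true(ok, info = s)
        expect_true(validObject(m))
    }
})

test_that("catalogs are byte-identical across repeated construction", {
    s <- randomSeq(1500)
    expect_identical(findSSRs(s), findSSRs(s))
})

test_that("A/T proportion comes from the reference bases", {
    seqs <- c(chrA = "GGAAAATTTCCGCCG")
    cat1 <- makeCatalog("chrA", c(2L, 9L), c("A", "CCG"), c(4, 2))
    expect_equal(atProportion(cat1, seqs), c(1, 0))
    cat2 <- makeCatalog("chrA", 2L, "AT", 3)   # AAATTT window: mixed
    expect_equal(atProportion(cat2, seqs), 1)
})

test_that("genic annotation follows the midpoint rule", {
    genes <- GRanges("c", IRanges(1, 1000))
    inside <- makeCatalog("c", 100L, "A", 10)
    expect_true(annotateGenic(inside, genes)$genic)
    outside <- makeCatalog("c", 2000L, "A", 10)
    expect_warning(out <- annotateGenic(outside, genes), NA)
    expect_false(out$genic)
    # straddling loci: the gene covers 0-based [0, 1000)
    edge <- makeCatalog("c", 994L, "A", 10)   # midpoint 999 -> genic
    expect_true(annotateGenic(edge, genes)$genic)
    edge2 <- makeCatalog("c", 995L, "A", 10)  # midpoint 1000 -> not genic
    expect_false(annotateGenic(edge2, genes)$genic)
    # chromosome absent from annotation -> warning, non-genic
    other <- makeCatalog("chrX", 10L, "A", 10)
    w <- capture_warnings(res <- annotateGenic(other, genes))
    expect_true(any(grepl("chrX", w)))
    expect_false(res$genic)
})

test_that("TRF-style tables round-trip into the catalog", {
    dat <- file.path(tempdir(), "trf.dat")
    writeLines(c(
        "Tandem Repeats Finder Program",
        "Sequence: chr1",
        "Parameters: 2 7 7 80 10 3 500",
        "101 112 2 6.0 2 100 0 24 50 0 0 50 1.0 AT ATATATATATAT",
        "Sequence: chr2",
        "201 210 5 2.0 5 100 0 20 40 20 0 40 1.5 ACGTA ACGTAACGTA"),
        dat)
    cat1 <- readTrfDat(dat)
    expect_equal(length(cat1), 2L)
    expect_equal(as.character(seqnames(cat1)), c("chr1", "chr2"))
    expect_equal(start(cat1), c(101L, 201L))
    expect_equal(cat1$motif, c("AT", "ACGTA"))   # >4 bp allowed externally
    expect_equal(cat1$copy_number, c(6, 2))
    expect_equal(cat1$at_proportion, c(1, 0.8))
    expect_equal(cat1$source, c("external", "external"))
})

test_that("catalog TSV serialization round-trips with 0-based coordinates", {
    cat1 <- makeCatalog("c", c(5L, 30L), c("A", "ACG"), c(6, 3),
                        genic = c(TRUE, FALSE))
    p <- file.path(tempdir(), "cat.tsv")
    writeCatalog(cat1, p)
    tab <- read.table(p, header = TRUE, sep = "\t")
    expect_equal(tab$start, c(5L, 30L))          # 0-based on disk
    back <- readCatalog(p)
    expect_equal(catalogToDf(back), catalogToDf(cat1))
    expect_equal(back$genic, cat1$genic)
})

test_that("buildCatalog runs end to end on a small fasta", {
    fa <- file.path(tempdir(), "toy.fa")
    writeLines(c(">chrZ toy", "GGAAAAAGGGCACACACAGG"), fa)
    genes <- GRanges("chrZ", IRanges(1, 10))
    cat1 <- buildCatalog(fa, genes = genes)
    expect_s4_class(cat1, "SsrCatalog")
    expect_equal(cat1$motif, c("A", "CA"))   # motif phase as first seen
    expect_equal(cat1$genic, c(TRUE, FALSE))
})
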
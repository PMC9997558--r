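# A compact synthetic SSR call panel: loci in a handful of property groups,
# several strains, deltaGL under our control.
panelCatalog <- function(n_per_group = 30L) {
    # homopolymer A-rich at three copy numbers; dinucleotide mixed
    specs <- rbind(
        data.frame(motif = "A", copies = 5, n = n_per_group),
        data.frame(motif = "A", copies = 6, n = n_per_group),
        data.frame(motif = "A", copies = 12, n = n_per_group),
        data.frame(motif = "AG", copies = 4, n = n_per_group))
    motif <- rep(specs$motif, specs$n)
    copies <- rep(specs$copies, specs$n)
    len <- nchar(motif) * copies
    gap <- 25L
    start0 <- cumsum(c(0, head(len + gap, -1)))
    makeCatalog("c", as.integer(start0), motif, copies)
}

panelCalls <- function(catalog, strains = c("s1", "s2"), dgl_fun,
                       mutant_fun = function(n) rep(FALSE, n)) {
    ids <- locusIds(catalog)
    do.call(rbind, lapply(strains, function(s) {
        n <- length(ids)
        makeCalls(s, locus_id = ids, chrom = "c",
                  pos = start(catalog), delta_gl = dgl_fun(n),
                  is_mutant = mutant_fun(n))
    }))
}

test_that("group cutoffs equal the sorted-list quantile oracle", {
    set.seed(31)
    cat1 <- panelCatalog(30L)
    calls <- panelCalls(cat1, dgl_fun = function(n) round(rlnorm(n, 1, 0.7), 3))
    tab <- thresholdTable(buildThresholds(calls, cat1, quantile = 0.35))
    expect_gt(nrow(tab), 0)
    df <- merge(calls, data.frame(locus_id = locusIds(cat1),
                                  motif_length = nchar(cat1$motif),
                                  copy_number = cat1$copy_number))
    for (r in seq_len(nrow(tab))) {
        with_in <- df$motif_length == tab$motif_length[r] &
            abs(df$copy_number - tab$copy_number[r]) <= 2.5
        pool <- sort(df$delta_gl[with_in])
        expect_equal(tab$cutoff[r], pool[ceiling(0.35 * length(pool))],
                     info = paste("group row", r))
        expect_equal(tab$n_calls[r], length(pool))
    }
})

test_that("thresholds respect the >25-distinct-loci group minimum", {
    set.seed(32)
    cat_small <- panelCatalog(20L)     # A@12 group: 20 loci, isolated window
    calls <- panelCalls(cat_small, dgl_fun = function(n) rlnorm(n))
    tab <- thresholdTable(buildThresholds(calls, cat_small, 0.35))
    # the 12-copy homopolymer window [9.5, 14.5] spans only 20 loci -> absent
    expect_false(any(tab$motif_length == 1 & tab$copy_number == 12))
    # the 5- and 6-copy windows see each other: 40 distinct loci -> present
    expect_true(any(tab$motif_length == 1 & tab$copy_number == 5))
    # unthresholdable loci (the 12-copy A group and the 20-locus AG group)
    # are dropped at application, with a count
    pass <- applyThresholds(calls, cat_small,
                            buildThresholds(calls, cat_small, 0.35))
    expect_equal(attr(pass, "dropped"), 2L * 40L)
})

test_that("quantile 0 passes every call", {
    set.seed(33)
    cat1 <- panelCatalog(30L)
    calls <- panelCalls(cat1, dgl_fun = function(n) rlnorm(n))
    pass <- applyThresholds(calls, cat1, buildThresholds(calls, cat1, 0))
    expect_equal(nrow(pass), nrow(calls))
})

test_that("calls exactly at the cutoff pass (ties kept)", {
    cat1 <- panelCatalog(30L)
    calls <- panelCalls(cat1, dgl_fun = function(n) rep(c(1, 2), length.out = n))
    tab <- buildThresholds(calls, cat1, 0.5)
    pass <- applyThresholds(calls, cat1, tab)
    # every cutoff is 1 or 2; calls equal to their cutoff must pass
    tt <- thresholdTable(tab)
    expect_true(all(pass$delta_gl >= tt$cutoff[match(
        paste(pass$motif_length, pass$copy_number),
        paste(tt$motif_length, tt$copy_number))]))
    expect_true(any(pass$delta_gl == 1))   # ties at the 50% cutoff retained
})

test_that("passing sets nest monotonically in the quantile (property)", {
    set.seed(34)
    cat1 <- panelCatalog(40L)
    calls <- panelCalls(cat1, strains = paste0("s", 1:3),
                        dgl_fun = function(n) rlnorm(n, 1, 0.8))
    calls$.row <- seq_len(nrow(calls))
    prev <- NULL
    for (q in c(0, 0.2, 0.35, 0.6, 0.95)) {
        pass <- applyThresholds(calls, cat1, buildThresholds(calls, cat1, q))
        if (!is.null(prev)) expect_true(all(pass$.row %in% prev))
        prev <- pass$.row
    }
})

test_that("thresholds are mutation-agnostic (label permutation changes nothing)", {
    set.seed(35)
    cat1 <- panelCatalog(30L)
    calls <- panelCalls(cat1, strains = c("s1", "s2"),
                        dgl_fun = function(n) rlnorm(n, 1, 0.8),
                        mutant_fun = function(n) runif(n) < 0.2)
    calls$.row <- seq_len(nrow(calls))
    tab1 <- thresholdTable(buildThresholds(calls, cat1, 0.35))
    shuffled <- calls
    shuffled$is_mutant <- sample(shuffled$is_mutant)
    tab2 <- thresholdTable(buildThresholds(shuffled, cat1, 0.35))
    expect_equal(tab1, tab2)
    p1 <- applyThresholds(calls, cat1, buildThresholds(calls, cat1, 0.35))
    p2 <- applyThresholds(shuffled, cat1, buildThresholds(shuffled, cat1, 0.35))
    expect_equal(p1$.row, p2$.row)
    # and a mutant call with the same deltaGL/group as a non-mutant call
    # has the same fate by construction (same cutoff applied)
})

test_that("stability scan recovers the plateau at the simulated truth", {
    # stutter-correlated false positives at low deltaGL inflate the
    # quantile-0 estimate; the mid-range plateau sits on the truth
    set.seed(36)
    cfg <- simulationConfig(n_loci = 3000, n_msh3d = 10, n_wt = 0,
                            o_base = 5e-5, seed = 36)
    sim <- simulateCallSet(cfg)
    truth_rate <- nrow(sim$cohort$mutations) / (length(sim$catalog) * 10)
    scan <- stabilityScan(sim$calls, sim$catalog,
                          quantile_grid = seq(0, 0.6, by = 0.05))
    expect_gt(scan$mutant_rate[1], truth_rate)   # raw estimate inflated
    mid <- scan[scan$quantile >= 0.35 & scan$quantile <= 0.6, ]
    # binomial SE at each point; all mid-range estimates within 2 SE of truth
    se <- sqrt(truth_rate * (1 - truth_rate) / mid$n_calls_pass)
    expect_true(all(abs(mid$mutant_rate - truth_rate) < 2 * se +
                    0.15 * truth_rate))
    expect_gt(length(attr(scan, "plateau")), 1)
})

test_that("no-noise calls give a flat scan and exact truth recovery", {
    set.seed(37)
    cfg <- simulationConfig(n_loci = 1500, n_msh3d = 6, n_wt = 0,
                            o_base = 5e-5, fp_scale = 0, seed = 37)
    sim <- simulateCallSet(cfg)
    # with no false positives and quantile 0, selection recovers exactly
    # the truth restricted to called loci in thresholdable groups
    ev <- selectMutations(sim$calls, sim$catalog, quantile = 0)
    called <- sim$calls[sim$calls$called, ]
    tab <- thresholdTable(buildThresholds(sim$calls, sim$catalog, 0))
    cat_df <- data.frame(locus_id = locusIds(sim$catalog),
                         motif_length = nchar(sim$catalog$motif),
                         at_bin = as.character(ssrmut:::atBin(sim$catalog$at_proportion)),
                         copy_number = sim$catalog$copy_number)
    thresholdable <- cat_df$locus_id[
        paste(cat_df$motif_length, cat_df$at_bin, cat_df$copy_number) %in%
        paste(tab$motif_length, tab$at_bin, tab$copy_number)]
    truth_called <- merge(sim$cohort$mutations,
                          called[, c("strain", "locus_id")])
    truth_called <- truth_called[truth_called$locus_id %in% thresholdable, ]
    expect_equal(nrow(ev), nrow(truth_called))
    expect_setequal(paste(ev$strain, ev$locus_id),
                    paste(truth_called$strain, truth_called$locus_id))
    expect_equal(sort(ev$delta_copies), sort(truth_called$delta_copies))
})

test_that("rate estimates are robust to the grouping window half-width", {
    set.seed(38)
    cfg <- simulationConfig(n_loci = 3000, n_msh3d = 10, n_wt = 0,
                            o_base = 5e-5, seed = 38)
    sim <- simulateCallSet(cfg)
    rates <- vapply(c(1.5, 2.5, 3.5), function(w) {
        pass <- applyThresholds(sim$calls, sim$catalog,
                                buildThresholds(sim$calls, sim$catalog, 0.35,
                                                window = w))
        mean(pass$is_mutant)
    }, numeric(1))
    truth_rate <- nrow(sim$cohort$mutations) / (length(sim$catalog) * 10)
    se <- sqrt(truth_rate / (0.6 * nrow(sim$calls)))
    expect_lt(max(rates) - min(rates), 2 * se + 0.1 * truth_rate)
})

test_that("higher quantiles select fewer mutations", {
    set.seed(39)
    cfg <- simulationConfig(n_loci = 2000, n_msh3d = 8, n_wt = 0,
                            o_base = 5e-5, seed = 39)
    sim <- simulateCallSet(cfg)
    n35 <- nrow(selectMutations(sim$calls, sim$catalog, 0.35))
    n95 <- nrow(selectMutations(sim$calls, sim$catalog, 0.95))
    n0 <- nrow(selectMutations(sim$calls, sim$catalog, 0))
    expect_lte(n95, n35)
    expect_lte(n35, n0)
    # empty cohort
    empty <- sim$calls[0, ]
    expect_equal(nrow(selectMutations(empty, sim$catalog, 0.35)), 0L)
})
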
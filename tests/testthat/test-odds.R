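# Small deterministic outcome sets plus simulation-based recovery checks.

toyOutcomes <- function(n = 4000, seed = 51, o_base = 2e-4, theta_long = 20,
                        theta_motif = 1, theta_at = 1, p_long = 0.3) {
    set.seed(seed)
    len_short <- sample(4:7, n, replace = TRUE)
    len_long <- sample(8:20, n, replace = TRUE)
    long <- runif(n) < p_long
    length_bp <- ifelse(long, len_long, len_short)
    motif_length <- sample(1:3, n, replace = TRUE)
    at <- sample(c(0, 0.5, 1), n, replace = TRUE)
    odds <- length_bp * o_base * theta_long^long * theta_motif^motif_length *
        theta_at^at
    data.frame(strain = "s", locus_id = as.character(seq_len(n)),
               length_bp = length_bp, long = long,
               motif_length = motif_length, at_proportion = at,
               genotype = "msh3d",
               mutated = runif(n) < odds / (1 + odds))
}

test_that("the offset makes fitted odds proportional to locus length", {
    set.seed(52)
    n <- 60000
    length_bp <- sample(c(5L, 10L), n, replace = TRUE)
    o_base <- 3e-3
    out <- data.frame(strain = "s", locus_id = as.character(1:n),
                      length_bp = length_bp, long = FALSE,
                      motif_length = 1, at_proportion = 1,
                      genotype = "msh3d",
                      mutated = runif(n) < (length_bp * o_base) /
                          (1 + length_bp * o_base))
    fit <- fitOddsModel(out, terms = character(0))
    ob <- oddsEstimates(fit)[["(baseline)"]]
    expect_equal(ob, o_base, tolerance = 0.15)
    # predicted mutation probability follows n*O/(1+n*O) for both lengths
    for (nl in c(5, 10)) {
        pred <- nl * ob / (1 + nl * ob)
        expect_equal(mean(out$mutated[out$length_bp == nl]), pred,
                     tolerance = 0.1)
    }
})

test_that("MLEs agree with an independent glm fit", {
    out <- toyOutcomes(theta_motif = 0.8, theta_at = 0.5)
    fit <- fitOddsModel(out, terms = c("long", "motif_length", "at_proportion"))
    g <- stats::glm(mutated ~ long + motif_length + at_proportion +
                        offset(log(length_bp)),
                    family = binomial, data = out)
    expect_equal(unname(fit@coefficients), unname(coef(g)), tolerance = 1e-6)
    expect_equal(modelLogLik(fit), as.numeric(logLik(g)), tolerance = 1e-6)
})

test_that("likelihood-ratio tests follow the nested-model contract", {
    out <- toyOutcomes()
    full <- fitOddsModel(out, terms = c("long", "motif_length"))
    null <- fitOddsModel(out, terms = "long")
    base <- fitOddsModel(out, terms = character(0))

    same <- lrTest(full, full)
    expect_equal(same$statistic, 0)
    expect_equal(same$p, 1)

    lt <- lrTest(full, null)
    expect_equal(lt$df, 1L)
    # statistic equals twice the directly evaluated likelihood difference
    expect_equal(lt$statistic, 2 * (modelLogLik(full) - modelLogLik(null)))
    expect_equal(lt$p, pchisq(lt$statistic, 1, lower.tail = FALSE))

    # adding terms never decreases the maximized log-likelihood
    expect_gte(modelLogLik(null), modelLogLik(base))
    expect_gte(modelLogLik(full), modelLogLik(null))
    expect_error(lrTest(null, full), "nested")

    # the long effect is overwhelmingly significant at this effect size
    expect_lt(lrTest(null, base)$p, 1e-3)
})

test_that("profile intervals contain the MLE and match Wald asymptotically", {
    out <- toyOutcomes(n = 20000, theta_long = 8)
    fit <- fitOddsModel(out, terms = "long")
    ci <- profileCI(fit, "long")
    est <- oddsEstimates(fit)[["long"]]
    expect_true(ci["low"] < est && est < ci["high"])
    g <- stats::glm(mutated ~ long + offset(log(length_bp)),
                    family = binomial, data = out)
    wald <- exp(coef(g)["longTRUE"] +
                c(-1, 1) * 1.96 * sqrt(diag(vcov(g))["longTRUE"]))
    expect_equal(unname(log(ci)), unname(log(wald)), tolerance = 0.05)
    # and the MASS profile oracle where available
    skip_if_not_installed("MASS")
    mci <- suppressMessages(exp(confint(g, "longTRUE")))
    expect_equal(unname(ci), unname(mci), tolerance = 1e-3)
})

test_that("complete separation yields a one-sided profile interval", {
    # zero mutations in the wild-type genotype: the genotype coefficient
    # is unbounded above with a finite lower profile bound
    out <- toyOutcomes(n = 8000)
    wt <- out
    wt$strain <- "w"; wt$genotype <- "MSH3+"; wt$mutated <- FALSE
    both <- rbind(out, wt)
    both$genotype <- factor(both$genotype, levels = c("MSH3+", "msh3d"))
    fit <- fitOddsModel(both, terms = c("long", "genotype"))
    expect_false(fit@converged[["genotype"]])
    expect_true(fit@converged[["long"]])
    expect_equal(oddsEstimates(fit)[["genotype"]], Inf)
    ci <- profileCI(fit, "genotype")
    expect_true(is.finite(ci["low"]) && ci["low"] > 1)
    expect_equal(unname(ci["high"]), Inf)
    # non-separated terms still estimated sensibly
    expect_equal(log(oddsEstimates(fit)[["long"]]), log(20), tolerance = 0.5)
})

test_that("separation detection is exact on a constructed stratum", {
    out <- toyOutcomes(n = 3000)
    out$mutated[out$long] <- FALSE            # no mutations among long loci
    out$mutated[!out$long][1:40] <- TRUE
    fit <- fitOddsModel(out, terms = "long")
    expect_false(fit@converged[["long"]])
    expect_equal(oddsEstimates(fit)[["long"]], 0)   # diverges downward
    ci <- profileCI(fit, "long")
    expect_equal(unname(ci["low"]), 0)
    expect_true(is.finite(ci["high"]))
})

test_that("outcome assembly maps calls, genotypes and the 8-bp long rule", {
    cat1 <- makeCatalog("c", c(0L, 50L, 100L), c("A", "A", "AC"), c(7, 8, 5))
    ids <- locusIds(cat1)
    passing <- rbind(
        makeCalls("a", locus_id = ids, chrom = "c", pos = start(cat1),
                  is_mutant = c(FALSE, TRUE, FALSE)),
        makeCalls("b", locus_id = ids[1:2], chrom = "c", pos = start(cat1)[1:2]))
    gt <- data.frame(strain = c("a", "b"), genotype = c("msh3d", "msh3d"))
    out <- assembleOutcomes(passing, cat1, gt)
    expect_equal(nrow(out), 5L)
    expect_equal(out$long, c(FALSE, TRUE, TRUE, FALSE, TRUE))  # 7bp/8bp/10bp
    expect_equal(sum(out$mutated), 1L)
    # a strain with no passing loci contributes nothing; locus mutated in
    # one strain is unmutated in the other
    expect_equal(sum(out$strain == "b" & out$mutated), 0L)
    # inconsistent event at an uncalled locus-strain errors
    ev <- data.frame(strain = "b", locus_id = ids[3])
    expect_error(assembleOutcomes(passing, cat1, gt, events = ev), "uncalled")
})

test_that("profile CIs cover the generating long-SSR effect (recovery)", {
    # 100 fast replicates at reduced scale: 3000 loci x 10 strains
    set.seed(57)
    covered <- logical(100)
    for (i in 1:100) {
        cfg <- simulationConfig(n_loci = 3000, n_msh3d = 10, n_wt = 0,
                                o_base = 4e-5, seed = 5700 + i)
        cat1 <- generateCatalog(cfg)
        coh <- simulateCohort(cat1, cfg)
        out <- outcomesFromTruth(cat1, coh, genotype = "msh3d")
        fit <- fitOddsModel(out, terms = c("long", "motif_length",
                                           "at_proportion"))
        ci <- profileCI(fit, "long")
        covered[i] <- ci["low"] <= 33 && 33 <= ci["high"]
    }
    expect_gte(mean(covered), 0.90)
})
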
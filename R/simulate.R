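#' SimulationConfig: study conditions for the bundled simulator
#'
#' Holds every tunable of the synthetic catalog / cohort / call-set
#' generator. The defaults are the bundled preset: a mutation-accumulation
#' cohort of 34 mutant (msh3-deleted) and 5 wild-type haploid strains over
#' 200 generations; per-bp mutation odds following
#' `odds = n * O_base * theta_long^long * theta_motif^motif_len *
#' theta_AT^at` with `theta_long = 33`, `theta_motif = 0.9`,
#' `theta_AT = 0.5` and an effectively separating genotype effect; a
#' deletion-dominant single-copy indel spectrum; per-strain callability
#' centered on 0.63; and a log-normal deltaGL model whose location
#' increases with motif length and A/T proportion and decreases with copy
#' number, with stutter-like false positives drawn from the same family
#' shifted downward and occurring in proportion to the locus's mutation
#' odds. The default locus count (15000) yields roughly 5e5 mutant-genotype
#' locus-strain outcomes per cohort.
#'
#' @slot n_loci number of catalog loci.
#' @slot motif_length_probs probabilities of motif lengths 1-4.
#' @slot min_copies minimum copy number per motif length.
#' @slot copy_geom_p geometric tail parameter of copy counts per motif
#'   length.
#' @slot partial_prob probability a locus (motif length >1) carries a
#'   partial trailing copy.
#' @slot at_rich_prob probability an individual motif base is A or T.
#' @slot genic_tri,genic_nontri genic probability for trinucleotide and
#'   other loci.
#' @slot genic_long_factor multiplier on the genic probability of
#'   non-trinucleotide loci with at least `long_copy_threshold` copies.
#' @slot long_copy_threshold copy-number threshold for the genic depletion.
#' @slot n_msh3d,n_wt strains per genotype.
#' @slot generations reporting metadata only (mutations are drawn per
#'   cohort, not per transfer).
#' @slot o_base baseline per-bp mutation odds in the mutant genotype.
#' @slot theta_long,theta_motif,theta_at,theta_genotype odds multipliers;
#'   `theta_genotype` divides the mutant odds to give wild-type odds.
#' @slot long_cutoff_bp length (bp) at which a locus counts as long.
#' @slot substitution_prob fraction of mutations that are in-SSR
#'   substitutions.
#' @slot p_deletion probability an indel is a deletion.
#' @slot delta_copies_probs probabilities of |delta copies| = 1, 2, 3.
#' @slot callability_shape1,callability_shape2 Beta parameters of
#'   per-strain callability.
#' @slot depth_mu,depth_size negative-binomial read-depth model.
#' @slot dgl_base,dgl_motif,dgl_at,dgl_copy,dgl_sd log-normal deltaGL
#'   location/scale model (location = base + motif*(k-1) + at*AT -
#'   copy*copies).
#' @slot fp_shift downward location shift of false-positive deltaGL.
#' @slot fp_scale,fp_cap false-positive probability per non-mutated called
#'   locus: `min(fp_scale * p_mut, fp_cap)`.
#' @slot seed integer RNG seed (NA = use the current RNG state).
#' @export
setClass("SimulationConfig", representation(
    n_loci = "numeric", motif_length_probs = "numeric", min_copies = "numeric",
    copy_geom_p = "numeric", partial_prob = "numeric", at_rich_prob = "numeric",
    genic_tri = "numeric", genic_nontri = "numeric",
    genic_long_factor = "numeric", long_copy_threshold = "numeric",
    n_msh3d = "numeric", n_wt = "numeric", generations = "numeric",
    o_base = "numeric", theta_long = "numeric", theta_motif = "numeric",
    theta_at = "numeric", theta_genotype = "numeric", long_cutoff_bp = "numeric",
    substitution_prob = "numeric", p_deletion = "numeric",
    delta_copies_probs = "numeric",
    callability_shape1 = "numeric", callability_shape2 = "numeric",
    depth_mu = "numeric", depth_size = "numeric",
    dgl_base = "numeric", dgl_motif = "numeric", dgl_at = "numeric",
    dgl_copy = "numeric", dgl_sd = "numeric", fp_shift = "numeric",
    fp_scale = "numeric", fp_cap = "numeric", seed = "numeric"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@n_loci < 1) msg <- c(msg, "n_loci must be at least 1")
    p <- object@motif_length_probs
    if (length(p) != 4 || any(p < 0) || abs(sum(p) - 1) > 1e-8)
        msg <- c(msg, "motif_length_probs must be 4 non-negative values summing to 1")
    for (nm in c("partial_prob", "at_rich_prob", "genic_tri", "genic_nontri",
                 "substitution_prob", "p_deletion", "fp_cap"))
        if (methods::slot(object, nm) < 0 || methods::slot(object, nm) > 1)
            msg <- c(msg, paste(nm, "must lie in [0, 1]"))
    dp <- object@delta_copies_probs
    if (length(dp) != 3 || abs(sum(dp) - 1) > 1e-8)
        msg <- c(msg, "delta_copies_probs must be 3 values summing to 1")
    if (object@o_base <= 0 || object@theta_long <= 0 || object@theta_motif <= 0 ||
        object@theta_at <= 0 || object@theta_genotype <= 0)
        msg <- c(msg, "odds parameters must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' @param ... any [SimulationConfig-class] slot, overriding the preset
#'   default.
#' @return a validated `SimulationConfig`.
#' @examples
#' cfg <- simulationConfig(n_loci = 500, seed = 1)
#' @export
simulationConfig <- function(...) {
    defaults <- list(
        n_loci = 15000, motif_length_probs = c(0.86, 0.07, 0.05, 0.02),
        min_copies = c(4, 3, 3, 3), copy_geom_p = c(0.55, 0.6, 0.65, 0.7),
        partial_prob = 0.3, at_rich_prob = 0.62,
        genic_tri = 0.80, genic_nontri = 0.72, genic_long_factor = 0.35,
        long_copy_threshold = 10,
        n_msh3d = 34, n_wt = 5, generations = 200,
        o_base = 7e-6, theta_long = 33, theta_motif = 0.9, theta_at = 0.5,
        theta_genotype = 1.7e7, long_cutoff_bp = 8,
        substitution_prob = 0.1, p_deletion = 0.75,
        delta_copies_probs = c(0.88, 0.08, 0.04),
        callability_shape1 = 12.6, callability_shape2 = 7.4,
        depth_mu = 62, depth_size = 8,
        dgl_base = 1.0, dgl_motif = 0.45, dgl_at = 0.5, dgl_copy = 0.08,
        dgl_sd = 0.6, fp_shift = 1.5, fp_scale = 2, fp_cap = 0.25,
        seed = NA_real_)
    over <- list(...)
    bad <- setdiff(names(over), names(defaults))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    args <- utils::modifyList(defaults, over)
    do.call(methods::new, c(list("SimulationConfig"), args))
}

.maybeSeed <- function(config, offset) {
    if (!is.na(config@seed)) set.seed(as.integer(config@seed) + offset)
}

# Draw one primitive motif of length k.
.drawMotif <- function(k, at_prob) {
    p <- c(at_prob / 2, at_prob / 2, (1 - at_prob) / 2, (1 - at_prob) / 2)
    repeat {
        m <- paste(sample(c("A", "T", "C", "G"), k, replace = TRUE, prob = p),
                   collapse = "")
        if (isPrimitiveMotif(m)) return(m)
    }
}

#' Generate a synthetic SSR catalog
#'
#' Loci are laid end to end (with random gaps) on one synthetic
#' chromosome; each locus draws a motif length, a primitive motif with
#' A/T-biased composition, a geometric-tailed copy number (with optional
#' partial trailing copy), and a genic flag from the trinucleotide-enriched,
#' length-depleted genic model.
#'
#' @param config a [SimulationConfig-class].
#' @return an [SsrCatalog-class]; the per-locus genic probability used by
#'   the generator is attached as metadata column `genic_prob` for
#'   calibration checks.
#' @export
generateCatalog <- function(config) {
    methods::validObject(config)
    .maybeSeed(config, 0L)
    n <- as.integer(config@n_loci)
    k <- sample(1:4, n, replace = TRUE, prob = config@motif_length_probs)
    base_copies <- config@min_copies[k] +
        rgeom(n, config@copy_geom_p[k])
    extra <- ifelse(k > 1 & runif(n) < config@partial_prob,
                    vapply(k, function(kk) if (kk > 1) sample(kk - 1L, 1L) else 0L,
                           integer(1)),
                    0L)
    len <- as.integer(base_copies * k + extra)
    copies <- len / k
    motif <- vapply(k, .drawMotif, character(1), at_prob = config@at_rich_prob)
    at <- vapply(seq_len(n), function(i)
        atFraction(patternBases(motif[i], 0L, 0L, len[i])), numeric(1))
    gap <- 30L + rgeom(n, 0.05)
    start0 <- cumsum(c(0L, len[-n] + gap[-n])) + gap[1]
    tri <- k == 3L
    gp <- ifelse(tri, config@genic_tri, config@genic_nontri)
    gp <- ifelse(!tri & copies >= config@long_copy_threshold,
                 gp * config@genic_long_factor, gp)
    genic <- runif(n) < gp
    gr <- GenomicRanges::GRanges("sim1", IRanges::IRanges(start0 + 1L,
                                                          start0 + len))
    gr$motif <- motif
    gr$copy_number <- copies
    gr$at_proportion <- at
    gr$source <- "string-search"
    gr$genic <- genic
    gr$genic_prob <- gp
    SsrCatalog(gr)
}

#' Per-locus mutation probability under the odds model
#'
#' @param catalog an [SsrCatalog-class].
#' @param config a [SimulationConfig-class].
#' @param genotype `"msh3d"` or `"MSH3+"`.
#' @return numeric vector of per-locus mutation probabilities.
#' @export
mutationProbability <- function(catalog, config, genotype = "msh3d") {
    len <- GenomicRanges::width(catalog)
    k <- nchar(catalog$motif)
    eta <- log(len) + log(config@o_base) +
        (len >= config@long_cutoff_bp) * log(config@theta_long) +
        k * log(config@theta_motif) +
        catalog$at_proportion * log(config@theta_at)
    if (genotype != "msh3d") eta <- eta - log(config@theta_genotype)
    1 / (1 + exp(-eta))
}

#' Simulate a mutation-accumulation cohort
#'
#' Each locus x strain mutates independently with the odds-model
#' probability for the strain's genotype; mutated loci draw a mutation kind
#' and motif-copy change from the configured (deletion-dominant,
#' single-copy-dominant) spectrum. Deletions never remove the final motif
#' copy. `generations` is reporting metadata only: the cohort is drawn in
#' one step, not transfer by transfer.
#'
#' @param catalog an [SsrCatalog-class].
#' @param config a [SimulationConfig-class].
#' @return list with `strains` (data.frame `strain`, `genotype`,
#'   `callability`), `mutations` (data.frame `strain`, `locus_id`, `kind`,
#'   `delta_copies`, `delta_bp`) and `generations`.
#' @export
simulateCohort <- function(catalog, config) {
    methods::validObject(config)
    .maybeSeed(config, 1L)
    strains <- data.frame(
        strain = c(sprintf("A%02d", seq_len(config@n_msh3d)),
                   sprintf("W%02d", seq_len(config@n_wt))),
        genotype = factor(rep(c("msh3d", "MSH3+"),
                              c(config@n_msh3d, config@n_wt)),
                          levels = c("MSH3+", "msh3d")),
        stringsAsFactors = FALSE)
    strains$callability <- rbeta(nrow(strains), config@callability_shape1,
                                 config@callability_shape2)
    p_mut <- list(msh3d = mutationProbability(catalog, config, "msh3d"),
                  `MSH3+` = mutationProbability(catalog, config, "MSH3+"))
    ids <- locusIds(catalog)
    k <- nchar(catalog$motif)
    copies <- catalog$copy_number
    muts <- list()
    for (s in seq_len(nrow(strains))) {
        p <- p_mut[[as.character(strains$genotype[s])]]
        hit <- which(runif(length(catalog)) < p)
        if (!length(hit)) next
        is_sub <- runif(length(hit)) < config@substitution_prob
        n_ind <- sum(!is_sub)
        mag <- sample(1:3, n_ind, replace = TRUE,
                      prob = config@delta_copies_probs)
        sign_del <- ifelse(runif(n_ind) < config@p_deletion, -1L, 1L)
        # a deletion may not remove the last motif copy
        max_del <- pmax(1L, ceiling(copies[hit][!is_sub]) - 1L)
        mag <- ifelse(sign_del < 0, pmin(mag, max_del), mag)
        dc <- numeric(length(hit))
        dc[!is_sub] <- sign_del * mag
        kind <- ifelse(is_sub, "substitution",
                       ifelse(dc < 0, "deletion", "insertion"))
        muts[[length(muts) + 1L]] <- data.frame(
            strain = strains$strain[s], locus_id = ids[hit], kind = kind,
            delta_copies = dc, delta_bp = as.integer(dc * k[hit]),
            stringsAsFactors = FALSE)
    }
    mutations <- if (length(muts)) do.call(rbind, muts)
        else data.frame(strain = character(0), locus_id = character(0),
                        kind = character(0), delta_copies = numeric(0),
                        delta_bp = integer(0))
    list(strains = strains, mutations = mutations,
         generations = config@generations)
}

#' Locus-strain outcome records straight from simulated truth
#'
#' Expands a simulated cohort into the outcome table the odds model
#' consumes, one record per locus x strain (all loci counted as called;
#' use [emitCalls()] + the filtering path for the noisy route).
#'
#' @param catalog an [SsrCatalog-class].
#' @param cohort result of [simulateCohort()].
#' @param genotype optional subset: keep only strains of this genotype.
#' @param long_cutoff_bp see [assembleOutcomes()].
#' @return outcome data.frame (see [assembleOutcomes()]).
#' @export
outcomesFromTruth <- function(catalog, cohort, genotype = NULL,
                              long_cutoff_bp = 8L) {
    strains <- cohort$strains
    if (!is.null(genotype))
        strains <- strains[strains$genotype == genotype, , drop = FALSE]
    ids <- locusIds(catalog)
    nl <- length(catalog); ns <- nrow(strains)
    out <- data.frame(
        strain = rep(strains$strain, each = nl),
        locus_id = rep(ids, ns),
        length_bp = rep(GenomicRanges::width(catalog), ns),
        motif_length = rep(nchar(catalog$motif), ns),
        at_proportion = rep(catalog$at_proportion, ns),
        genotype = rep(strains$genotype, each = nl),
        stringsAsFactors = FALSE)
    out$long <- out$length_bp >= long_cutoff_bp
    out$mutated <- paste(out$strain, out$locus_id) %in%
        paste(cohort$mutations$strain, cohort$mutations$locus_id)
    out[, c("strain", "locus_id", "length_bp", "long", "motif_length",
            "at_proportion", "genotype", "mutated")]
}

# Reference allele strings for every locus, plus the one-copy-shorter
# synthetic alternative used for non-mutant calls.
.locusAlleles <- function(catalog) {
    k <- nchar(catalog$motif)
    len <- GenomicRanges::width(catalog)
    anc <- vapply(seq_along(catalog), function(i)
        paste(patternBases(catalog$motif[i], 0L, 0L, len[i]), collapse = ""),
        character(1))
    shorter <- vapply(seq_along(catalog), function(i)
        substr(anc[i], 1L, max(1L, len[i] - k[i])), character(1))
    list(ancestral = anc, shorter = shorter)
}

# Derived allele for a mutation event at locus i.
.derivedAllele <- function(anc, motif, kind, delta_bp) {
    if (kind == "substitution") {
        pos <- 1L
        old <- substr(anc, pos, pos)
        newb <- setdiff(c("A", "C", "G", "T"), old)[1]
        return(paste0(newb, substr(anc, 2L, nchar(anc))))
    }
    len <- nchar(anc)
    if (delta_bp < 0) return(substr(anc, 1L, len + delta_bp))
    extra <- patternBases(motif, 0L, 0L, delta_bp)
    paste0(anc, paste(extra, collapse = ""))
}

#' Emit a noisy per-strain call set from simulated truth
#'
#' Every locus x strain yields one record: uncalled (per the strain's
#' callability) or called with a read depth and a deltaGL drawn from the
#' group-dependent log-normal model. True mutations are emitted as mutant
#' calls with their simulated derived allele; non-mutated loci acquire
#' stutter-like false-positive mutant calls (typically one motif copy
#' short) with probability proportional to the locus's mutation odds and a
#' deltaGL drawn from the same family shifted low. Remaining calls are
#' clean non-mutant records whose runner-up allele is the one-motif-copy-
#' shorter synthetic alternative.
#'
#' @param catalog an [SsrCatalog-class].
#' @param cohort result of [simulateCohort()].
#' @param config a [SimulationConfig-class].
#' @return list with `calls` (normalized call table; no truth columns) and
#'   `labels` (data.frame `strain`, `locus_id`, `label` in
#'   `true_positive` / `false_positive` for every emitted mutant call).
#' @export
emitCalls <- function(catalog, cohort, config) {
    methods::validObject(config)
    .maybeSeed(config, 2L)
    ids <- locusIds(catalog)
    nl <- length(catalog)
    k <- nchar(catalog$motif)
    alle <- .locusAlleles(catalog)
    meanlog <- config@dgl_base + config@dgl_motif * (k - 1) +
        config@dgl_at * catalog$at_proportion -
        config@dgl_copy * catalog$copy_number
    p_fp <- pmin(config@fp_scale *
                 mutationProbability(catalog, config, "msh3d"), config@fp_cap)
    chrom <- as.character(GenomicRanges::seqnames(catalog))
    pos <- GenomicRanges::start(catalog)
    mut_key <- paste(cohort$mutations$strain, cohort$mutations$locus_id)

    out <- vector("list", nrow(cohort$strains))
    labels <- list()
    for (s in seq_len(nrow(cohort$strains))) {
        st <- cohort$strains$strain[s]
        called <- runif(nl) < cohort$strains$callability[s]
        depth <- rnbinom(nl, size = config@depth_size, mu = config@depth_mu)
        midx <- match(paste(st, ids), mut_key)
        true_mut <- !is.na(midx)
        fp <- !true_mut & called & runif(nl) < p_fp
        dgl <- rlnorm(nl, meanlog - ifelse(fp, config@fp_shift, 0),
                      config@dgl_sd)
        best <- alle$ancestral
        second <- alle$shorter
        if (any(true_mut)) {
            mi <- which(true_mut)
            ev <- cohort$mutations[midx[mi], , drop = FALSE]
            best[mi] <- vapply(seq_along(mi), function(j)
                .derivedAllele(alle$ancestral[mi[j]], catalog$motif[mi[j]],
                               ev$kind[j], ev$delta_bp[j]), character(1))
            second[mi] <- alle$ancestral[mi]
        }
        if (any(fp)) {
            fi <- which(fp)
            best[fi] <- alle$shorter[fi]
            second[fi] <- alle$ancestral[fi]
        }
        is_mut <- true_mut | fp
        df <- data.frame(
            strain = st, chrom = chrom, pos = pos, locus_id = ids,
            ancestral_allele = alle$ancestral,
            best_allele = ifelse(called, best, NA_character_),
            second_allele = ifelse(called, second, NA_character_),
            delta_gl = ifelse(called, dgl, NA_real_),
            depth = ifelse(called, depth, NA_integer_),
            alt_support = ifelse(called, rbeta(nl, 2, 30), NA_real_),
            is_mutant = ifelse(called, is_mut, NA),
            called = called, stringsAsFactors = FALSE)
        out[[s]] <- df
        lab <- called & is_mut
        if (any(lab))
            labels[[length(labels) + 1L]] <- data.frame(
                strain = st, locus_id = ids[lab],
                label = ifelse(true_mut[lab], "true_positive",
                               "false_positive"),
                stringsAsFactors = FALSE)
    }
    calls <- do.call(rbind, out)
    rownames(calls) <- NULL
    labs <- if (length(labels)) do.call(rbind, labels)
        else data.frame(strain = character(0), locus_id = character(0),
                        label = character(0))
    list(calls = calls, labels = labs)
}

#' One-call simulation of catalog, cohort and calls
#'
#' @param config a [SimulationConfig-class].
#' @return list with `catalog`, `cohort`, `calls`, `labels`, `config`.
#' @export
simulateCallSet <- function(config = simulationConfig()) {
    catalog <- generateCatalog(config)
    cohort <- simulateCohort(catalog, config)
    emitted <- emitCalls(catalog, cohort, config)
    list(catalog = catalog, cohort = cohort, calls = emitted$calls,
         labels = emitted$labels, config = config)
}
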
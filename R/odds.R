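# Per-bp mutation-odds model
#
# odds(mutation at locus, strain) = n * O_base * prod_i theta_i
#
# i.e. a binomial GLM on the logit scale with offset log(n) (locus length in
# bp), intercept log(O_base), and one log(theta) coefficient per term:
#   long          : indicator, locus length >= 8 bp
#   motif_length  : numeric, per +1 bp of motif
#   at_proportion : numeric in [0, 1]
#   genotype      : indicator for the mutant (msh3-deleted) genotype
# Fitted by iteratively reweighted least squares with step-halving; complete
# separation (a coefficient running off to +/-Inf with ever-decreasing
# deviance, e.g. zero mutations in one genotype) is detected per term.

.oddsTerms <- c("long", "motif_length", "at_proportion", "genotype")

#' Assemble locus-strain outcome records for the odds model
#'
#' One record per called, threshold-passing locus x strain with the model
#' covariates and the mutation indicator. The `long` flag is
#' `length_bp >= long_cutoff_bp` (default 8 bp, i.e. "long" means >7 bp).
#'
#' @param passing data.frame of passing calls as returned by
#'   [applyThresholds()] (or the `passing` attribute of
#'   [selectMutations()]).
#' @param catalog an [SsrCatalog-class].
#' @param genotypes data.frame with columns `strain` and `genotype`;
#'   `genotype` must have exactly the reference level first when converted
#'   to factor (e.g. `"MSH3+"` < `"msh3d"`), or be a factor with the
#'   wild-type level first.
#' @param events optional mutation-event data.frame used to cross-check
#'   that every event occurs at a called locus; an event at an uncalled
#'   locus-strain is an inconsistency and raises an error.
#' @param long_cutoff_bp threshold for the `long` indicator (default 8).
#' @return data.frame of outcomes: `strain`, `locus_id`, `length_bp`,
#'   `long`, `motif_length`, `at_proportion`, `genotype`, `mutated`.
#' @export
assembleOutcomes <- function(passing, catalog, genotypes, events = NULL,
                             long_cutoff_bp = 8L) {
    stopifnot(all(c("strain", "genotype") %in% colnames(genotypes)))
    ids <- locusIds(catalog)
    idx <- match(passing$locus_id, ids)
    if (anyNA(idx)) stop("passing calls reference loci absent from the catalog")
    gt <- genotypes$genotype[match(passing$strain, genotypes$strain)]
    if (anyNA(gt)) stop("strain(s) missing from the genotype table")
    out <- data.frame(strain = passing$strain, locus_id = passing$locus_id,
                      length_bp = GenomicRanges::width(catalog)[idx],
                      motif_length = nchar(catalog$motif)[idx],
                      at_proportion = catalog$at_proportion[idx],
                      genotype = gt,
                      mutated = passing$is_mutant,
                      stringsAsFactors = FALSE)
    out$long <- out$length_bp >= long_cutoff_bp
    if (!is.null(events) && nrow(events)) {
        key <- paste(out$strain, out$locus_id)
        bad <- !(paste(events$strain, events$locus_id) %in% key)
        if (any(bad))
            stop(sum(bad), " mutation event(s) at uncalled locus-strain pairs")
        out$mutated <- out$mutated | key %in% paste(events$strain, events$locus_id)
    }
    out[, c("strain", "locus_id", "length_bp", "long", "motif_length",
            "at_proportion", "genotype", "mutated")]
}

# Build the aggregated design for a term subset. Outcomes sharing identical
# covariates and offset collapse to binomial (successes, trials) rows, which
# makes IRLS and profiling cheap at any cohort size.
.oddsDesign <- function(outcomes, terms) {
    stopifnot(all(terms %in% .oddsTerms))
    n <- nrow(outcomes)
    cols <- list(`(baseline)` = rep(1, n))
    if ("long" %in% terms) cols$long <- as.numeric(outcomes$long)
    if ("motif_length" %in% terms) cols$motif_length <- as.numeric(outcomes$motif_length)
    if ("at_proportion" %in% terms) cols$at_proportion <- as.numeric(outcomes$at_proportion)
    if ("genotype" %in% terms) {
        g <- outcomes$genotype
        if (!is.factor(g)) g <- factor(g)
        if (nlevels(g) != 2L) stop("genotype must have exactly two levels")
        cols$genotype <- as.numeric(g == levels(g)[2L])
    }
    X <- do.call(cbind, cols)
    off <- log(outcomes$length_bp)
    y <- as.numeric(outcomes$mutated)
    key <- do.call(paste, c(as.data.frame(X), list(off)))
    grp <- match(key, unique(key))
    Xa <- X[!duplicated(grp), , drop = FALSE]
    offa <- off[!duplicated(grp)]
    list(X = Xa, offset = offa,
         succ = as.numeric(tapply(y, grp, sum)),
         size = as.numeric(tapply(y, grp, length)))
}

.bernoulliLogLik <- function(eta, succ, size) {
    # log-likelihood in Bernoulli form (no binomial coefficient)
    sum(succ * eta - size * log1p(exp(eta)))
}

# IRLS for the aggregated binomial logit fit; `fixed` pins coefficients
# (named values) for profiling. Returns beta, loglik, convergence info.
.irlsFit <- function(design, fixed = NULL, max_iter = 100L, tol = 1e-10,
                     sep_cutoff = 15) {
    X <- design$X; off <- design$offset
    succ <- design$succ; size <- design$size
    free <- setdiff(colnames(X), names(fixed))
    off_eff <- off
    if (length(fixed))
        off_eff <- off + drop(X[, names(fixed), drop = FALSE] %*% unlist(fixed))
    Xf <- X[, free, drop = FALSE]
    beta <- setNames(rep(0, length(free)), free)
    if ("(baseline)" %in% free) {
        p0 <- max(sum(succ), 0.5) / sum(size)
        beta["(baseline)"] <- log(p0 / (1 - p0)) - mean(off_eff)
    }
    eta <- drop(Xf %*% beta) + off_eff
    ll <- .bernoulliLogLik(eta, succ, size)
    iter_converged <- FALSE
    for (it in seq_len(max_iter)) {
        p <- 1 / (1 + exp(-eta))
        w <- size * p * (1 - p)
        w <- pmax(w, 1e-12)
        z <- eta - off_eff + (succ - size * p) / w
        fit <- lm.wfit(Xf, z, w)
        beta_new <- setNames(fit$coefficients, free)
        beta_new[is.na(beta_new)] <- 0
        # step-halving if the likelihood does not improve
        step <- beta_new - beta
        ll_new <- -Inf
        for (h in 0:25) {
            cand <- beta + step / 2^h
            eta_c <- drop(Xf %*% cand) + off_eff
            ll_c <- .bernoulliLogLik(eta_c, succ, size)
            if (is.finite(ll_c) && ll_c >= ll - 1e-12) {
                beta_new <- cand; eta <- eta_c; ll_new <- ll_c; break
            }
        }
        if (!is.finite(ll_new)) break
        done <- abs(ll_new - ll) < tol * (abs(ll) + 1)
        beta <- beta_new; ll <- ll_new
        if (done) { iter_converged <- TRUE; break }
    }
    separated <- abs(beta) > sep_cutoff
    names(separated) <- free
    list(beta = beta, loglik = ll, iter_converged = iter_converged,
         separated = separated)
}

#' Fit the per-bp mutation-odds model
#'
#' Maximizes the binomial likelihood of
#' `mutated ~ logit^-1(log(n) + log(O_base) + sum(log theta_i))`, where the
#' locus length `n` enters as a fixed offset. Estimates are reported on the
#' log-odds scale in the fit object; use [oddsEstimates()] for fold-odds.
#' A term whose coefficient diverges (complete separation, e.g. no
#' mutations in the wild-type genotype) is flagged `converged = FALSE` and
#' its odds estimate is `Inf` (or 0); the remaining terms are still valid.
#'
#' @param outcomes data.frame from [assembleOutcomes()] (needs `length_bp`,
#'   `mutated`, plus the columns for the requested terms).
#' @param terms subset of `c("long", "motif_length", "at_proportion",
#'   "genotype")`.
#' @return an [OddsModelFit-class].
#' @export
fitOddsModel <- function(outcomes, terms = c("long", "motif_length",
                                             "at_proportion")) {
    stopifnot(nrow(outcomes) > 0)
    if (!any(outcomes$mutated) || all(outcomes$mutated))
        warning("all outcomes share one state; the baseline is not identifiable")
    design <- .oddsDesign(outcomes, terms)
    fit <- .irlsFit(design)
    beta <- fit$beta
    conv <- !fit$separated
    beta[fit$separated] <- sign(beta[fit$separated]) * Inf
    new("OddsModelFit", coefficients = beta, terms = terms,
        loglik = fit$loglik, converged = conv,
        n = nrow(outcomes), n_mutated = as.integer(sum(outcomes$mutated)),
        data = list(design = design))
}

#' Likelihood-ratio test of nested odds models
#'
#' @param full,null [OddsModelFit-class] objects fitted to the same
#'   outcomes; `null`'s terms must be a strict subset of `full`'s.
#' @return list with `statistic` (twice the log-likelihood difference),
#'   `df` and `p` (chi-square upper tail).
#' @export
lrTest <- function(full, null) {
    if (!all(null@terms %in% full@terms))
        stop("models are not nested: null terms must be a subset of full terms")
    if (full@n != null@n)
        stop("models were fitted to different numbers of outcomes")
    stat <- max(0, 2 * (full@loglik - null@loglik))
    df <- length(full@terms) - length(null@terms)
    if (df == 0) return(list(statistic = stat, df = 0L, p = 1))
    list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

# Profiled log-likelihood with one coefficient pinned at value t.
.profileLogLik <- function(design, term, t) {
    .irlsFit(design, fixed = setNames(list(t), term))$loglik
}

#' Profile-likelihood confidence interval for one coefficient
#'
#' Bounds are the points where the profiled deviance rises by the
#' chi-square(1) quantile above its minimum, located by geometric bracket
#' expansion followed by bisection on the log-odds axis. When the deviance
#' never reaches the cutoff on a side (separation), that bound is `Inf`
#' (or 0 on the odds scale for the lower side).
#'
#' @param fit an [OddsModelFit-class].
#' @param term `"(baseline)"` or one of the fit's terms.
#' @param level confidence level (default 0.95).
#' @return named numeric `c(low, high)` on the fold-odds scale.
#' @export
profileCI <- function(fit, term, level = 0.95) {
    stopifnot(term %in% names(fit@coefficients))
    design <- fit@data$design
    cutoff <- qchisq(level, 1)
    mle <- fit@coefficients[[term]]
    cap <- 30
    if (is.finite(mle)) {
        anchor <- mle
        ll_hat <- fit@loglik
    } else {
        # separated term: walk outward until the profiled likelihood is
        # flat (or the fit degrades numerically) and anchor at its argmax
        dirn <- sign(mle)
        anchor <- dirn * 2; ll_hat <- .profileLogLik(design, term, anchor)
        prev <- ll_hat
        for (t in seq(4, cap, by = 2)) {
            ll_t <- .profileLogLik(design, term, dirn * t)
            if (!is.finite(ll_t) || ll_t < ll_hat - 1e-8) break
            if (ll_t > ll_hat) { ll_hat <- ll_t; anchor <- dirn * t }
            if (t > 6 && ll_t - prev < 1e-6) break
            prev <- ll_t
        }
    }
    dev <- function(t) 2 * (ll_hat - .profileLogLik(design, term, t))

    bound <- function(dir) {        # dir = -1 lower, +1 upper
        if (!is.finite(mle) && sign(mle) == dir) return(dir * Inf)
        step <- 0.5
        t_in <- anchor
        repeat {
            t_out <- t_in + dir * step
            if (dev(t_out) >= cutoff) break
            t_in <- t_out
            step <- step * 2
            if (abs(t_out - anchor) > 12 + cap) return(dir * Inf)
        }
        lo <- min(t_in, t_out); hi <- max(t_in, t_out)
        for (i in 1:60) {
            mid <- (lo + hi) / 2
            high_side <- dev(mid) >= cutoff
            if ((dir > 0) == high_side) hi <- mid else lo <- mid
            if (hi - lo < 1e-4) break
        }
        (lo + hi) / 2
    }
    lo <- bound(-1); hi <- bound(1)
    c(low = exp(lo), high = exp(hi))
}
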
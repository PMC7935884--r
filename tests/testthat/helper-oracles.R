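# Independent oracles and small builders used across the suite. The oracles
# deliberately re-derive quantities by brute force (explicit sums, direct
# simulation) and never call the code paths they check.

makeSummary <- function(m, sem, n = 100L, channel = "green",
                        condition = "EV", replicate = "r1") {
    methods::new("PopulationSummary", condition = condition,
                 replicate = replicate, channel = channel, n = as.integer(n),
                 mean = m, sd = sem * sqrt(n), sem = sem,
                 percentiles = c(p10 = m, p25 = m, p50 = m, p75 = m, p90 = m))
}

makeRatio <- function(v, d, n = 500L) {
    methods::new("RatioWithError", value = v, delta = d,
                 nInjured = as.integer(n), nUninjured = as.integer(n))
}

# Monte-Carlo SD of a quotient of two Gaussian-uncertain means.
mcRatioSD <- function(mi, si, mu, su, nDraws = 1e5, seed = 1) {
    withr::with_seed(seed, {
        num <- rnorm(nDraws, mi, si)
        den <- rnorm(nDraws, mu, su)
        sd(num / den)
    })
}

# Monte-Carlo SD of the index (EV - RNAi)/(EV - 1) where the two ratios are
# Gaussian with the stated errors.
mcIndexSD <- function(ev, dEv, rnai, dRnai, nDraws = 1e5, seed = 1) {
    withr::with_seed(seed, {
        e <- rnorm(nDraws, ev, dEv)
        r <- rnorm(nDraws, rnai, dRnai)
        sd((e - r) / (e - 1))
    })
}

# Brute-force complete-case pairwise Pearson from explicit sums.
bruteForcePearson <- function(mat) {
    cc <- rowSums(is.na(mat)) == 0
    m <- mat[cc, , drop = FALSE]
    k <- ncol(m)
    r <- diag(1, k)
    for (i in seq_len(k)) for (j in seq_len(k)) {
        x <- m[, i]; y <- m[, j]
        n <- length(x)
        sx <- sum(x); sy <- sum(y)
        num <- sum(x * y) - sx * sy / n
        den <- sqrt((sum(x^2) - sx^2 / n) * (sum(y^2) - sy^2 / n))
        r[i, j] <- num / den
    }
    dimnames(r) <- list(colnames(mat), colnames(mat))
    r
}

# Step-up FDR oracle straight from the definition:
# q_(i) = min_{j >= i} ( n * p_(j) / j ), capped at 1, on the sorted scale.
bhStepUp <- function(p) {
    n <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- pmin(1, n * ps / seq_len(n))
    q <- rev(cummin(rev(q)))
    out <- numeric(n)
    out[o] <- q
    out
}

# Population-level index from raw per-arm green values (Eq.-2 semantics,
# no package code involved).
bruteForceIndex <- function(evInj, evUninj, gInj, gUninj) {
    ev <- mean(evInj) / mean(evUninj)
    g <- mean(gInj) / mean(gUninj)
    (ev - g) / (ev - 1)
}

# A well-separated flow configuration: every contaminant class sits >= 4
# adult-SDs (log scale) from the gate that should catch it.
separatedFlowConfig <- function(nWorms = 20000L, seed = 1L,
                                fractions = c(larva = 0.10, bacteria = 0.10,
                                              doublet = 0.05, curl = 0.05),
                                ...) {
    flowSimConfig(nWorms = nWorms,
                  adultTofSdlog = 0.04, adultExtSdlog = 0.04,
                  contaminantFractions = fractions, seed = seed, ...)
}

# Matching clean reference for gate derivation.
separatedReference <- function(seed = 99L) {
    sim <- generateFlowEvents(separatedFlowConfig(
        nWorms = 5000L, seed = seed,
        fractions = c(larva = 0, bacteria = 0, doublet = 0, curl = 0)))
    sim$events
}
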
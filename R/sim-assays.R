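# Seeded generators for the small behavioral/qPCR assay inputs.

#' Simulate a chemotaxis quadrant assay
#'
#' Each worm independently ends in a butanol quadrant (probability
#' `pButanol`), an ethanol quadrant (`pEthanol`) or the neutral center
#' (remainder); counts are a single multinomial draw.
#'
#' @param pButanol,pEthanol quadrant probabilities, `pButanol + pEthanol <= 1`.
#' @param n worms scored.
#' @param seed integer seed.
#' @return list with `nButanol`, `nEthanol`, `nTotal`.
#' @export
generateQuadrantCounts <- function(pButanol, pEthanol, n, seed = 1L) {
    if (pButanol < 0 || pEthanol < 0 || pButanol + pEthanol > 1)
        configError("quadrant probabilities must be in [0,1] and sum to <= 1")
    if (n < 1) configError("n must be positive")
    counts <- withr::with_seed(childSeed(seed, "quadrant"),
        as.vector(stats::rmultinom(1, n, c(pButanol, pEthanol,
                                           1 - pButanol - pEthanol))))
    list(nButanol = counts[1], nEthanol = counts[2], nTotal = as.integer(n))
}

#' Simulate a paralysis tally
#'
#' @param pParalyzed probability a worm is scored paralyzed.
#' @param n worms scored.
#' @param seed integer seed.
#' @return list with `nParalyzed`, `nScored`.
#' @export
generateParalysisCounts <- function(pParalyzed, n, seed = 1L) {
    if (pParalyzed < 0 || pParalyzed > 1) configError("pParalyzed must be in [0,1]")
    if (n < 1) configError("n must be positive")
    k <- withr::with_seed(childSeed(seed, "paralysis"),
                          stats::rbinom(1, n, pParalyzed))
    list(nParalyzed = k, nScored = as.integer(n))
}

#' Simulate nose-touch trials
#'
#' @param pResponse per-trial probability of a positive response.
#' @param nWorms number of worms.
#' @param nTrials trials per worm (default 5).
#' @param seed integer seed.
#' @return logical matrix, worms x trials.
#' @export
generateNoseTouchTrials <- function(pResponse, nWorms, nTrials = 5L, seed = 1L) {
    if (pResponse < 0 || pResponse > 1) configError("pResponse must be in [0,1]")
    if (nWorms < 1 || nTrials < 1) configError("counts must be positive")
    withr::with_seed(childSeed(seed, "nosetouch"),
        matrix(stats::runif(nWorms * nTrials) < pResponse, nWorms, nTrials))
}

#' Simulate a qPCR Ct table
#'
#' Ct values follow `Ct = -log2(relative level) + housekeeping baseline +
#' N(0, noiseSd)`; the two housekeeping genes have relative level 1. A
#' configurable fraction of technical replicates is flagged with more than
#' one melt-curve peak (to be excluded downstream).
#'
#' @param levels data.frame with columns `sample`, `gene`, `level` (true
#'   relative transcript level of each target gene per sample).
#' @param housekeeping labels of the two housekeeping genes (defaults
#'   `"tba-1"` and `"Y45F10D.4"`).
#' @param baselineCt housekeeping baseline cycle count.
#' @param noiseSd Gaussian Ct noise (cycles).
#' @param nTechReps technical replicates per (sample, gene).
#' @param meltFlagFraction fraction of technical reps flagged with 2 melt
#'   peaks.
#' @param seed integer seed.
#' @return data.frame with columns `sample`, `gene`, `technical_rep`, `ct`,
#'   `melt_peaks` — the input format of [qpcrRelativeAbundance()].
#' @export
generateCtTable <- function(levels, housekeeping = c("tba-1", "Y45F10D.4"),
                            baselineCt = 19, noiseSd = 0.15, nTechReps = 3L,
                            meltFlagFraction = 0, seed = 1L) {
    if (!all(c("sample", "gene", "level") %in% names(levels)))
        configError("levels needs columns sample, gene, level")
    if (any(levels$level <= 0)) configError("relative levels must be positive")
    if (meltFlagFraction < 0 || meltFlagFraction >= 1)
        configError("meltFlagFraction must lie in [0, 1)")
    samples <- unique(levels$sample)
    hk <- data.frame(sample = rep(samples, each = length(housekeeping)),
                     gene = rep(housekeeping, length(samples)),
                     level = 1, stringsAsFactors = FALSE)
    full <- rbind(levels[, c("sample", "gene", "level")], hk)
    out <- full[rep(seq_len(nrow(full)), each = nTechReps), ]
    out$technical_rep <- rep(seq_len(nTechReps), nrow(full))
    withr::with_seed(childSeed(seed, "qpcr"), {
        out$ct <- -log2(out$level) + baselineCt +
            stats::rnorm(nrow(out), 0, noiseSd)
        out$melt_peaks <- ifelse(stats::runif(nrow(out)) < meltFlagFraction, 2L, 1L)
    })
    out$level <- NULL
    rownames(out) <- NULL
    out
}
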
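# Behavioral and qPCR assay metrics.

#' Chemotactic index of a quadrant assay
#'
#' `(n_butanol - n_ethanol) / n_total`: 1 means 100% preference for the
#' attractant, 0 no preference, negative values avoidance. Worms remaining
#' in the neutral center circle count toward the denominator but neither
#' attractant tally.
#'
#' @param nButanol,nEthanol worms in the butanol / ethanol quadrants.
#' @param nTotal all worms scored (>= `nButanol + nEthanol`).
#' @return the index, in [-1, 1].
#' @examples
#' chemotacticIndex(100, 0, 100)   # 1: full preference
#' chemotacticIndex(40, 40, 100)   # 0: no preference
#' @export
chemotacticIndex <- function(nButanol, nEthanol, nTotal) {
    if (nTotal < 1) dataError("nTotal must be >= 1")
    if (nButanol < 0 || nEthanol < 0 || nButanol + nEthanol > nTotal)
        dataError("quadrant counts must be non-negative and sum to <= nTotal")
    (nButanol - nEthanol) / nTotal
}

#' Paralyzed fraction with Wilson 95% CI
#'
#' @param nParalyzed worms failing to thrash.
#' @param nScored worms scored (>= 1).
#' @return list with `fraction`, `ciLow`, `ciHigh`, `nParalyzed`, `nScored`.
#' @export
paralysisFraction <- function(nParalyzed, nScored) {
    if (nScored < 1) dataError("nScored must be >= 1")
    if (nParalyzed < 0 || nParalyzed > nScored)
        dataError("nParalyzed must lie in [0, nScored]")
    ci <- wilsonInterval(nParalyzed, nScored)
    list(fraction = nParalyzed / nScored,
         ciLow = unname(ci[1]), ciHigh = unname(ci[2]),
         nParalyzed = nParalyzed, nScored = nScored)
}

#' Dose-response paralysis table
#'
#' Tabulates [paralysisFraction()] across agitation frequencies.
#'
#' @param counts data.frame with columns `frequency`, `nParalyzed`,
#'   `nScored`.
#' @return data.frame with per-frequency fraction and Wilson bounds.
#' @export
paralysisDoseResponse <- function(counts) {
    need <- c("frequency", "nParalyzed", "nScored")
    if (!all(need %in% names(counts)))
        dataError("counts needs columns frequency, nParalyzed, nScored")
    rows <- lapply(seq_len(nrow(counts)), function(i) {
        f <- paralysisFraction(counts$nParalyzed[i], counts$nScored[i])
        data.frame(frequency = counts$frequency[i], fraction = f$fraction,
                   ciLow = f$ciLow, ciHigh = f$ciHigh)
    })
    do.call(rbind, rows)
}

#' Nose-touch response score
#'
#' Each worm receives a percent of positive responses over its trials; the
#' population mean and SEM are computed over worms (the worm, not the
#' trial, is the experimental unit).
#'
#' @param trials logical matrix (worms x trials) or list of per-worm logical
#'   vectors; every worm must have `nTrials` trials.
#' @param nTrials expected trials per worm (default 5).
#' @return list with `perWorm` (percent positive per worm), `mean`, `sem`,
#'   `nWorms`.
#' @export
noseTouchScore <- function(trials, nTrials = 5L) {
    if (is.matrix(trials)) trials <- asplit(trials, 1)
    if (!length(trials)) dataError("no worms scored")
    len <- lengths(trials)
    if (any(len != nTrials))
        dataError(paste0("every worm must have exactly ", nTrials, " trials"))
    perWorm <- vapply(trials, function(w) 100 * mean(as.logical(w)), numeric(1))
    n <- length(perWorm)
    list(perWorm = unname(perWorm), mean = mean(perWorm),
         sem = sdOrZero(perWorm) / sqrt(n), nWorms = n)
}

#' Tally movement phenotypes
#'
#' @param labels per-worm category labels.
#' @param categories the closed set of allowed categories; defaults to the
#'   observed labels.
#' @return data.frame with `category`, `n`, `proportion` (summing to 1).
#' @export
movementPhenotypeTally <- function(labels, categories = NULL) {
    if (!length(labels)) dataError("no worms scored")
    labels <- as.character(labels)
    if (is.null(categories)) categories <- unique(labels)
    bad <- setdiff(labels, categories)
    if (length(bad))
        dataError(paste("labels outside the declared category set:",
                        paste(unique(bad), collapse = ", ")))
    n <- vapply(categories, function(k) sum(labels == k), integer(1))
    data.frame(category = categories, n = n, proportion = n / length(labels),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Relative transcript abundance by the delta-Ct method
#'
#' Technical replicates with more than one melt-curve peak are excluded;
#' remaining replicates are averaged per (sample, gene). The delta-Ct uses
#' the arithmetic mean of the two housekeeping Cts — algebraically identical
#' to normalizing the `2^-Ct` level by the geometric mean of the two
#' housekeeping levels — and the relative level is `2^-deltaCt` (100%
#' amplification efficiency assumed). With a reference condition, levels are
#' further divided by that condition's mean level per gene (fold change).
#'
#' @param ct data.frame with columns `sample`, `gene`, `technical_rep`,
#'   `ct`, `melt_peaks`, and optionally `condition` (defaults to `sample`).
#' @param housekeeping the two housekeeping gene labels (defaults `"tba-1"`,
#'   `"Y45F10D.4"`).
#' @param referenceCondition optional condition label to express levels as
#'   fold changes against.
#' @return data.frame with `sample`, `condition`, `gene`, `meanCt`,
#'   `deltaCt`, `level` (and `foldChange` when a reference is given); one
#'   row per (sample, target gene).
#' @examples
#' ct <- data.frame(sample = "s1", gene = c("lys-3", "tba-1", "Y45F10D.4"),
#'                  technical_rep = 1, ct = c(20, 18, 20), melt_peaks = 1)
#' qpcrRelativeAbundance(ct)   # deltaCt = 1, level = 0.5
#' @export
qpcrRelativeAbundance <- function(ct, housekeeping = c("tba-1", "Y45F10D.4"),
                                  referenceCondition = NULL) {
    need <- c("sample", "gene", "technical_rep", "ct", "melt_peaks")
    missing <- setdiff(need, names(ct))
    if (length(missing))
        dataError(paste("Ct table lacks columns:", paste(missing, collapse = ", ")))
    if (length(housekeeping) != 2L)
        configError("exactly two housekeeping genes are required")
    if (any(ct$ct <= 0)) dataError("Ct values must be positive")
    if (is.null(ct$condition)) ct$condition <- ct$sample
    kept <- ct[ct$melt_peaks <= 1L, , drop = FALSE]
    dropped <- unique(paste0(ct$sample, "/", ct$gene))
    keptCells <- unique(paste0(kept$sample, "/", kept$gene))
    lost <- setdiff(dropped, keptCells)
    if (length(lost))
        dataError(paste("all technical replicates excluded by melt-curve",
                        "analysis for:", paste(lost, collapse = ", ")))
    agg <- stats::aggregate(ct ~ sample + condition + gene, data = kept, FUN = mean)
    out <- list()
    for (s in unique(agg$sample)) {
        sub <- agg[agg$sample == s, , drop = FALSE]
        hk <- sub$ct[match(housekeeping, sub$gene)]
        if (anyNA(hk))
            dataError(paste0("sample '", s, "' lacks housekeeping gene(s): ",
                             paste(housekeeping[is.na(hk)], collapse = ", ")))
        targets <- sub[!sub$gene %in% housekeeping, , drop = FALSE]
        if (!nrow(targets)) next
        dct <- targets$ct - mean(hk)
        out[[s]] <- data.frame(sample = s, condition = targets$condition,
                               gene = targets$gene, meanCt = targets$ct,
                               deltaCt = dct, level = 2^(-dct),
                               stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    if (!is.null(referenceCondition)) {
        if (!referenceCondition %in% res$condition)
            dataError(paste0("reference condition '", referenceCondition,
                             "' not present"))
        ref <- res[res$condition == referenceCondition, , drop = FALSE]
        refMean <- tapply(ref$level, ref$gene, mean)
        res$foldChange <- res$level / as.numeric(refMean[res$gene])
    }
    res
}
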
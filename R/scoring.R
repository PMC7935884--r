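# Dopaminergic GFP Index: ratio -> index -> replicate combination -> hits.

#' Injured/uninjured fluorescence ratio with quadrature error
#'
#' The retained-fluorescence ratio `R = m_injured / m_uninjured` of two
#' population summaries on the same channel. Its uncertainty follows the
#' general quadrature propagation rule applied to a quotient:
#' `delta = R * sqrt((sem_i/m_i)^2 + (sem_u/m_u)^2)`.
#'
#' @param injured,uninjured [PopulationSummary-class] objects on the same
#'   channel; the uninjured mean must be positive.
#' @return A [RatioWithError-class].
#' @examples
#' s <- function(m, sem, n = 100L) methods::new("PopulationSummary",
#'     condition = "EV", replicate = "r1", channel = "green", n = n,
#'     mean = m, sd = sem * sqrt(n), sem = sem,
#'     percentiles = c(p10 = m, p25 = m, p50 = m, p75 = m, p90 = m))
#' fluorescenceRatio(s(50, 2), s(100, 4))  # 0.5 +/- 0.0283
#' @export
fluorescenceRatio <- function(injured, uninjured) {
    if (!methods::is(injured, "PopulationSummary") ||
        !methods::is(uninjured, "PopulationSummary"))
        dataError("both arguments must be PopulationSummary objects")
    if (injured@channel != uninjured@channel)
        dataError("summaries must be on the same channel")
    if (uninjured@mean <= 0)
        dataError("uninjured mean must be > 0 to form a ratio")
    if (injured@mean <= 0)
        dataError("injured mean must be > 0 to form a ratio")
    value <- injured@mean / uninjured@mean
    delta <- value * sqrt((injured@sem / injured@mean)^2 +
                          (uninjured@sem / uninjured@mean)^2)
    methods::new("RatioWithError", value = value, delta = delta,
                 nInjured = injured@n, nUninjured = uninjured@n)
}

#' Single-replicate Dopaminergic GFP Index
#'
#' The screen statistic `index = (EV - RNAi) / (EV - 1)`, where `EV` and
#' `RNAi` are the injured/uninjured retained-fluorescence ratios of the
#' empty-vector control and the knockdown condition in the same replicate.
#' An index of 1 means no fluorescence loss relative to uninjured controls
#' (full protection), 0 means the same loss as the control, negative values
#' mean increased loss (sensitization). The within-replicate error applies
#' the general quadrature propagation rule through the index formula, using
#' its partial derivatives in the two ratios:
#' `delta = sqrt((dRNAi/(EV-1))^2 + (dEV*(RNAi-1)/(EV-1)^2)^2)`.
#' When the knockdown ratio equals the control ratio (index 0) this reduces
#' to the symmetric form `sqrt(dEV^2 + dRNAi^2)/(1-EV)`.
#'
#' A control with essentially no GFP loss (`|EV - 1| <= epsilonGuard`) makes
#' the index undefined and raises a degenerate-control error.
#'
#' @param ev,rnai [RatioWithError-class] objects for the control and the
#'   knockdown condition.
#' @param epsilonGuard guard band around EV = 1 (default 0.02).
#' @return A single-replicate [IndexResult-class] (between-replicate error 0).
#' @examples
#' r <- function(v, d) methods::new("RatioWithError", value = v, delta = d,
#'                                  nInjured = 500L, nUninjured = 500L)
#' indexEstimate(gfpIndex(r(0.5, 0), r(1.0, 0)))  # 1: full protection
#' indexEstimate(gfpIndex(r(0.5, 0), r(0.5, 0)))  # 0: same loss as control
#' @export
gfpIndex <- function(ev, rnai, epsilonGuard = 0.02) {
    if (!methods::is(ev, "RatioWithError") || !methods::is(rnai, "RatioWithError"))
        dataError("ev and rnai must be RatioWithError objects")
    if (abs(ev@value - 1) <= epsilonGuard)
        dataError(paste0("degenerate control: EV ratio ", format(ev@value),
                         " is within ", format(epsilonGuard),
                         " of 1 (no GFP loss in EV; index undefined)"))
    denom <- ev@value - 1
    index <- (ev@value - rnai@value) / denom
    delta <- sqrt((rnai@delta / denom)^2 +
                  (ev@delta * (rnai@value - 1) / denom^2)^2)
    z <- stats::qnorm(0.975)
    methods::new("IndexResult", index = index, deltaWithin = delta,
                 deltaBetween = 0, deltaTotal = delta,
                 ciLow = index - z * delta, ciHigh = index + z * delta,
                 nReplicates = 1L, replicateIndices = index)
}

#' Combine per-replicate indices
#'
#' The combined index is the mean of the replicate indices. The
#' within-replicate errors are added in quadrature and scaled as an error of
#' the mean (`sqrt(sum(delta_r^2)) / n`); the between-replicate error is the
#' SEM of the replicate indices; the two are combined in quadrature and the
#' 95% confidence interval is `index +/- z * deltaTotal`.
#'
#' @param results list of single-replicate [IndexResult-class] objects.
#' @return A combined [IndexResult-class].
#' @export
combineReplicates <- function(results) {
    if (!length(results)) dataError("at least one replicate is required")
    if (!all(vapply(results, methods::is, logical(1), "IndexResult")))
        dataError("results must be IndexResult objects")
    idx <- vapply(results, function(r) r@index, numeric(1))
    deltas <- vapply(results, function(r) r@deltaWithin, numeric(1))
    n <- length(idx)
    index <- mean(idx)
    deltaWithin <- sqrt(sum(deltas^2)) / n
    deltaBetween <- sdOrZero(idx) / sqrt(n)
    deltaTotal <- sqrt(deltaWithin^2 + deltaBetween^2)
    z <- stats::qnorm(0.975)
    methods::new("IndexResult", index = index, deltaWithin = deltaWithin,
                 deltaBetween = deltaBetween, deltaTotal = deltaTotal,
                 ciLow = index - z * deltaTotal, ciHigh = index + z * deltaTotal,
                 nReplicates = as.integer(n), replicateIndices = idx)
}

#' Call protective and sensitizing hits
#'
#' A knockdown is protective when its confidence interval lies entirely
#' above zero, sensitizing when entirely below, otherwise no effect. The CI
#' is recomputed from `deltaTotal` at the requested `alpha`.
#'
#' @param results named list of [IndexResult-class] objects (one per gene),
#'   including the `"EV"` control.
#' @param alpha two-sided significance level (default 0.05).
#' @return data.frame sorted by index (descending) with columns `gene`,
#'   `index`, `deltaWithin`, `deltaBetween`, `deltaTotal`, `ciLow`, `ciHigh`,
#'   `nReplicates`, `classification`.
#' @export
callHits <- function(results, alpha = 0.05) {
    if (is.null(names(results)) || !"EV" %in% names(results))
        dataError("results must be a named list including the EV control")
    z <- stats::qnorm(1 - alpha / 2)
    rows <- lapply(names(results), function(g) {
        r <- results[[g]]
        lo <- r@index - z * r@deltaTotal
        hi <- r@index + z * r@deltaTotal
        cls <- if (lo > 0) "protective" else if (hi < 0) "sensitizing" else "no_effect"
        data.frame(gene = g, index = r@index,
                   deltaWithin = r@deltaWithin, deltaBetween = r@deltaBetween,
                   deltaTotal = r@deltaTotal, ciLow = lo, ciHigh = hi,
                   nReplicates = r@nReplicates, classification = cls,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(-out$index), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Score a whole screen from raw event tables
#'
#' Full composition of the pipeline: gate each arm, summarize the scoring
#' channel per replicate, form injured/uninjured ratios, compute the
#' per-replicate index against the same-replicate EV ratio, combine
#' replicates, and call hits.
#'
#' @param experiment named list (one entry per condition, including `"EV"`)
#'   of lists with `injured` and `uninjured` [FlowEventTable-class] objects;
#'   replicates are identified by the `replicate` column and must match
#'   across conditions.
#' @param gates a [GateConfig-class], or `NULL` to derive [defaultGates()]
#'   from the uninjured EV table.
#' @param channel scoring channel (default `"green"`).
#' @param alpha significance level for hit calling.
#' @param epsilonGuard degenerate-control guard for [gfpIndex()].
#' @param stat location statistic passed to [summarizePopulation()].
#' @return list with `hits` (the report table from [callHits()]), `results`
#'   (named list of combined [IndexResult-class] objects) and `gates`.
#' @examples
#' cfg <- screenSimConfig(genes = "geneA", trueIndex = c(geneA = 0.8),
#'                        flowConfig = flowSimConfig(nWorms = 300), seed = 42)
#' sim <- generateScreenExperiment(cfg)
#' scoreScreen(sim$experiment)$hits
#' @export
scoreScreen <- function(experiment, gates = NULL, channel = "green",
                        alpha = 0.05, epsilonGuard = 0.02, stat = "mean") {
    if (is.null(names(experiment)) || !"EV" %in% names(experiment))
        dataError("experiment must be a named list including the EV condition")
    for (g in names(experiment)) {
        if (!all(c("injured", "uninjured") %in% names(experiment[[g]])))
            dataError(paste0("condition '", g, "' must have injured and ",
                             "uninjured arms"))
    }
    if (is.null(gates))
        gates <- defaultGates(experiment[["EV"]]$uninjured)
    reps <- sort(unique(eventData(experiment[["EV"]]$uninjured)$replicate))
    armSummaries <- function(tab) {
        gated <- gateEvents(tab, gates)$events
        ev <- gated@events
        lapply(stats::setNames(reps, reps), function(r) {
            sub <- FlowEventTable(ev[ev$replicate == r, , drop = FALSE])
            if (nEvents(sub) == 0L)
                dataError(paste0("replicate '", r, "' missing from a condition"))
            summarizePopulation(sub, channel = channel, stat = stat)
        })
    }
    ratios <- lapply(experiment, function(arms) {
        inj <- armSummaries(arms$injured)
        uninj <- armSummaries(arms$uninjured)
        lapply(stats::setNames(reps, reps),
               function(r) fluorescenceRatio(inj[[r]], uninj[[r]]))
    })
    results <- lapply(ratios, function(rg) {
        perRep <- lapply(reps, function(r)
            gfpIndex(ratios[["EV"]][[r]], rg[[r]], epsilonGuard = epsilonGuard))
        combineReplicates(perRep)
    })
    list(hits = callHits(results, alpha = alpha), results = results,
         gates = gates)
}
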
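# Gating of raw COPAS event tables and population summaries.

#' Derive default gates from an uninjured reference population
#'
#' The instrument's exact thresholds are not published, so gates are derived
#' from the adult medians of a reference (typically uninjured EV) table:
#' the TOF lower bound at 0.5x the median TOF removes larvae, the extinction
#' lower bound at 0.1x the median extinction removes *E. coli* debris (an
#' extinction cut targets bacteria, a length cut targets larvae), the
#' doublet bound is a flat extinction ceiling at 1.7x the median, and curled
#' worms are called at TOF < 0.6x with extinction > 1.2x the medians. The
#' red-channel death threshold sits midway (geometrically) between the live
#' baseline and the propidium-iodide-positive law.
#'
#' @param reference a [FlowEventTable-class] of an uninjured reference run.
#' @param tofMinScale,extMinScale,doubletExtScale,curlTofScale,curlExtScale
#'   multipliers applied to the reference medians.
#' @param redDeadThreshold red-channel threshold for dead objects.
#' @return A [GateConfig-class].
#' @examples
#' sim <- generateFlowEvents(flowSimConfig(nWorms = 500, seed = 1))
#' defaultGates(sim$events)
#' @export
defaultGates <- function(reference,
                         tofMinScale = 0.5, extMinScale = 0.1,
                         doubletExtScale = 1.7,
                         curlTofScale = 0.6, curlExtScale = 1.2,
                         redDeadThreshold = 50) {
    if (!methods::is(reference, "FlowEventTable"))
        dataError("reference must be a FlowEventTable")
    if (nEvents(reference) == 0L) dataError("reference table is empty")
    ev <- reference@events
    medTof <- stats::median(ev$tof)
    medExt <- stats::median(ev$extinction)
    GateConfig(extMin = extMinScale * medExt,
               tofMin = tofMinScale * medTof,
               doubletIntercept = doubletExtScale * medExt,
               doubletSlope = 0,
               curlTofMax = curlTofScale * medTof,
               curlExtMin = curlExtScale * medExt,
               redDeadThreshold = redDeadThreshold)
}

#' Gate a raw event table
#'
#' Flags contaminant events in the fixed order bacteria, larva, doublet,
#' curl; each event receives its first matching flag only. Bacteria are
#' events failing the extinction lower bound; larvae are events failing the
#' TOF lower bound whose extinction does not exceed the curl threshold (a
#' short but optically dense object is a coiled adult, not a larva, and is
#' left for the curl gate); events above the upper interval bounds or above the linear
#' doublet bound `ext > doubletIntercept + doubletSlope * tof` are doublets;
#' events with `tof < curlTofMax & ext > curlExtMin` are curled worms.
#' Intervals are closed-left, open-right: an event exactly at a lower bound
#' is retained. Dead objects (red above `redDeadThreshold`) are flagged in
#' the `dead` column but not removed. Gating is idempotent.
#'
#' @param events a [FlowEventTable-class].
#' @param gates a [GateConfig-class].
#' @return list with `events` (the flagged [FlowEventTable-class]) and
#'   `report`, a data.frame of events removed per gate in gate order plus
#'   the retained count.
#' @export
gateEvents <- function(events, gates) {
    if (!methods::is(events, "FlowEventTable"))
        dataError("events must be a FlowEventTable")
    if (!methods::is(gates, "GateConfig"))
        configError("gates must be a GateConfig")
    if (nEvents(events) == 0L) dataError("cannot gate an empty event table")
    ev <- events@events
    flag <- rep("", nrow(ev))
    unset <- function() !nzchar(flag)
    ## order matters: first matching flag only
    i <- unset() & ev$extinction < gates@extMin
    flag[i] <- "bacteria"
    ## short AND not optically dense: a short object with extinction above
    ## the curl threshold is a coiled adult, left for the curl gate
    i <- unset() & ev$tof < gates@tofMin & ev$extinction <= gates@curlExtMin
    flag[i] <- "larva"
    i <- unset() & (ev$extinction >= gates@extMax | ev$tof >= gates@tofMax |
                    ev$extinction > gates@doubletIntercept +
                                    gates@doubletSlope * ev$tof)
    flag[i] <- "doublet"
    i <- unset() & ev$tof < gates@curlTofMax & ev$extinction > gates@curlExtMin
    flag[i] <- "curl"
    ev$gate_flag <- flag
    ev$dead <- ev$red > gates@redDeadThreshold
    removed <- vapply(GATE_CLASSES, function(g) sum(flag == g), integer(1))
    if (all(nzchar(flag))) {
        dominant <- GATE_CLASSES[which.max(removed)]
        dataError(paste0("all events were gated out (dominant gate: ",
                         dominant, ")"))
    }
    report <- data.frame(gate = c(GATE_CLASSES, "retained"),
                         n = c(removed, sum(!nzchar(flag))),
                         stringsAsFactors = FALSE)
    list(events = FlowEventTable(ev), report = report)
}

#' Summarize a gated population on one channel
#'
#' Computes the arithmetic mean (default; the ratio algebra of the index
#' works on means), the n-1 standard deviation, the standard error of the
#' mean, and the 10/25/50/75/90th percentiles of retained (ungated) events.
#'
#' @param events a [FlowEventTable-class]; rows with a non-empty `gate_flag`
#'   are excluded.
#' @param channel one of `"green"`, `"red"`, `"tof"`, `"extinction"`.
#' @param stat `"mean"` (default) or `"median"` as the location estimate
#'   stored in the `mean` slot (sd/sem are always moment-based).
#' @return A [PopulationSummary-class].
#' @export
summarizePopulation <- function(events, channel = c("green", "red", "tof",
                                                    "extinction"),
                                stat = c("mean", "median")) {
    channel <- match.arg(channel)
    stat <- match.arg(stat)
    if (!methods::is(events, "FlowEventTable"))
        dataError("events must be a FlowEventTable")
    ev <- events@events[!nzchar(events@events$gate_flag), , drop = FALSE]
    if (nrow(ev) == 0L) dataError("no retained events to summarize")
    x <- ev[[channel]]
    n <- length(x)
    loc <- if (stat == "mean") mean(x) else stats::median(x)
    s <- sdOrZero(x)
    pct <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
    names(pct) <- c("p10", "p25", "p50", "p75", "p90")
    methods::new("PopulationSummary",
                 condition = paste(unique(ev$condition), collapse = "+"),
                 replicate = paste(unique(ev$replicate), collapse = "+"),
                 channel = channel, n = as.integer(n),
                 mean = loc, sd = s, sem = s / sqrt(n), percentiles = pct)
}

#' Select events within an empirical percentile band
#'
#' Keeps events whose channel value lies within the `[lo, hi)` empirical
#' percentile band (linear-interpolation percentile definition, i.e.
#' [stats::quantile()] type 7). `hi = 100` closes the upper end so that
#' `(0, 100)` is the identity and complementary bands partition the table.
#' Used e.g. to extract the bottom decile of dopaminergic GFP intensity.
#'
#' @param events a [FlowEventTable-class].
#' @param channel channel to rank on.
#' @param lo,hi percentile bounds, `0 <= lo < hi <= 100`.
#' @return The subset [FlowEventTable-class].
#' @export
selectPercentile <- function(events, channel = c("green", "red", "tof",
                                                 "extinction"),
                             lo = 0, hi = 100) {
    channel <- match.arg(channel)
    if (!(lo >= 0 && lo < hi && hi <= 100))
        configError("percentile bounds must satisfy 0 <= lo < hi <= 100")
    if (!methods::is(events, "FlowEventTable"))
        dataError("events must be a FlowEventTable")
    ev <- events@events
    if (nrow(ev) == 0L) dataError("empty event table")
    x <- ev[[channel]]
    qlo <- stats::quantile(x, lo / 100, names = FALSE, type = 7)
    qhi <- stats::quantile(x, hi / 100, names = FALSE, type = 7)
    keep <- x >= qlo & (if (hi == 100) x <= qhi else x < qhi)
    FlowEventTable(ev[keep, , drop = FALSE])
}

#' Fraction of dead (propidium-iodide-positive) worms
#'
#' @param events a gated [FlowEventTable-class]; only retained events count.
#' @param redDeadThreshold red-channel threshold separating dead worms.
#' @return list with `fraction`, `nDead`, `n`, and the Wilson 95% CI
#'   (`ciLow`, `ciHigh`).
#' @export
deadFraction <- function(events, redDeadThreshold) {
    if (!methods::is(events, "FlowEventTable"))
        dataError("events must be a FlowEventTable")
    ev <- events@events[!nzchar(events@events$gate_flag), , drop = FALSE]
    if (nrow(ev) == 0L) dataError("no retained events")
    dead <- ev$red > redDeadThreshold
    ci <- wilsonInterval(sum(dead), length(dead))
    list(fraction = mean(dead), nDead = sum(dead), n = length(dead),
         ciLow = unname(ci[1]), ciHigh = unname(ci[2]))
}

#' Normalize an injured time course to age-matched uninjured controls
#'
#' For each timepoint the injured mean fluorescence is divided by the mean of
#' the age-matched uninjured population, with the uncertainty propagated by
#' the quadrature quotient rule (see [fluorescenceRatio()]).
#'
#' @param injured named list of [PopulationSummary-class] objects, one per
#'   timepoint.
#' @param uninjured named list with the same timepoint names.
#' @return data.frame with one row per timepoint: normalized `value`, its
#'   propagated `delta`, and 95% normal bounds.
#' @export
normalizeTimecourse <- function(injured, uninjured) {
    tp <- names(injured)
    if (is.null(tp) || !setequal(tp, names(uninjured)))
        dataError("injured and uninjured summaries must share timepoint names")
    z <- stats::qnorm(0.975)
    rows <- lapply(tp, function(t) {
        r <- fluorescenceRatio(injured[[t]], uninjured[[t]])
        data.frame(timepoint = t, value = r@value, delta = r@delta,
                   ciLow = r@value - z * r@delta,
                   ciHigh = r@value + z * r@delta,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
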
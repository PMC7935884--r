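# S4 containers for the screen pipeline.

FLOW_COLUMNS <- c("event_id", "tof", "extinction", "green", "red",
                  "condition", "replicate")
CHANNELS <- c("tof", "extinction", "green", "red")
GATE_CLASSES <- c("bacteria", "larva", "doublet", "curl")

#' FlowEventTable: per-object large-particle flow-cytometry events
#'
#' One row per detected object from a COPAS-style sorter: time-of-flight
#' (`tof`, a length proxy), `extinction` (optical density), `green` and `red`
#' fluorescence, plus `condition` and `replicate` labels. Gating adds a
#' `gate_flag` column (`""` for retained events, otherwise the first matching
#' contaminant class among bacteria/larva/doublet/curl) and a logical `dead`
#' column (red channel above the propidium-iodide threshold).
#'
#' @slot events data.frame with the columns above.
#' @seealso [gateEvents()], [summarizePopulation()], [generateFlowEvents()]
#' @export
setClass("FlowEventTable", slots = c(events = "data.frame"))

setValidity("FlowEventTable", function(object) {
    ev <- object@events
    missing <- setdiff(FLOW_COLUMNS, names(ev))
    if (length(missing))
        return(paste("missing required columns:", paste(missing, collapse = ", ")))
    for (ch in CHANNELS) {
        if (!is.numeric(ev[[ch]]))
            return(paste0("column '", ch, "' must be numeric"))
        if (any(!is.na(ev[[ch]]) & ev[[ch]] < 0))
            return(paste0("channel '", ch, "' contains negative values"))
    }
    if (nrow(ev) && (any(!nzchar(ev$condition)) || any(!nzchar(ev$replicate))))
        return("condition/replicate labels must be non-empty")
    if (!is.character(ev$gate_flag))
        return("gate_flag must be character")
    bad <- setdiff(unique(ev$gate_flag), c("", GATE_CLASSES))
    if (length(bad))
        return(paste("unknown gate_flag value(s):", paste(bad, collapse = ", ")))
    if (!is.logical(ev$dead))
        return("dead must be logical")
    TRUE
})

#' Construct a FlowEventTable
#'
#' @param events data.frame with at least the columns `event_id`, `tof`,
#'   `extinction`, `green`, `red`, `condition`, `replicate`. `gate_flag`
#'   (character) and `dead` (logical) are added if absent.
#' @return A [FlowEventTable-class] object.
#' @examples
#' ft <- FlowEventTable(data.frame(
#'     event_id = "e1", tof = 900, extinction = 210, green = 150, red = 4,
#'     condition = "EV", replicate = "r1"))
#' nEvents(ft)
#' @export
FlowEventTable <- function(events) {
    events <- as.data.frame(events)
    if (is.null(events$gate_flag)) events$gate_flag <- rep("", nrow(events))
    if (is.null(events$dead)) events$dead <- rep(FALSE, nrow(events))
    events$condition <- as.character(events$condition)
    events$replicate <- as.character(events$replicate)
    events$gate_flag <- as.character(events$gate_flag)
    rownames(events) <- NULL
    methods::new("FlowEventTable", events = events)
}

#' ExpressionMatrix: gene-by-sample expression values
#'
#' A light container for gene x sample (or gene x dataset) values: raw
#' intensities, counts, linear fold changes or log2 fold changes, with the
#' kind recorded so downstream operations know whether to log-transform.
#' `NaN`/`NA` entries are permitted.
#'
#' @slot values numeric matrix; rownames are unique gene identifiers,
#'   colnames are sample/dataset labels.
#' @slot kind one of `"intensity"`, `"count"`, `"fc"` (linear fold change) or
#'   `"log2fc"`.
#' @export
setClass("ExpressionMatrix",
         slots = c(values = "matrix", kind = "character"))

setValidity("ExpressionMatrix", function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be a numeric matrix")
    if (ncol(v) < 1L) return("at least one column required")
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
        return("rownames must be unique gene identifiers")
    if (length(object@kind) != 1L ||
        !object@kind %in% c("intensity", "count", "fc", "log2fc"))
        return("kind must be one of intensity/count/fc/log2fc")
    TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix with gene rownames and sample colnames.
#' @param kind value kind; see [ExpressionMatrix-class].
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("a", "b")))
#' ExpressionMatrix(m, kind = "log2fc")
#' @export
ExpressionMatrix <- function(values, kind = c("intensity", "count", "fc", "log2fc")) {
    kind <- match.arg(kind)
    methods::new("ExpressionMatrix", values = as.matrix(values), kind = kind)
}

#' GateConfig: gating thresholds for COPAS event tables
#'
#' Gates are fully configuration-driven (the instrument-specific thresholds
#' live in supplementary material, not in code). Events failing the extinction
#' lower bound are flagged bacteria, events failing the TOF lower bound are
#' flagged larvae, events above the linear doublet bound
#' `extinction > doubletIntercept + doubletSlope * tof` are flagged doublets,
#' and events with `tof < curlTofMax & extinction > curlExtMin` are flagged
#' curled worms. `redDeadThreshold` marks propidium-iodide-positive (dead)
#' objects on the red channel.
#'
#' @seealso [defaultGates()], [gateEvents()]
#' @export
setClass("GateConfig",
         slots = c(extMin = "numeric", extMax = "numeric",
                   tofMin = "numeric", tofMax = "numeric",
                   doubletIntercept = "numeric", doubletSlope = "numeric",
                   curlTofMax = "numeric", curlExtMin = "numeric",
                   redDeadThreshold = "numeric"))

setValidity("GateConfig", function(object) {
    for (s in methods::slotNames(object)) {
        v <- methods::slot(object, s)
        if (length(v) != 1L || is.na(v))
            return(paste0("slot '", s, "' must be a single non-NA number"))
    }
    if (object@extMin >= object@extMax) return("extMin must be < extMax")
    if (object@tofMin >= object@tofMax) return("tofMin must be < tofMax")
    TRUE
})

#' Construct a GateConfig
#'
#' @param extMin,extMax extinction interval retained (closed-left, open-right).
#' @param tofMin,tofMax time-of-flight interval retained.
#' @param doubletIntercept,doubletSlope linear doublet bound on (tof, ext).
#' @param curlTofMax,curlExtMin curled-worm rule (low TOF, high extinction).
#' @param redDeadThreshold red-channel threshold for dead objects.
#' @return A [GateConfig-class] object.
#' @export
GateConfig <- function(extMin, extMax = Inf, tofMin, tofMax = Inf,
                       doubletIntercept = Inf, doubletSlope = 0,
                       curlTofMax = 0, curlExtMin = Inf,
                       redDeadThreshold = Inf) {
    methods::new("GateConfig", extMin = extMin, extMax = extMax,
                 tofMin = tofMin, tofMax = tofMax,
                 doubletIntercept = doubletIntercept, doubletSlope = doubletSlope,
                 curlTofMax = curlTofMax, curlExtMin = curlExtMin,
                 redDeadThreshold = redDeadThreshold)
}

#' PopulationSummary: per-condition, per-replicate channel summary
#'
#' @slot condition,replicate labels of the summarized population.
#' @slot channel summarized channel.
#' @slot n number of retained events.
#' @slot mean,sd,sem arithmetic mean, n-1 standard deviation, `sd/sqrt(n)`.
#' @slot percentiles named numeric vector (10/25/50/75/90th percentiles).
#' @export
setClass("PopulationSummary",
         slots = c(condition = "character", replicate = "character",
                   channel = "character", n = "integer",
                   mean = "numeric", sd = "numeric", sem = "numeric",
                   percentiles = "numeric"))

setValidity("PopulationSummary", function(object) {
    if (object@n < 1L) return("n must be >= 1")
    if (object@sd < 0) return("sd must be >= 0")
    if (abs(object@sem - object@sd / sqrt(object@n)) >
        1e-8 * (object@sd + 1e-300)) return("sem must equal sd/sqrt(n)")
    TRUE
})

#' RatioWithError: injured/uninjured fluorescence ratio with propagated error
#'
#' The retained-fluorescence ratio for one condition and replicate
#' (mean injured over mean uninjured), with its uncertainty from the
#' quadrature quotient rule.
#'
#' @slot value the ratio (dimensionless, > 0).
#' @slot delta propagated error of the ratio.
#' @slot nInjured,nUninjured event counts of the two arms.
#' @seealso [fluorescenceRatio()]
#' @export
setClass("RatioWithError",
         slots = c(value = "numeric", delta = "numeric",
                   nInjured = "integer", nUninjured = "integer"))

setValidity("RatioWithError", function(object) {
    if (object@value <= 0) return("value must be > 0")
    if (object@delta < 0) return("delta must be >= 0")
    TRUE
})

#' IndexResult: Dopaminergic GFP Index with propagated uncertainty
#'
#' Holds the index (1 = fluorescence fully retained relative to uninjured
#' controls, 0 = same loss as the empty-vector control, negative = increased
#' loss), the within-replicate quadrature error, the between-replicate SEM,
#' their quadrature combination, and the 95% normal confidence bounds.
#'
#' @slot index combined index (mean over replicates).
#' @slot deltaWithin quadrature-propagated within-replicate error, scaled as
#'   an error of the mean.
#' @slot deltaBetween SEM of the per-replicate indices.
#' @slot deltaTotal `sqrt(deltaWithin^2 + deltaBetween^2)`.
#' @slot ciLow,ciHigh 95% confidence bounds.
#' @slot nReplicates number of biological replicates combined.
#' @slot replicateIndices the per-replicate indices.
#' @seealso [gfpIndex()], [combineReplicates()]
#' @export
setClass("IndexResult",
         slots = c(index = "numeric", deltaWithin = "numeric",
                   deltaBetween = "numeric", deltaTotal = "numeric",
                   ciLow = "numeric", ciHigh = "numeric",
                   nReplicates = "integer", replicateIndices = "numeric"))

setValidity("IndexResult", function(object) {
    if (object@deltaWithin < 0 || object@deltaBetween < 0)
        return("error components must be >= 0")
    tot <- sqrt(object@deltaWithin^2 + object@deltaBetween^2)
    if (abs(object@deltaTotal - tot) > 1e-8 * (tot + 1e-300))
        return("deltaTotal must combine the components in quadrature")
    if (object@ciLow > object@index || object@ciHigh < object@index)
        return("confidence bounds must bracket the index")
    TRUE
})

#' CorrelationMatrix: cross-dataset Pearson correlations
#'
#' @slot r symmetric Pearson correlation matrix with unit diagonal.
#' @slot nGenesUsed number of complete-case genes the matrix was computed on.
#' @seealso [crossCorrelate()]
#' @export
setClass("CorrelationMatrix",
         slots = c(r = "matrix", nGenesUsed = "integer"))

setValidity("CorrelationMatrix", function(object) {
    r <- object@r
    if (nrow(r) != ncol(r)) return("r must be square")
    if (max(abs(r - t(r))) > 1e-12) return("r must be symmetric")
    if (max(abs(diag(r) - 1)) > 1e-12) return("diagonal must be 1")
    if (any(abs(r) > 1 + 1e-12)) return("|r| must be <= 1")
    TRUE
})

## ---- show methods -----------------------------------------------------------

setMethod("show", "FlowEventTable", function(object) {
    ev <- object@events
    gated <- sum(nzchar(ev$gate_flag))
    cat("FlowEventTable with", nrow(ev), "events |",
        length(unique(ev$condition)), "condition(s),",
        length(unique(ev$replicate)), "replicate(s)\n")
    if (gated) {
        tab <- table(ev$gate_flag[nzchar(ev$gate_flag)])
        cat("  gated out:", paste(names(tab), tab, sep = "=", collapse = ", "),
            "| retained:", nrow(ev) - gated, "\n")
    }
})

setMethod("show", "ExpressionMatrix", function(object) {
    cat("ExpressionMatrix:", nrow(object@values), "genes x",
        ncol(object@values), "columns |", "kind:", object@kind, "|",
        sum(is.na(object@values)), "missing values\n")
})

setMethod("show", "GateConfig", function(object) {
    cat(sprintf(paste0("GateConfig: ext [%.4g, %.4g), tof [%.4g, %.4g), ",
                       "doublet ext > %.4g + %.4g*tof,\n",
                       "  curl (tof < %.4g & ext > %.4g), dead red > %.4g\n"),
                object@extMin, object@extMax, object@tofMin, object@tofMax,
                object@doubletIntercept, object@doubletSlope,
                object@curlTofMax, object@curlExtMin, object@redDeadThreshold))
})

setMethod("show", "PopulationSummary", function(object) {
    cat(sprintf("PopulationSummary [%s/%s] %s: n=%d mean=%.6g sd=%.6g sem=%.6g\n",
                object@condition, object@replicate, object@channel,
                object@n, object@mean, object@sd, object@sem))
})

setMethod("show", "RatioWithError", function(object) {
    cat(sprintf("RatioWithError: %.6g +/- %.3g (n injured=%d, uninjured=%d)\n",
                object@value, object@delta, object@nInjured, object@nUninjured))
})

setMethod("show", "IndexResult", function(object) {
    cat(sprintf(paste0("Dopaminergic GFP Index: %.4g  95%% CI [%.4g, %.4g]\n",
                       "  delta within=%.4g between=%.4g total=%.4g  (%d replicate(s))\n"),
                object@index, object@ciLow, object@ciHigh, object@deltaWithin,
                object@deltaBetween, object@deltaTotal, object@nReplicates))
})

setMethod("show", "CorrelationMatrix", function(object) {
    cat("CorrelationMatrix over", nrow(object@r), "datasets |",
        object@nGenesUsed, "complete-case genes\n")
    print(round(object@r, 3))
})
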
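# Accessor generics and methods.

#' Accessors for pipeline containers
#'
#' `eventData()` returns the underlying event data.frame, `nEvents()` the
#' event count, `retainedEvents()` the subset passing all gates,
#' `gateFlags()` the per-event flag vector, `exprValues()` the numeric matrix
#' of an [ExpressionMatrix-class], `exprKind()` its value kind,
#' `corValues()` the correlation matrix of a [CorrelationMatrix-class], and
#' `indexEstimate()` / `confint()`-style bounds come from
#' [IndexResult-class] slots via `indexEstimate()` and `indexCI()`.
#'
#' @param x the object.
#' @return See details above.
#' @name accessors
#' @aliases eventData nEvents retainedEvents gateFlags exprValues exprKind
#'   corValues indexEstimate indexCI
#' @examples
#' ft <- FlowEventTable(data.frame(
#'     event_id = 1:2, tof = c(900, 950), extinction = c(200, 220),
#'     green = c(150, 140), red = c(5, 4), condition = "EV", replicate = "r1"))
#' nEvents(ft)
#' head(eventData(ft))
NULL

#' @rdname accessors
#' @export
setGeneric("eventData", function(x) standardGeneric("eventData"))
#' @rdname accessors
#' @export
setMethod("eventData", "FlowEventTable", function(x) x@events)

#' @rdname accessors
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))
#' @rdname accessors
#' @export
setMethod("nEvents", "FlowEventTable", function(x) nrow(x@events))

#' @rdname accessors
#' @export
setGeneric("retainedEvents", function(x) standardGeneric("retainedEvents"))
#' @rdname accessors
#' @export
setMethod("retainedEvents", "FlowEventTable", function(x) {
    FlowEventTable(x@events[!nzchar(x@events$gate_flag), , drop = FALSE])
})

#' @rdname accessors
#' @export
setGeneric("gateFlags", function(x) standardGeneric("gateFlags"))
#' @rdname accessors
#' @export
setMethod("gateFlags", "FlowEventTable", function(x) x@events$gate_flag)

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("exprKind", function(x) standardGeneric("exprKind"))
#' @rdname accessors
#' @export
setMethod("exprKind", "ExpressionMatrix", function(x) x@kind)

#' @rdname accessors
#' @export
setGeneric("corValues", function(x) standardGeneric("corValues"))
#' @rdname accessors
#' @export
setMethod("corValues", "CorrelationMatrix", function(x) x@r)

#' @rdname accessors
#' @export
setGeneric("indexEstimate", function(x) standardGeneric("indexEstimate"))
#' @rdname accessors
#' @export
setMethod("indexEstimate", "IndexResult", function(x) x@index)

#' @rdname accessors
#' @export
setGeneric("indexCI", function(x) standardGeneric("indexCI"))
#' @rdname accessors
#' @export
setMethod("indexCI", "IndexResult", function(x) c(lower = x@ciLow, upper = x@ciHigh))
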
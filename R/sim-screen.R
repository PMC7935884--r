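# Whole-screen simulator: planted per-gene indices, replicate structure.

#' ScreenSimConfig: a simulated RNAi screen with planted indices
#'
#' Each gene condition (plus the mandatory empty-vector control `"EV"`) gets
#' an injured and an uninjured arm in every replicate. The injured-arm GFP
#' retention factor for gene *g* is chosen so the population-level index
#' equals the planted value exactly in expectation:
#' `factor_g = 1 - (1 - trueIndex_g) * (1 - evInjuryGfpFactor)`.
#' On top of that, the *delivered* injury varies between tubes: the GFP loss
#' of each condition x replicate is jittered by an independent lognormal
#' factor `exp(N(0, replicateInjurySd))`, emulating day-to-day variation in
#' agitation severity (each condition is injured in its own tube).
#'
#' @slot genes condition labels, including `"EV"`.
#' @slot trueIndex named planted index per gene; `trueIndex["EV"] == 0` by
#'   construction.
#' @slot evInjuryGfpFactor GFP retention of injured EV worms, in (0, 1).
#' @slot nReplicates biological replicates.
#' @slot replicateInjurySd sdlog of the per-tube injury-severity jitter.
#' @slot flowConfig template [FlowSimConfig-class] for every arm.
#' @slot seed integer master seed.
#' @export
setClass("ScreenSimConfig",
         slots = c(genes = "character", trueIndex = "numeric",
                   evInjuryGfpFactor = "numeric", nReplicates = "integer",
                   replicateInjurySd = "numeric",
                   flowConfig = "FlowSimConfig", seed = "integer"))

setValidity("ScreenSimConfig", function(object) {
    if (!"EV" %in% object@genes) return("genes must include the EV control")
    if (!setequal(names(object@trueIndex), object@genes))
        return("trueIndex must be named by genes")
    if (abs(object@trueIndex[["EV"]]) > 0)
        return("trueIndex for EV must be 0")
    if (object@evInjuryGfpFactor <= 0 || object@evInjuryGfpFactor >= 1)
        return("evInjuryGfpFactor must lie in (0, 1)")
    if (object@nReplicates < 1L) return("nReplicates must be >= 1")
    if (object@replicateInjurySd < 0) return("replicateInjurySd must be >= 0")
    TRUE
})

#' Construct a ScreenSimConfig
#'
#' @param genes gene labels; `"EV"` is added if absent.
#' @param trueIndex named numeric of planted indices (EV fixed at 0; omitted
#'   genes default to 0).
#' @param evInjuryGfpFactor injured/uninjured GFP retention of the EV arm.
#' @param nReplicates biological replicates.
#' @param replicateInjurySd per-tube lognormal injury jitter (sdlog).
#' @param flowConfig template [FlowSimConfig-class]; its condition/replicate/
#'   injury fields are overridden per arm.
#' @param seed integer master seed.
#' @return A [ScreenSimConfig-class] object.
#' @examples
#' cfg <- screenSimConfig(genes = c("EV", "geneA"),
#'                        trueIndex = c(geneA = 0.8),
#'                        flowConfig = flowSimConfig(nWorms = 200), seed = 1)
#' sim <- generateScreenExperiment(cfg)
#' names(sim$experiment)
#' @export
screenSimConfig <- function(genes, trueIndex = NULL,
                            evInjuryGfpFactor = 0.5, nReplicates = 3L,
                            replicateInjurySd = 0.05,
                            flowConfig = flowSimConfig(), seed = 1L) {
    genes <- unique(c("EV", genes))
    ti <- stats::setNames(rep(0, length(genes)), genes)
    if (!is.null(trueIndex)) ti[names(trueIndex)] <- trueIndex
    ti[["EV"]] <- 0
    ## a planted index t requires factor_g = 1 - (1-t)(1-f_ev) in (0, 1]
    lossBase <- 1 - evInjuryGfpFactor
    factors <- 1 - (1 - ti) * lossBase
    if (any(factors <= 0))
        configError(paste("planted index too negative for evInjuryGfpFactor:",
                          "implied GFP factor would be <= 0 for",
                          paste(genes[factors <= 0], collapse = ", ")))
    obj <- try(methods::new("ScreenSimConfig", genes = genes, trueIndex = ti,
                            evInjuryGfpFactor = evInjuryGfpFactor,
                            nReplicates = as.integer(nReplicates),
                            replicateInjurySd = replicateInjurySd,
                            flowConfig = flowConfig, seed = as.integer(seed)),
               silent = TRUE)
    if (inherits(obj, "try-error"))
        configError(paste("invalid screen simulation configuration:",
                          attr(obj, "condition")$message))
    obj
}

#' Generate a full simulated screen with ground truth
#'
#' For every gene and replicate, draws the realized injury severity (the
#' planted GFP loss times the per-tube jitter), then generates injured and
#' uninjured event tables from independent child streams of the master seed.
#'
#' @param config a [ScreenSimConfig-class].
#' @return list with
#'   * `experiment`: named list (one entry per gene) of lists with
#'     `injured` and `uninjured` [FlowEventTable-class] objects covering all
#'     replicates;
#'   * `truth`: list with `trueIndex` (planted indices), `realizedFactor`
#'     (gene x replicate matrix of delivered GFP retention factors),
#'     `realizedIndex` (gene x replicate matrix of per-tube indices implied
#'     by the realized factors), and `events` (per-event truth tables).
#' @seealso [scoreScreen()]
#' @export
generateScreenExperiment <- function(config) {
    if (!methods::is(config, "ScreenSimConfig"))
        configError("config must be a ScreenSimConfig")
    methods::validObject(config)
    genes <- config@genes
    reps <- paste0("r", seq_len(config@nReplicates))
    lossBase <- 1 - config@evInjuryGfpFactor
    realizedFactor <- matrix(NA_real_, length(genes), length(reps),
                             dimnames = list(genes, reps))
    experiment <- list()
    eventTruth <- list()
    for (g in genes) {
        plantedLoss <- (1 - config@trueIndex[[g]]) * lossBase
        injTabs <- uninjTabs <- vector("list", length(reps))
        truthTabs <- vector("list", 2L * length(reps))
        for (r in seq_along(reps)) {
            jitter <- withr::with_seed(
                childSeed(config@seed, "injury", g, reps[r]),
                exp(stats::rnorm(1, 0, config@replicateInjurySd)))
            loss <- min(plantedLoss * jitter, 0.99)
            realizedFactor[g, r] <- 1 - loss
            base <- config@flowConfig
            base@condition <- g
            base@replicate <- reps[r]
            base@seed <- config@seed
            inj <- base
            inj@injured <- TRUE
            inj@injuryGfpFactor <- 1 - loss
            uninj <- base
            uninj@injured <- FALSE
            simI <- generateFlowEvents(inj)
            simU <- generateFlowEvents(uninj)
            injTabs[[r]] <- simI$events@events
            uninjTabs[[r]] <- simU$events@events
            truthTabs[[2L * r - 1L]] <- simI$truth
            truthTabs[[2L * r]] <- simU$truth
        }
        experiment[[g]] <- list(
            injured = FlowEventTable(do.call(rbind, injTabs)),
            uninjured = FlowEventTable(do.call(rbind, uninjTabs)))
        eventTruth[[g]] <- do.call(rbind, truthTabs)
    }
    af <- config@flowConfig@injuryAffectedFraction
    ## per-tube index implied by the realized factors: the affected fraction
    ## cancels between numerator and denominator
    evLoss <- 1 - realizedFactor["EV", ]
    realizedIndex <- 1 - t(t(1 - realizedFactor) / evLoss)
    list(experiment = experiment,
         truth = list(trueIndex = config@trueIndex,
                      realizedFactor = realizedFactor,
                      realizedIndex = realizedIndex,
                      affectedFraction = af,
                      events = eventTruth))
}
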
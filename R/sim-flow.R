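# Synthetic COPAS event generator with planted ground truth.

# Contaminant channel scales relative to the adult laws; chosen so each class
# sits on the documented side of its gate (larvae < 0.4x adult medians,
# bacteria < 0.05x, curls TOF < 0.6x with extinction > 1.2x).
LARVA_SCALE <- 0.3
BACTERIA_SCALE <- 0.02
CURL_TOF_SCALE <- 0.4
CURL_EXT_SCALE <- 1.43
RED_BASE_MEANLOG <- log(5)
RED_DEAD_MEANLOG <- log(500)
RED_SDLOG <- 0.25

#' FlowSimConfig: parameters of one simulated cytometry run
#'
#' Per-object optics are lognormal (cytometry intensities are right-skewed).
#' Contaminant subpopulations are parameterized relative to the adult medians
#' so that gates can be derived from configuration alone. Injury is a
#' two-component mixture: a Bernoulli(`injuryAffectedFraction`) subset of
#' worms has its green (GFP) channel multiplied by `injuryGfpFactor`,
#' reflecting per-worm heterogeneity in neuronal loss.
#'
#' @slot nWorms number of events to generate.
#' @slot adultTofMeanlog,adultTofSdlog lognormal parameters of adult
#'   time-of-flight (a.u.).
#' @slot adultExtMeanlog,adultExtSdlog lognormal parameters of adult
#'   extinction (a.u.).
#' @slot gfpMeanlog,gfpSdlog lognormal parameters of the dopaminergic GFP
#'   reporter (a.u.).
#' @slot injuryAffectedFraction fraction of worms losing GFP after injury.
#' @slot injuryGfpFactor multiplicative GFP retention in affected worms
#'   (in (0, 1]).
#' @slot contaminantFractions named fractions for larva/bacteria/doublet/curl.
#' @slot redDeathFraction fraction of worms stained propidium-iodide positive.
#' @slot condition,replicate labels stamped on the events.
#' @slot injured whether this run is an injured arm.
#' @slot seed integer master seed; events are drawn from a child stream keyed
#'   by (seed, condition, replicate, arm).
#' @export
setClass("FlowSimConfig",
         slots = c(nWorms = "integer",
                   adultTofMeanlog = "numeric", adultTofSdlog = "numeric",
                   adultExtMeanlog = "numeric", adultExtSdlog = "numeric",
                   gfpMeanlog = "numeric", gfpSdlog = "numeric",
                   injuryAffectedFraction = "numeric",
                   injuryGfpFactor = "numeric",
                   contaminantFractions = "numeric",
                   redDeathFraction = "numeric",
                   condition = "character", replicate = "character",
                   injured = "logical", seed = "integer"))

setValidity("FlowSimConfig", function(object) {
    if (object@nWorms < 1L) return("nWorms must be positive")
    if (object@adultTofSdlog <= 0 || object@adultExtSdlog <= 0 ||
        object@gfpSdlog <= 0) return("sdlog parameters must be > 0")
    if (object@injuryAffectedFraction < 0 || object@injuryAffectedFraction > 1)
        return("injuryAffectedFraction must lie in [0, 1]")
    if (object@injuryGfpFactor <= 0 || object@injuryGfpFactor > 1)
        return("injuryGfpFactor must lie in (0, 1]")
    cf <- object@contaminantFractions
    if (!setequal(names(cf), GATE_CLASSES))
        return("contaminantFractions must be named larva/bacteria/doublet/curl")
    if (any(cf < 0) || any(cf >= 1)) return("contaminant fractions must lie in [0, 1)")
    if (sum(cf) >= 1) return("contaminant fractions must sum to < 1")
    if (object@redDeathFraction < 0 || object@redDeathFraction > 1)
        return("redDeathFraction must lie in [0, 1]")
    TRUE
})

#' Construct a FlowSimConfig
#'
#' Defaults emulate a day-1 adult, age-synchronized population: tight adult
#' TOF/extinction laws (sdlog 0.1), a broader GFP reporter law (sdlog 0.5),
#' 80% of worms affected by a paralytic injury that halves their retained
#' GFP, and realistic low contaminant loads.
#'
#' @param nWorms events per run.
#' @param adultTofMeanlog,adultTofSdlog,adultExtMeanlog,adultExtSdlog,gfpMeanlog,gfpSdlog
#'   lognormal channel parameters.
#' @param injuryAffectedFraction,injuryGfpFactor injury mixture parameters.
#' @param contaminantFractions named numeric for larva/bacteria/doublet/curl.
#' @param redDeathFraction fraction of dead (PI-positive) worms.
#' @param condition,replicate,injured labels for the run.
#' @param seed integer master seed.
#' @return A [FlowSimConfig-class] object.
#' @examples
#' cfg <- flowSimConfig(nWorms = 200, seed = 1)
#' sim <- generateFlowEvents(cfg)
#' sim$events
#' @export
flowSimConfig <- function(nWorms = 500L,
                          adultTofMeanlog = log(1000), adultTofSdlog = 0.1,
                          adultExtMeanlog = log(200), adultExtSdlog = 0.1,
                          gfpMeanlog = log(150), gfpSdlog = 0.5,
                          injuryAffectedFraction = 0.8,
                          injuryGfpFactor = 0.5,
                          contaminantFractions = c(larva = 0.05, bacteria = 0.03,
                                                   doublet = 0.02, curl = 0.02),
                          redDeathFraction = 0,
                          condition = "EV", replicate = "r1",
                          injured = FALSE, seed = 1L) {
    if (!is.numeric(nWorms) || length(nWorms) != 1L || is.na(nWorms) || nWorms < 1)
        configError("nWorms must be a positive count")
    cf <- contaminantFractions[GATE_CLASSES]
    names(cf) <- GATE_CLASSES
    if (anyNA(cf)) configError("contaminantFractions must name larva/bacteria/doublet/curl")
    obj <- try(methods::new("FlowSimConfig",
                            nWorms = as.integer(nWorms),
                            adultTofMeanlog = adultTofMeanlog,
                            adultTofSdlog = adultTofSdlog,
                            adultExtMeanlog = adultExtMeanlog,
                            adultExtSdlog = adultExtSdlog,
                            gfpMeanlog = gfpMeanlog, gfpSdlog = gfpSdlog,
                            injuryAffectedFraction = injuryAffectedFraction,
                            injuryGfpFactor = injuryGfpFactor,
                            contaminantFractions = cf,
                            redDeathFraction = redDeathFraction,
                            condition = condition, replicate = replicate,
                            injured = injured, seed = as.integer(seed)),
               silent = TRUE)
    if (inherits(obj, "try-error"))
        configError(paste("invalid flow simulation configuration:",
                          attr(obj, "condition")$message))
    obj
}

#' Generate one synthetic COPAS event table with ground truth
#'
#' Draws `nWorms` events: adults from the configured lognormal laws; larvae
#' with all channels scaled to 0.3x the adult draws; bacteria at 0.02x the
#' adult medians (green near zero); doublets as channel-wise sums of two
#' independent adult draws; curled worms with TOF scaled to 0.4x and
#' extinction to 1.43x. In injured arms a Bernoulli subset of worm-class
#' events (adults, both doublet components, curls) has green multiplied by
#' `injuryGfpFactor`. Dead worms get a red channel drawn from a clearly
#' separated high law. Identical configurations yield identical tables.
#'
#' @param config a [FlowSimConfig-class].
#' @return list with `events` (a [FlowEventTable-class]) and `truth`, a
#'   data.frame of per-event true class, affected and dead status.
#' @export
generateFlowEvents <- function(config) {
    if (!methods::is(config, "FlowSimConfig"))
        configError("config must be a FlowSimConfig")
    methods::validObject(config)
    n <- config@nWorms
    cf <- config@contaminantFractions
    probs <- c(adult = 1 - sum(cf), cf)
    arm <- if (config@injured) "injured" else "uninjured"
    stream <- childSeed(config@seed, config@condition, config@replicate, arm)
    withr::with_seed(stream, {
        cls <- sample(names(probs), n, replace = TRUE, prob = probs)
        tof <- stats::rlnorm(n, config@adultTofMeanlog, config@adultTofSdlog)
        ext <- stats::rlnorm(n, config@adultExtMeanlog, config@adultExtSdlog)
        grn <- stats::rlnorm(n, config@gfpMeanlog, config@gfpSdlog)
        red <- stats::rlnorm(n, RED_BASE_MEANLOG, RED_SDLOG)
        affected <- rep(FALSE, n)
        wormLike <- cls %in% c("adult", "doublet", "curl")
        if (config@injured && config@injuryAffectedFraction > 0) {
            affected[wormLike] <- stats::runif(sum(wormLike)) <
                config@injuryAffectedFraction
            grn[affected] <- grn[affected] * config@injuryGfpFactor
        }
        ## larvae: whole animal scaled down
        i <- cls == "larva"
        tof[i] <- tof[i] * LARVA_SCALE
        ext[i] <- ext[i] * LARVA_SCALE
        grn[i] <- grn[i] * LARVA_SCALE
        ## bacteria: debris-level signal on every channel
        i <- cls == "bacteria"
        medTof <- exp(config@adultTofMeanlog)
        medExt <- exp(config@adultExtMeanlog)
        tof[i] <- BACTERIA_SCALE * medTof *
            exp(stats::rnorm(sum(i), 0, config@adultTofSdlog))
        ext[i] <- BACTERIA_SCALE * medExt *
            exp(stats::rnorm(sum(i), 0, config@adultExtSdlog))
        grn[i] <- 0.01 * exp(config@gfpMeanlog) *
            exp(stats::rnorm(sum(i), 0, config@gfpSdlog))
        ## doublets: channel-wise sum of two adult draws; the second animal
        ## receives its own injury Bernoulli
        i <- cls == "doublet"
        n2 <- sum(i)
        if (n2) {
            tof2 <- stats::rlnorm(n2, config@adultTofMeanlog, config@adultTofSdlog)
            ext2 <- stats::rlnorm(n2, config@adultExtMeanlog, config@adultExtSdlog)
            grn2 <- stats::rlnorm(n2, config@gfpMeanlog, config@gfpSdlog)
            red2 <- stats::rlnorm(n2, RED_BASE_MEANLOG, RED_SDLOG)
            if (config@injured && config@injuryAffectedFraction > 0) {
                hit2 <- stats::runif(n2) < config@injuryAffectedFraction
                grn2[hit2] <- grn2[hit2] * config@injuryGfpFactor
            }
            tof[i] <- tof[i] + tof2
            ext[i] <- ext[i] + ext2
            grn[i] <- grn[i] + grn2
            red[i] <- red[i] + red2
        }
        ## curled worms: short and optically dense
        i <- cls == "curl"
        tof[i] <- tof[i] * CURL_TOF_SCALE
        ext[i] <- ext[i] * CURL_EXT_SCALE
        ## death staining among single worms
        dead <- rep(FALSE, n)
        if (config@redDeathFraction > 0) {
            single <- cls %in% c("adult", "curl")
            dead[single] <- stats::runif(sum(single)) < config@redDeathFraction
            red[dead] <- stats::rlnorm(sum(dead), RED_DEAD_MEANLOG, RED_SDLOG)
        }
        ids <- sprintf("%s_%s_%s_%06d", config@condition, config@replicate,
                       substr(arm, 1, 3), seq_len(n))
        events <- FlowEventTable(data.frame(
            event_id = ids, tof = tof, extinction = ext, green = grn, red = red,
            condition = config@condition, replicate = config@replicate,
            stringsAsFactors = FALSE))
        truth <- data.frame(event_id = ids, class = cls,
                            affected = affected, dead = dead,
                            stringsAsFactors = FALSE)
        list(events = events, truth = truth)
    })
}
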
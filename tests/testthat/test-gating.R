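# Gating, population summaries, percentile selection, dead fraction,
# time-course normalization.

test_that("wide-open gates remove nothing and boundary events are retained", {
    sim <- generateFlowEvents(flowSimConfig(nWorms = 500L, seed = 2L))
    open <- GateConfig(extMin = 0, tofMin = 0)
    g <- gateEvents(sim$events, open)
    expect_equal(sum(g$report$n[g$report$gate != "retained"]), 0)
    ## an event exactly at tofMin is retained (closed lower bound)
    ft <- FlowEventTable(data.frame(event_id = "e", tof = 100, extinction = 50,
                                    green = 10, red = 1, condition = "x",
                                    replicate = "r1"))
    g2 <- gateEvents(ft, GateConfig(extMin = 50, tofMin = 100))
    expect_identical(gateFlags(g2$events), "")
})

test_that("gating separates planted contaminant classes at >= 99% purity and recall", {
    sim <- generateFlowEvents(separatedFlowConfig(nWorms = 20000L, seed = 17L))
    gates <- defaultGates(separatedReference())
    gated <- gateEvents(sim$events, gates)
    flags <- gateFlags(gated$events)
    truth <- sim$truth$class
    for (cls in c("larva", "bacteria", "doublet", "curl")) {
        recall <- sum(flags == cls & truth == cls) / sum(truth == cls)
        purity <- sum(flags == cls & truth == cls) / sum(flags == cls)
        expect_gte(recall, 0.99)
        expect_gte(purity, 0.99)
    }
    adultKept <- sum(flags == "" & truth == "adult") / sum(truth == "adult")
    expect_gte(adultKept, 0.99)
})

test_that("gating is idempotent", {
    sim <- generateFlowEvents(separatedFlowConfig(nWorms = 5000L, seed = 23L))
    gates <- defaultGates(separatedReference())
    once <- gateEvents(sim$events, gates)
    twice <- gateEvents(once$events, gates)
    expect_identical(eventData(once$events), eventData(twice$events))
    expect_identical(once$report, twice$report)
})

test_that("fully gated-out tables raise a data error naming the dominant gate", {
    ft <- FlowEventTable(data.frame(event_id = c("a", "b"), tof = c(1, 2),
                                    extinction = c(1, 2), green = 0, red = 0,
                                    condition = "x", replicate = "r1"))
    expect_error(gateEvents(ft, GateConfig(extMin = 10, tofMin = 10)),
                 "dominant gate: bacteria",
                 class = "traumaScreen_data_error")
    expect_error(gateEvents(FlowEventTable(ft@events[0, ]),
                            GateConfig(extMin = 0, tofMin = 0)),
                 class = "traumaScreen_data_error")
})

test_that("population summaries match hand and moment computations", {
    mk <- function(v) FlowEventTable(data.frame(
        event_id = seq_along(v), tof = 1, extinction = 1, green = v, red = 0,
        condition = "x", replicate = "r1"))
    s <- summarizePopulation(mk(c(1, 1, 1)))
    expect_equal(c(s@mean, s@sd, s@sem), c(1, 0, 0))
    s2 <- summarizePopulation(mk(c(1, 3)))
    expect_equal(c(s2@mean, s2@sd, s2@sem), c(2, sqrt(2), 1))
    ## lognormal moment check: mean within 3 sem of exp(mu + sigma^2/2)
    sim <- generateFlowEvents(flowSimConfig(
        nWorms = 1e5L, gfpMeanlog = log(150), gfpSdlog = 0.5,
        contaminantFractions = c(larva = 0, bacteria = 0, doublet = 0, curl = 0),
        seed = 31L))
    s3 <- summarizePopulation(sim$events, "green")
    expect_lt(abs(s3@mean - 150 * exp(0.5^2 / 2)), 3 * s3@sem)
    ## brute-force re-computation on the same table
    x <- eventData(sim$events)$green
    expect_equal(s3@mean, sum(x) / length(x))
    expect_equal(s3@sd, sqrt(sum((x - mean(x))^2) / (length(x) - 1)))
})

test_that("percentile selection uses linear interpolation and partitions", {
    withr::with_seed(7, v <- sample(seq_len(1000)))
    ft <- FlowEventTable(data.frame(event_id = seq_along(v), tof = 1,
                                    extinction = 1, green = v, red = 0,
                                    condition = "x", replicate = "r1"))
    expect_identical(eventData(selectPercentile(ft, "green", 0, 100)),
                     eventData(ft))
    bottom <- selectPercentile(ft, "green", 0, 10)
    expect_equal(sort(eventData(bottom)$green), 1:100)
    top <- selectPercentile(ft, "green", 90, 100)
    rest <- selectPercentile(ft, "green", 0, 90)
    expect_equal(nEvents(top) + nEvents(rest), nEvents(ft))
    expect_length(intersect(eventData(top)$event_id, eventData(rest)$event_id), 0)
    expect_error(selectPercentile(ft, "green", 50, 50),
                 class = "traumaScreen_config_error")
})

test_that("dead fraction recovers the planted death rate with a Wilson CI", {
    sim <- generateFlowEvents(flowSimConfig(
        nWorms = 10000L, redDeathFraction = 0.49,
        contaminantFractions = c(larva = 0, bacteria = 0, doublet = 0, curl = 0),
        seed = 41L))
    d <- deadFraction(sim$events, redDeadThreshold = 50)
    expect_equal(d$fraction, 0.49, tolerance = 0.011 / 0.49)
    expect_true(d$ciLow < d$fraction && d$fraction < d$ciHigh)
    ## degenerate thresholds
    ft <- FlowEventTable(data.frame(event_id = 1:3, tof = 1, extinction = 1,
                                    green = 1, red = 0, condition = "x",
                                    replicate = "r1"))
    expect_equal(deadFraction(ft, 1)$fraction, 0)
    expect_equal(deadFraction(ft, -1)$fraction, 1)
})

test_that("time-course normalization divides by age-matched controls", {
    inj <- list(t24 = makeSummary(100, 0), t48 = makeSummary(50, 2))
    un <- list(t24 = makeSummary(100, 0), t48 = makeSummary(100, 4))
    tc <- normalizeTimecourse(inj, un)
    expect_equal(tc$value, c(1, 0.5))
    expect_equal(tc$delta[1], 0)
    ## propagated error vs Monte-Carlo at the second timepoint
    expect_equal(tc$delta[2], mcRatioSD(50, 2, 100, 4), tolerance = 0.1)
    expect_error(normalizeTimecourse(inj, un["t24"]),
                 class = "traumaScreen_data_error")
})
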
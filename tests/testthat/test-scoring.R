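# Index algebra, quadrature error propagation, replicate combination,
# hit calling and whole-screen scoring.

test_that("fluorescence ratio follows the quadrature quotient rule", {
    r0 <- fluorescenceRatio(makeSummary(100, 0), makeSummary(100, 0))
    expect_equal(r0@value, 1)
    expect_equal(r0@delta, 0)
    r <- fluorescenceRatio(makeSummary(50, 2), makeSummary(100, 4))
    expect_equal(r@value, 0.5)
    expect_equal(r@delta, 0.5 * sqrt(0.0016 + 0.0016))
    expect_equal(r@delta, 0.028284, tolerance = 1e-4)
    expect_error(fluorescenceRatio(makeSummary(50, 2), makeSummary(0.0, 0)),
                 class = "traumaScreen_data_error")
})

test_that("ratio error matches a Monte-Carlo oracle at small relative error", {
    cases <- list(c(50, 2, 100, 4), c(80, 1, 100, 2), c(30, 1.5, 60, 3))
    for (cs in cases) {
        r <- fluorescenceRatio(makeSummary(cs[1], cs[2]), makeSummary(cs[3], cs[4]))
        expect_equal(r@delta, mcRatioSD(cs[1], cs[2], cs[3], cs[4]),
                     tolerance = 0.1)
    }
})

test_that("index anchors: full protection is 1, control-level loss is 0", {
    expect_equal(indexEstimate(gfpIndex(makeRatio(0.5, 0), makeRatio(1, 0))), 1)
    expect_equal(indexEstimate(gfpIndex(makeRatio(0.5, 0), makeRatio(0.5, 0))), 0)
    ## quotient-rule arithmetic by hand at index -0.5 ...
    res <- gfpIndex(makeRatio(0.5, 0.02), makeRatio(0.25, 0.02))
    expect_equal(indexEstimate(res), -0.5)
    expect_equal(res@deltaWithin,
                 sqrt((0.02 / 0.5)^2 + (0.02 * 0.75 / 0.25)^2))
    expect_equal(res@deltaWithin, 0.072111, tolerance = 1e-4)
    ## ... and at index 0, where the propagation collapses to the symmetric
    ## quadrature of the two ratio errors
    res0 <- gfpIndex(makeRatio(0.5, 0.02), makeRatio(0.5, 0.02))
    expect_equal(res0@deltaWithin, sqrt(0.0016 + 0.0016))
    expect_equal(res0@deltaWithin, 0.056568, tolerance = 1e-4)
})

test_that("index error matches a Monte-Carlo oracle at small relative error", {
    res <- gfpIndex(makeRatio(0.5, 0.01), makeRatio(0.75, 0.015))
    expect_equal(res@deltaWithin, mcIndexSD(0.5, 0.01, 0.75, 0.015),
                 tolerance = 0.1)
})

test_that("a no-loss control is rejected as degenerate", {
    expect_error(gfpIndex(makeRatio(0.995, 0.01), makeRatio(0.5, 0.01)),
                 "degenerate control", class = "traumaScreen_data_error")
    ## configurable guard
    expect_s4_class(gfpIndex(makeRatio(0.995, 0.01), makeRatio(0.5, 0.01),
                             epsilonGuard = 0.001), "IndexResult")
})

test_that("replicate combination follows the two-tier quadrature", {
    one <- gfpIndex(makeRatio(0.5, 0.02), makeRatio(0.75, 0.02))
    comb1 <- combineReplicates(list(one))
    expect_equal(indexEstimate(comb1), indexEstimate(one))
    expect_equal(comb1@deltaBetween, 0)
    expect_equal(comb1@deltaTotal, one@deltaWithin)
    ## identical replicates with zero within-error: total error 0
    zero <- gfpIndex(makeRatio(0.5, 0), makeRatio(0.5, 0))
    expect_equal(combineReplicates(list(zero, zero, zero))@deltaTotal, 0)
    ## quadrature arithmetic
    reps <- list(gfpIndex(makeRatio(0.5, 0.02), makeRatio(0.8, 0.02)),
                 gfpIndex(makeRatio(0.48, 0.02), makeRatio(0.78, 0.02)),
                 gfpIndex(makeRatio(0.52, 0.02), makeRatio(0.79, 0.02)))
    comb <- combineReplicates(reps)
    d <- vapply(reps, function(r) r@deltaWithin, numeric(1))
    idx <- vapply(reps, indexEstimate, numeric(1))
    expect_equal(comb@deltaWithin, sqrt(sum(d^2)) / 3)
    expect_equal(comb@deltaBetween, sd(idx) / sqrt(3))
    expect_equal(comb@deltaTotal,
                 sqrt(comb@deltaWithin^2 + comb@deltaBetween^2))
})

test_that("combined within-error matches a parametric bootstrap SD", {
    reps <- list(gfpIndex(makeRatio(0.5, 0.01), makeRatio(0.8, 0.012)),
                 gfpIndex(makeRatio(0.49, 0.011), makeRatio(0.81, 0.01)),
                 gfpIndex(makeRatio(0.51, 0.009), makeRatio(0.79, 0.011)))
    comb <- combineReplicates(reps)
    boot <- withr::with_seed(55, {
        draws <- vapply(reps, function(r)
            rnorm(1e5, r@index, r@deltaWithin), numeric(1e5))
        sd(rowMeans(draws))
    })
    expect_equal(comb@deltaWithin, boot, tolerance = 0.1)
})

test_that("hits are classified by whether the CI excludes zero", {
    mk <- function(i, d) methods::new("IndexResult", index = i,
        deltaWithin = d, deltaBetween = 0, deltaTotal = d,
        ciLow = i - 1.96 * d, ciHigh = i + 1.96 * d, nReplicates = 3L,
        replicateIndices = i)
    hits <- callHits(list(EV = mk(0, 0.05), a = mk(0.8, 0.25),
                          b = mk(-0.4, 0.15), c = mk(0.2, 0.15)))
    expect_equal(hits$classification[hits$gene == "a"], "protective")
    expect_equal(hits$classification[hits$gene == "b"], "sensitizing")
    expect_equal(hits$classification[hits$gene == "c"], "no_effect")
    ## sorted by index, descending
    expect_equal(hits$gene, c("a", "c", "EV", "b"))
})

test_that("the index is affine-invariant and monotone in the RNAi ratio", {
    ## rescaling every fluorescence value by one positive constant leaves
    ## every index unchanged
    sim <- generateScreenExperiment(screenSimConfig(
        genes = "A", trueIndex = c(A = 0.5),
        flowConfig = flowSimConfig(nWorms = 300L), seed = 33L))
    scaled <- lapply(sim$experiment, function(arms) lapply(arms, function(ft) {
        ev <- eventData(ft)
        ev$green <- ev$green * 7.3
        FlowEventTable(ev)
    }))
    h1 <- scoreScreen(sim$experiment)$hits
    h2 <- scoreScreen(scaled)$hits
    expect_equal(h1$index, h2$index, tolerance = 1e-12)
    expect_equal(h1$deltaTotal, h2$deltaTotal, tolerance = 1e-12)
    ## strictly monotone in rnai.value for fixed ev < 1: more retained GFP
    ## (higher knockdown ratio) always means a higher index, pinned by the
    ## anchors rnai = ev -> 0 and rnai = 1 -> 1
    ev <- makeRatio(0.5, 0.01)
    vals <- vapply(seq(0.2, 1.2, by = 0.1), function(v)
        indexEstimate(gfpIndex(ev, makeRatio(v, 0.01))), numeric(1))
    expect_true(all(diff(vals) > 0))
})

test_that("a screen with planted effects recovers the classifications", {
    sim <- generateScreenExperiment(screenSimConfig(
        genes = c("A", "B", "C"),
        trueIndex = c(A = 0.8, B = -0.5, C = 0),
        flowConfig = flowSimConfig(nWorms = 500L), seed = 77L))
    hits <- scoreScreen(sim$experiment)$hits
    expect_equal(hits$classification[hits$gene == "A"], "protective")
    expect_equal(hits$classification[hits$gene == "B"], "sensitizing")
    expect_equal(hits$classification[hits$gene == "C"], "no_effect")
    expect_equal(hits$index[hits$gene == "A"], 0.8, tolerance = 0.25)
})

test_that("conditions duplicated from EV data score exactly zero with no hits", {
    for (s in c(1L, 2L, 3L)) {
        sim <- generateScreenExperiment(screenSimConfig(
            genes = "EV", flowConfig = flowSimConfig(nWorms = 200L), seed = s))
        experiment <- list(EV = sim$experiment$EV,
                           dupA = sim$experiment$EV,
                           dupB = sim$experiment$EV)
        hits <- scoreScreen(experiment)$hits
        expect_equal(hits$index, rep(0, 3))
        expect_true(all(hits$classification == "no_effect"))
    }
})
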
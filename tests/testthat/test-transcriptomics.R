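# DE filtering, z-scoring, cross-correlation, overlaps, age trend,
# candidate filtering.

plantedDEMatrix <- function(seed = 19L) {
    ## 20 genes, 4 with true 4-fold shifts, tight noise, n = 3/group
    withr::with_seed(seed, {
        base <- matrix(2^(8 + rnorm(120, 0, 0.05)), 20, 6,
                       dimnames = list(sprintf("g%02d", 1:20),
                                       c(paste0("a", 1:3), paste0("b", 1:3))))
        base[1:4, 1:3] <- base[1:4, 1:3] * 4
        base
    })
}

test_that("identical groups yield no significant genes", {
    m <- plantedDEMatrix()
    de <- differentialExpression(ExpressionMatrix(m, "intensity"),
                                 c("a1", "a2", "a3"), c("a1", "a2", "a3"))
    expect_false(any(de$significant))
})

test_that("exactly the planted genes pass the fold-change/p filter", {
    m <- plantedDEMatrix()
    de <- differentialExpression(ExpressionMatrix(m, "intensity"),
                                 paste0("a", 1:3), paste0("b", 1:3),
                                 fcThreshold = 2, pThreshold = 0.05)
    expect_setequal(de$gene[de$significant], sprintf("g%02d", 1:4))
    expect_true(all(de$direction[de$significant] == "up"))
    ## FDR variant still finds only planted genes
    deq <- differentialExpression(ExpressionMatrix(m, "intensity"),
                                  paste0("a", 1:3), paste0("b", 1:3),
                                  fdr = TRUE)
    expect_setequal(deq$gene[deq$significant], sprintf("g%02d", 1:4))
})

test_that("zero-variance genes get p = 1 and significance is monotone", {
    m <- plantedDEMatrix()
    m[5, ] <- 256
    de <- differentialExpression(ExpressionMatrix(m, "intensity"),
                                 paste0("a", 1:3), paste0("b", 1:3))
    expect_equal(de$p[de$gene == "g05"], 1)
    ## lowering fc or raising p thresholds never removes a significant gene
    sig <- function(fc, p) {
        d <- differentialExpression(ExpressionMatrix(m, "intensity"),
                                    paste0("a", 1:3), paste0("b", 1:3),
                                    fcThreshold = fc, pThreshold = p)
        d$gene[d$significant]
    }
    base <- sig(2, 0.05)
    expect_true(all(base %in% sig(1.5, 0.05)))
    expect_true(all(base %in% sig(2, 0.2)))
})

test_that("BH q-values match the hand example and the step-up definition", {
    expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.5), method = "BH"),
                 c(0.04, 0.04, 0.04, 0.5))
    grid <- seq(0.01, 1, by = 0.01)
    ## exhaustive over all length-1 and length-2 grid vectors
    for (p1 in grid) expect_equal(p.adjust(p1, "BH"), bhStepUp(p1))
    two <- unname(as.matrix(expand.grid(grid, grid)))
    ok2 <- vapply(seq_len(nrow(two)), function(i) {
        p <- two[i, ]
        isTRUE(all.equal(p.adjust(p, "BH"), bhStepUp(p)))
    }, logical(1))
    expect_true(all(ok2))
    ## all sorted length-3 combinations, plus random length-4/5 vectors
    three <- utils::combn(grid, 3)
    ok3 <- vapply(seq_len(ncol(three)), function(i) {
        p <- three[, i]
        isTRUE(all.equal(p.adjust(p, "BH"), bhStepUp(p)))
    }, logical(1))
    expect_true(all(ok3))
    okLong <- withr::with_seed(29, {
        vapply(1:4000, function(i) {
            p <- sample(grid, if (i %% 2) 4L else 5L, replace = TRUE)
            isTRUE(all.equal(p.adjust(p, "BH"), bhStepUp(p)))
        }, logical(1))
    })
    expect_true(all(okLong))
})

test_that("z-score normalization centers, scales and preserves NaN", {
    expect_equal(zscoreNormalize(c(1, 2, 3)), c(-1, 0, 1))
    z <- zscoreNormalize(c(1, NaN, 3))
    expect_true(is.na(z[2]))
    expect_equal(z[1], -z[3])
    expect_error(zscoreNormalize(c(2, 2, 2)), class = "traumaScreen_data_error")
})

test_that("cross-correlation equals the brute-force complete-case oracle", {
    sim <- generateStressExpression(exprSimConfig(nGenes = 400L, nDatasets = 4L,
                                                  nanFraction = 0.05, seed = 37L))
    cm <- crossCorrelate(sim$datasets)
    oracle <- bruteForcePearson(exprValues(sim$datasets))
    expect_lt(max(abs(corValues(cm) - oracle)), 1e-12)
    expect_equal(cm@nGenesUsed,
                 sum(complete.cases(exprValues(sim$datasets))))
    ## self and negation anchors
    v <- exprValues(sim$datasets)[, 1]
    cm2 <- crossCorrelate(list(a = v, b = v, c = -v))
    expect_equal(corValues(cm2)["a", "b"], 1, tolerance = 1e-12)
    expect_equal(corValues(cm2)["a", "c"], -1, tolerance = 1e-12)
})

test_that("cross-correlation is invariant to positive affine rescaling", {
    sim <- generateStressExpression(exprSimConfig(nGenes = 300L, seed = 43L))
    v <- exprValues(sim$datasets)
    v2 <- v
    v2[, 2] <- 3.7 * v2[, 2] + 11
    cm <- crossCorrelate(ExpressionMatrix(v, "log2fc"))
    cm2 <- crossCorrelate(ExpressionMatrix(v2, "log2fc"))
    expect_equal(corValues(cm), corValues(cm2), tolerance = 1e-12)
})

test_that("cross-correlation recovers the generator's closed-form truth", {
    L <- matrix(c(0.9, 0.1, 0.5, -0.5, 0.2, 0.8), 3, 2, byrow = TRUE)
    sim <- generateStressExpression(exprSimConfig(
        nGenes = 2000L, nDatasets = 3L, nPrograms = 2L, loadings = L,
        noiseSd = 0.2, nanFraction = 0.02, seed = 51L))
    cm <- crossCorrelate(sim$datasets)
    expect_lt(max(abs(corValues(cm) - sim$truth$correlation)), 0.05)
    ## restriction to a reference set and the minimum-gene guard
    ref <- rownames(exprValues(sim$datasets))[1:100]
    cmRef <- crossCorrelate(sim$datasets, referenceSet = ref)
    expect_lte(cmRef@nGenesUsed, 100L)
    expect_error(crossCorrelate(sim$datasets, referenceSet = ref[1:2]),
                 class = "traumaScreen_data_error")
})

test_that("set overlaps are exact set algebra", {
    o <- overlapSets(paste0("g", 1:10), paste0("g", 6:15))
    expect_equal(c(o$aOnly, o$shared, o$bOnly), c(5, 5, 5))
    expect_equal(o$aOnly + o$shared + o$bOnly,
                 length(union(paste0("g", 1:10), paste0("g", 6:15))))
    same <- overlapSets(letters[1:4], letters[1:4])
    expect_equal(c(same$aOnly, same$shared, same$bOnly), c(0, 4, 0))
    expect_equal(overlapSets(letters[1:3], letters[4:6])$shared, 0)
})

test_that("age-response trend detects planted attenuation", {
    same <- ageResponseTrend(c(2, 4, 8), c(2, 4, 8))
    expect_equal(same$meanDiff, 0)
    expect_equal(same$p, 1)
    withr::with_seed(61, {
        d1 <- 2 + rnorm(100, 0, 0.1)          # log2 scale
        d4 <- d1 - 1 + rnorm(100, 0, 0.1)     # uniform 1-log2 attenuation
        tr <- ageResponseTrend(d1, d4, inputScale = "log2")
    })
    expect_equal(tr$meanDiff, 1, tolerance = 0.03)
    expect_lt(tr$p, 1e-10)
    expect_equal(tr$nAboveBoth, sum(d1 >= 1 & d4 >= 1))
    ## antisymmetry under swapping the two days
    rev <- ageResponseTrend(d4, d1, inputScale = "log2")
    expect_equal(rev$meanDiff, -tr$meanDiff)
})

test_that("candidate filtering applies all annotation flags", {
    genes <- sprintf("c%03d", 1:120)
    de <- data.frame(gene = genes, significant = TRUE)
    ## 89 pass expression/neuronal/homolog; 51 of those have RNAi clones
    ann <- data.frame(gene = genes,
                      expression_level = c(rep(2, 89), rep(0.5, 31)),
                      neuronal = TRUE, homolog = TRUE,
                      rnai_available = c(rep(TRUE, 51), rep(FALSE, 69)))
    firstThree <- screenCandidateFilter(
        de, transform(ann, rnai_available = TRUE))
    expect_length(firstThree, 89)
    candidates <- screenCandidateFilter(de, ann)
    expect_length(candidates, 51)
    ## all flags true: candidates equal the significant set
    allTrue <- transform(ann, expression_level = 2, rnai_available = TRUE)
    expect_setequal(screenCandidateFilter(de, allTrue), genes)
    ## no RNAi clones anywhere: empty list
    noRnai <- transform(ann, rnai_available = FALSE)
    expect_length(screenCandidateFilter(de, noRnai), 0)
    ## genes missing from the annotation table fail closed
    expect_length(screenCandidateFilter(de, ann[1:10, ]), 10)
})
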
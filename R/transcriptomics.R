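# Differential-expression filtering, cross-correlation, overlaps and the
# day-1 vs day-4 attenuation comparison.

#' Per-gene differential expression with fold-change/p-value filtering
#'
#' Welch's two-sided t-test per gene on log2 values, with the fold change
#' taken as the ratio of group means on the linear scale. A gene is
#' significant when its fold-change magnitude (`max(FC, 1/FC)`) is at least
#' `fcThreshold` and its p-value (or Benjamini-Hochberg q-value when
#' `fdr = TRUE`, the RNAseq-style filter) is at most `pThreshold`; both
#' thresholds are inclusive. Genes with zero variance in both groups get
#' p = 1 by convention. Input kinds `"intensity"`/`"count"`/`"fc"` are
#' log2-transformed (and must be positive); `"log2fc"` values are used as
#' given.
#'
#' @param expr an [ExpressionMatrix-class] with sample columns.
#' @param groupA,groupB column names of the two groups (>= 2 samples each).
#' @param fcThreshold fold-change threshold on the linear scale (default 2).
#' @param pThreshold p (or q) threshold (default 0.05).
#' @param fdr apply Benjamini-Hochberg correction and threshold q instead
#'   of p.
#' @return data.frame with one row per gene: `gene`, `log2fc` (A over B),
#'   `foldChange` (signed magnitude convention: linear ratio), `p`, `q`,
#'   `significant`, `direction`.
#' @examples
#' m <- matrix(2^rnorm(60, 8), 10, 6,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
#' de <- differentialExpression(ExpressionMatrix(m, "intensity"),
#'                              paste0("s", 1:3), paste0("s", 4:6))
#' head(de)
#' @export
differentialExpression <- function(expr, groupA, groupB, fcThreshold = 2,
                                   pThreshold = 0.05, fdr = FALSE) {
    if (!methods::is(expr, "ExpressionMatrix"))
        dataError("expr must be an ExpressionMatrix")
    v <- expr@values
    missing <- setdiff(c(groupA, groupB), colnames(v))
    if (length(missing))
        dataError(paste("unknown sample columns:", paste(missing, collapse = ", ")))
    if (length(groupA) < 2L || length(groupB) < 2L)
        dataError("each group needs at least 2 samples")
    if (expr@kind == "log2fc") {
        lg <- v
    } else {
        if (any(v[, c(groupA, groupB)] <= 0, na.rm = TRUE))
            dataError("linear-scale values must be positive for log2 transform")
        lg <- log2(v)
    }
    a <- lg[, groupA, drop = FALSE]
    b <- lg[, groupB, drop = FALSE]
    welch <- function(x, y) {
        x <- x[!is.na(x)]; y <- y[!is.na(y)]
        if (length(x) < 2L || length(y) < 2L) return(NA_real_)
        if (stats::sd(x) == 0 && stats::sd(y) == 0) return(1)
        stats::t.test(x, y, var.equal = FALSE)$p.value
    }
    p <- vapply(seq_len(nrow(lg)), function(i) welch(a[i, ], b[i, ]), numeric(1))
    log2fc <- rowMeans(a, na.rm = TRUE) - rowMeans(b, na.rm = TRUE)
    q <- stats::p.adjust(p, method = "BH")
    crit <- if (fdr) q else p
    fcMag <- 2^abs(log2fc)
    significant <- !is.na(crit) & fcMag >= fcThreshold & crit <= pThreshold
    data.frame(gene = rownames(v), log2fc = unname(log2fc),
               foldChange = unname(2^log2fc), p = p, q = q,
               significant = significant,
               direction = ifelse(log2fc >= 0, "up", "down"),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' z-score normalize a vector, preserving missing values
#'
#' Subtracts the mean and divides by the n-1 standard deviation of the
#' non-missing entries; `NaN`/`NA` positions are preserved.
#'
#' @param values numeric vector, possibly with missing entries.
#' @return normalized vector of the same length.
#' @export
zscoreNormalize <- function(values) {
    x <- values[!is.na(values)]
    if (length(x) < 2L) dataError("need at least 2 non-missing values")
    s <- stats::sd(x)
    if (s == 0) dataError("zero standard deviation: cannot z-score a constant")
    (values - mean(x)) / s
}

#' Cross-correlate stress-response fold-change signatures
#'
#' Restricts every dataset to a reference gene set (the genes significantly
#' regulated in the anchoring dataset), z-score normalizes each dataset,
#' drops every gene missing in *any* dataset (complete-case, matching a
#' concatenate-then-filter workflow; `naAction = "pairwise"` is offered as
#' an option), and computes the Pearson correlation matrix of the aligned
#' remainder.
#'
#' @param datasets an [ExpressionMatrix-class] whose columns are datasets,
#'   or a named list of numeric vectors sharing gene names.
#' @param referenceSet character vector of gene ids to restrict to; `NULL`
#'   uses all shared genes.
#' @param naAction `"complete"` (default) or `"pairwise"`.
#' @param inputScale `"log2"` (default: values are already log2 fold
#'   changes) or `"linear"` (positive linear fold changes, log2-transformed
#'   first).
#' @return A [CorrelationMatrix-class].
#' @examples
#' sim <- generateStressExpression(exprSimConfig(nGenes = 500, seed = 7))
#' crossCorrelate(sim$datasets)
#' @export
crossCorrelate <- function(datasets, referenceSet = NULL,
                           naAction = c("complete", "pairwise"),
                           inputScale = c("log2", "linear")) {
    naAction <- match.arg(naAction)
    inputScale <- match.arg(inputScale)
    if (methods::is(datasets, "ExpressionMatrix")) {
        v <- datasets@values
    } else {
        if (is.null(names(datasets)) || length(datasets) < 2L)
            dataError("datasets must be a named list or ExpressionMatrix")
        shared <- Reduce(intersect, lapply(datasets, names))
        v <- vapply(datasets, function(d) d[shared], numeric(length(shared)))
        rownames(v) <- shared
    }
    if (ncol(v) < 2L) dataError("need at least 2 datasets")
    if (!is.null(referenceSet)) {
        keep <- intersect(referenceSet, rownames(v))
        if (!length(keep)) dataError("reference set shares no genes with the data")
        v <- v[keep, , drop = FALSE]
    }
    if (inputScale == "linear") {
        if (any(v <= 0, na.rm = TRUE))
            dataError("linear fold changes must be positive for log2 transform")
        v <- log2(v)
    }
    z <- apply(v, 2, zscoreNormalize)
    if (naAction == "complete") {
        cc <- stats::complete.cases(z)
        if (sum(cc) < 3L)
            dataError("fewer than 3 complete-case genes across all datasets")
        r <- stats::cor(z[cc, , drop = FALSE])
        nUsed <- sum(cc)
    } else {
        r <- stats::cor(z, use = "pairwise.complete.obs")
        nUsed <- sum(stats::complete.cases(z))
    }
    r[abs(r) > 1] <- sign(r[abs(r) > 1])   # guard fp overshoot
    r <- (r + t(r)) / 2
    diag(r) <- 1
    methods::new("CorrelationMatrix", r = r, nGenesUsed = as.integer(nUsed))
}

#' Overlap of two gene sets
#'
#' @param setA,setB character vectors of gene ids (duplicates ignored).
#' @return list with counts `aOnly`, `shared`, `bOnly` and the corresponding
#'   membership vectors; the counts sum to the size of the union.
#' @export
overlapSets <- function(setA, setB) {
    a <- unique(as.character(setA))
    b <- unique(as.character(setB))
    shared <- intersect(a, b)
    list(aOnly = length(setdiff(a, b)), shared = length(shared),
         bOnly = length(setdiff(b, a)),
         aOnlyGenes = setdiff(a, b), sharedGenes = shared,
         bOnlyGenes = setdiff(b, a))
}

#' Compare stress-gene induction between two ages
#'
#' Paired comparison of per-gene fold changes measured at two ages (e.g.
#' day-1 vs day-4 adults, each normalized to age-matched controls): per-gene
#' log2 values, the mean paired difference (age 1 minus age 2), a two-sided
#' paired t-test, and the number of genes above the 2-fold threshold at both
#' ages.
#'
#' @param fcDay1,fcDay4 fold-change vectors over the same genes in the same
#'   order (>= 3 genes).
#' @param inputScale `"linear"` (default) or `"log2"`.
#' @param fcThreshold linear threshold for the both-days count.
#' @return list with `meanDiff`, `p`, `nGenes`, `nAboveBoth`, and the
#'   per-gene `log2Day1`, `log2Day4` vectors.
#' @export
ageResponseTrend <- function(fcDay1, fcDay4,
                             inputScale = c("linear", "log2"),
                             fcThreshold = 2) {
    inputScale <- match.arg(inputScale)
    if (length(fcDay1) != length(fcDay4))
        dataError("fold-change vectors must have the same length and gene order")
    if (length(fcDay1) < 3L) dataError("need at least 3 genes")
    if (inputScale == "linear") {
        if (any(c(fcDay1, fcDay4) <= 0, na.rm = TRUE))
            dataError("linear fold changes must be positive")
        l1 <- log2(fcDay1); l4 <- log2(fcDay4)
    } else {
        l1 <- fcDay1; l4 <- fcDay4
    }
    d <- l1 - l4
    ## a constant difference carries no sampling variability: p is 1 for a
    ## zero difference and 0 for a nonzero one
    p <- if (stats::sd(d) == 0) as.numeric(mean(d) == 0)
         else stats::t.test(l1, l4, paired = TRUE)$p.value
    list(meanDiff = mean(d), p = p, nGenes = length(d),
         nAboveBoth = sum(l1 >= log2(fcThreshold) & l4 >= log2(fcThreshold)),
         log2Day1 = l1, log2Day4 = l4)
}

#' Filter significant genes down to screenable candidates
#'
#' Candidates must be significantly regulated and, per the annotation table:
#' expressed above the expression threshold, expressed in mechanosensory
#' neurons, have a mammalian homolog, and have an RNAi clone available.
#' Genes missing from the annotation table fail all flags.
#'
#' @param de data.frame from [differentialExpression()].
#' @param annotations data.frame with columns `gene`, `expression_level`
#'   (numeric), `neuronal`, `homolog`, `rnai_available` (logical).
#' @param expressionThreshold minimum expression level (default 1,
#'   exclusive).
#' @return character vector of candidate gene ids in stable gene-id order.
#' @export
screenCandidateFilter <- function(de, annotations, expressionThreshold = 1) {
    need <- c("gene", "expression_level", "neuronal", "homolog", "rnai_available")
    missing <- setdiff(need, names(annotations))
    if (length(missing))
        dataError(paste("annotation table lacks columns:",
                        paste(missing, collapse = ", ")))
    sig <- de$gene[de$significant]
    ann <- annotations[match(sig, annotations$gene), , drop = FALSE]
    pass <- !is.na(ann$gene) &
        ann$expression_level > expressionThreshold &
        ann$neuronal %in% TRUE & ann$homolog %in% TRUE &
        ann$rnai_available %in% TRUE
    sort(sig[pass])
}
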
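# Latent stress-program generator for cross-dataset fold-change vectors.

#' ExprSimConfig: latent-program model for stress fold-change signatures
#'
#' Dataset *d* expresses gene *g* as
#' `value[d, g] = sum_p loading[d, p] * effect[p, g] + N(0, noiseSd)`,
#' i.e. each dataset is a weighted mixture of a small number of latent stress
#' programs (heat shock, oxidative stress, ...) shared across datasets. The
#' implied dataset-by-dataset correlation matrix follows in closed form from
#' the loadings, the empirical covariance of the program effects, and the
#' noise variance, and is returned as ground truth.
#'
#' @slot nGenes number of genes.
#' @slot nDatasets number of datasets (rows of the loading matrix).
#' @slot nPrograms number of latent programs.
#' @slot loadings dataset x program weight matrix.
#' @slot programGeneEffects program x gene log2-effect matrix; drawn N(0, 1)
#'   per entry when not supplied.
#' @slot noiseSd independent Gaussian noise SD (log2 units).
#' @slot nanFraction fraction of entries replaced by `NaN` uniformly at
#'   random, in [0, 1).
#' @slot seed integer master seed.
#' @export
setClass("ExprSimConfig",
         slots = c(nGenes = "integer", nDatasets = "integer",
                   nPrograms = "integer", loadings = "matrix",
                   programGeneEffects = "matrix", noiseSd = "numeric",
                   nanFraction = "numeric", seed = "integer"))

setValidity("ExprSimConfig", function(object) {
    if (object@nGenes < 3L) return("nGenes must be >= 3")
    if (!all(dim(object@loadings) == c(object@nDatasets, object@nPrograms)))
        return("loadings must be nDatasets x nPrograms")
    if (nrow(object@programGeneEffects) &&
        !all(dim(object@programGeneEffects) == c(object@nPrograms, object@nGenes)))
        return("programGeneEffects must be nPrograms x nGenes")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    if (object@nanFraction < 0 || object@nanFraction >= 1)
        return("nanFraction must lie in [0, 1)")
    TRUE
})

#' Construct an ExprSimConfig
#'
#' @param nGenes,nDatasets,nPrograms model dimensions.
#' @param loadings dataset x program matrix; defaults to independent
#'   Uniform(-1, 1) weights drawn from the seed's child stream.
#' @param programGeneEffects optional program x gene matrix of log2 effects.
#' @param noiseSd Gaussian noise SD.
#' @param nanFraction fraction of entries masked as `NaN`.
#' @param seed integer master seed.
#' @return An [ExprSimConfig-class].
#' @export
exprSimConfig <- function(nGenes = 2000L, nDatasets = 3L, nPrograms = 2L,
                          loadings = NULL, programGeneEffects = NULL,
                          noiseSd = 0.2, nanFraction = 0.02, seed = 1L) {
    if (is.null(loadings))
        loadings <- withr::with_seed(childSeed(seed, "loadings"),
            matrix(stats::runif(nDatasets * nPrograms, -1, 1),
                   nDatasets, nPrograms))
    if (is.null(programGeneEffects))
        programGeneEffects <- matrix(numeric(0), 0, 0)
    obj <- try(methods::new("ExprSimConfig",
                            nGenes = as.integer(nGenes),
                            nDatasets = as.integer(nDatasets),
                            nPrograms = as.integer(nPrograms),
                            loadings = as.matrix(loadings),
                            programGeneEffects = as.matrix(programGeneEffects),
                            noiseSd = noiseSd, nanFraction = nanFraction,
                            seed = as.integer(seed)),
               silent = TRUE)
    if (inherits(obj, "try-error"))
        configError(paste("invalid expression simulation configuration:",
                          attr(obj, "condition")$message))
    obj
}

#' Generate cross-correlated stress fold-change datasets
#'
#' @param config an [ExprSimConfig-class].
#' @return list with
#'   * `datasets`: an [ExpressionMatrix-class] (genes x datasets, kind
#'     `"log2fc"`) with `NaN` entries masked per `nanFraction`;
#'   * `truth`: list with `correlation` (the closed-form dataset-by-dataset
#'     Pearson matrix implied by the loadings, the empirical effect
#'     covariance and the noise variance), `loadings`, `effects`.
#' The closed-form matrix equals the empirical correlation of the noiseless,
#' unmasked data to machine precision.
#' @seealso [crossCorrelate()]
#' @export
generateStressExpression <- function(config) {
    if (!methods::is(config, "ExprSimConfig"))
        configError("config must be an ExprSimConfig")
    methods::validObject(config)
    genes <- sprintf("g%05d", seq_len(config@nGenes))
    dsets <- sprintf("dataset%02d", seq_len(config@nDatasets))
    withr::with_seed(childSeed(config@seed, "expression"), {
        effects <- config@programGeneEffects
        if (!nrow(effects))
            effects <- matrix(stats::rnorm(config@nPrograms * config@nGenes),
                              config@nPrograms, config@nGenes)
        signal <- config@loadings %*% effects        # datasets x genes
        noise <- matrix(stats::rnorm(length(signal), 0, config@noiseSd),
                        nrow(signal), ncol(signal))
        values <- t(signal + noise)                  # genes x datasets
        dimnames(values) <- list(genes, dsets)
        if (config@nanFraction > 0) {
            mask <- sample.int(length(values),
                               round(config@nanFraction * length(values)))
            values[mask] <- NaN
        }
        ## closed-form truth: Sigma = L S L' + sigma^2 I with S the empirical
        ## (n-1) covariance of the program effects over genes
        S <- stats::cov(t(effects))
        Sigma <- config@loadings %*% S %*% t(config@loadings) +
            diag(config@noiseSd^2, config@nDatasets)
        trueCor <- stats::cov2cor(Sigma)
        dimnames(trueCor) <- list(dsets, dsets)
        list(datasets = ExpressionMatrix(values, kind = "log2fc"),
             truth = list(correlation = trueCor,
                          loadings = config@loadings, effects = effects))
    })
}
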
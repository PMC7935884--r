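# Internal helpers: hierarchical seeding, condition classes, small numerics.

# Deterministic 31-based rolling hash of a label path, folded into [0, 2^31-2].
# One child stream per (condition, replicate, arm) keeps draws for existing
# conditions unchanged when new conditions are added to a simulation.
childSeed <- function(seed, ...) {
    labels <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                           character(1)), collapse = "/")
    h <- abs(as.numeric(seed)) %% 2147483647
    for (k in utf8ToInt(labels)) h <- (h * 31 + k) %% 2147483647
    as.integer(h)
}

configError <- function(msg) {
    stop(errorCondition(msg,
                        class = c("traumaScreen_config_error",
                                  "traumaScreen_error", "error", "condition")))
}

dataError <- function(msg) {
    stop(errorCondition(msg,
                        class = c("traumaScreen_data_error",
                                  "traumaScreen_error", "error", "condition")))
}

#' Wilson 95% score interval for a binomial proportion
#'
#' Thin wrapper around [stats::prop.test()] without continuity correction,
#' whose interval is the Wilson score interval.
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level.
#' @return numeric vector `c(lower, upper)`.
#' @keywords internal
wilsonInterval <- function(x, n, conf = 0.95) {
    ci <- suppressWarnings(
        stats::prop.test(x, n, conf.level = conf, correct = FALSE))$conf.int
    c(lower = ci[1], upper = ci[2])
}

# sd with the n-1 denominator is stats::sd; kept explicit for summaries where
# a single value must yield 0, not NA.
sdOrZero <- function(x) {
    if (length(x) < 2L) return(0)
    stats::sd(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
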
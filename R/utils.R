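# Internal helpers: deterministic seeding and ZScoreReport assembly.

# Derive a child seed < 2^31 from a master seed and a stream label, so
# per-site / per-species results do not depend on iteration order.
.childSeed <- function(seed, label) {
    h <- 0
    for (ch in utf8ToInt(as.character(label)))
        h <- (h * 131 + ch) %% 2147483563
    as.integer((as.numeric(seed) * 48271 + h) %% 2147483563)
}

# Evaluate expr under a local RNG state; seed = NULL uses the ambient stream.
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

.zreport <- function(statistic, observed, nulls, nDropped = 0L,
                     keepNulls = TRUE) {
    nulls <- as.numeric(nulls)
    if (!length(nulls))
        stop("empty null vector for statistic '", statistic, "'")
    mu <- mean(nulls)
    sdev <- stats::sd(nulls)
    z <- if (is.na(sdev) || sdev == 0) NA_real_ else (observed - mu) / sdev
    new("ZScoreReport", statistic = statistic, observed = observed,
        nullMean = mu, nullSd = if (is.na(sdev)) 0 else sdev, z = z,
        nSims = length(nulls), nDropped = as.integer(nDropped),
        nullValues = if (keepNulls) nulls else numeric(0))
}

#' Standardize an observed value against a null sample
#'
#' Computes `z = (observed - mean(nulls)) / sd(nulls)` using the sample
#' standard deviation. When the null sample is degenerate (zero standard
#' deviation) the z slot carries `NA` rather than an infinity.
#'
#' @param observed numeric scalar, the observed statistic.
#' @param nulls numeric vector of the statistic under the null model.
#' @param statistic label stored in the report.
#' @return A [ZScoreReport-class].
#' @examples
#' zScore(2, c(0.1, -0.2, 0.05, 0))
#' @export
zScore <- function(observed, nulls, statistic = "statistic") {
    stopifnot(is.numeric(observed), length(observed) == 1L)
    .zreport(statistic, observed, nulls)
}
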
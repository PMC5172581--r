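## Internal helpers shared across modules.

## Order chromosome labels numerically where possible ("1" < "2" < "10"),
## then lexicographically for non-numeric labels.
chromOrder <- function(chrom) {
    num <- suppressWarnings(as.numeric(chrom))
    order(is.na(num), num, as.character(chrom))
}

chromLevels <- function(chrom) {
    u <- unique(as.character(chrom))
    u[chromOrder(u)]
}

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG state. A NULL seed leaves the stream untouched.
withSeed <- function(seed, expr) {
    if (is.null(seed))
        return(expr)
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv())
    else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else {
            assign(".Random.seed", old, envir = globalenv())
        }
    })
    set.seed(seed)
    expr
}

## p-values are kept strictly inside (0, 1] so downstream -log10 and
## strict-inequality cutoffs stay well defined.
clampP <- function(p) pmin(pmax(p, .Machine$double.xmin), 1)

## Sample standard deviation (n - 1 denominator) that returns 0 for a
## single value instead of NA.
sampleSd <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(0)
    stats::sd(x)
}

WATSON_CRICK <- c(A = "T", C = "G", G = "C", T = "A")

complementAllele <- function(x) unname(WATSON_CRICK[x])
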
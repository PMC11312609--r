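#' @importFrom stats rnbinom rpois rbinom rbeta rlnorm runif median var sd cor
#'   pnorm qnorm pchisq phyper dhyper optim p.adjust quantile complete.cases
#'   fisher.test setNames lm coef
#' @importFrom utils read.delim write.table packageVersion head
NULL

# Evaluate expr with a locally seeded RNG, restoring global state afterwards.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
        old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (!is.null(old))
                assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        })
        set.seed(seed)
    }
    expr
}

# Derive a stream-specific 31-bit sub-seed from a master seed.
subSeed <- function(seed, stream) {
    stopifnot(is.numeric(seed), length(seed) == 1L)
    h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
    as.integer((abs(seed) * 48271 + h * 16807) %% 2147483647)
}

.toolHeader <- function(params = NULL) {
    hdr <- sprintf("# riboshift %s", as.character(packageVersion("riboshift")))
    if (length(params))
        hdr <- c(hdr, sprintf("# %s=%s", names(params),
                              vapply(params, function(x)
                                  paste(format(x, trim = TRUE), collapse = ","),
                                  character(1))))
    hdr
}

.assertWholeNonNeg <- function(x, what = "count") {
    if (any(is.na(x)))
        stop("missing ", what, " value")
    if (any(x < 0))
        stop("negative ", what)
    if (any(x != floor(x)))
        stop("non-integer ", what)
    invisible(x)
}

# Benjamini-Hochberg with explicit NA handling: NAs are excluded from the
# number of tests m and propagated as NA.
#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; NA p-values are excluded from the number of
#' tests and returned as NA.
#'
#' @param pvals numeric vector of p-values in [0,1], possibly with NA
#' @return vector of adjusted p-values, same length and order
#' @examples
#' bhAdjust(c(0.005, 0.01, 0.03, 0.04))  # 0.02 0.02 0.04 0.04
#' @export
bhAdjust <- function(pvals) {
    if (any(!is.na(pvals) & (pvals < 0 | pvals > 1)))
        stop("p-values must lie in [0,1]")
    out <- rep(NA_real_, length(pvals))
    ok <- !is.na(pvals)
    out[ok] <- p.adjust(pvals[ok], method = "BH")
    out
}

# Vectorized two-sided Fisher exact p for 2x2 tables (a b / c d), conditioning
# on the column margin a+c. Uses the standard relative-error tie rule (sum all
# outcome probabilities <= observed * (1 + 1e-7)), matching stats::fisher.test.
fisherPTwoSided <- function(a, b, c, d) {
    n <- max(length(a), length(b), length(c), length(d))
    a <- rep_len(a, n); b <- rep_len(b, n)
    c <- rep_len(c, n); d <- rep_len(d, n)
    vapply(seq_len(n), function(i) {
        m <- a[i] + b[i]          # foreground positions
        nn <- c[i] + d[i]         # background positions
        k <- a[i] + c[i]          # total successes (conditioned margin)
        if (m + nn == 0L) return(1)
        lo <- max(0, k - nn); hi <- min(k, m)
        xs <- lo:hi
        pr <- dhyper(xs, m, nn, k)
        obs <- pr[match(a[i], xs)]
        min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
    }, numeric(1))
}

.sampleOddsRatio <- function(a, b, c, d) {
    zero <- (a == 0 | b == 0 | c == 0 | d == 0)
    a <- a + 0.5 * zero; b <- b + 0.5 * zero
    c <- c + 0.5 * zero; d <- d + 0.5 * zero
    (a * d) / (b * c)
}
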
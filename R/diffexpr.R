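#' Median-of-ratios size factors
#'
#' DESeq-style normalization: per sample, the median over genes (with a
#' positive geometric mean across samples) of the ratio of the count to
#' that gene's geometric mean; factors are then rescaled to geometric
#' mean one and used as offsets in the NB GLM.
#'
#' @param object count matrix (genes x samples) or
#'   \linkS4class{TrapExperiment}
#' @return positive numeric vector, one factor per sample
#' @examples
#' sizeFactors(matrix(c(2, 2, 8, 8), 2, 2))  # 0.5, 2.0
#' @name sizeFactors
#' @aliases sizeFactors,matrix-method sizeFactors,TrapExperiment-method
#' @importFrom BiocGenerics sizeFactors
#' @export
setMethod("sizeFactors", "matrix", function(object) {
    logGeo <- rowMeans(log(object))
    use <- is.finite(logGeo)           # genes with all counts > 0
    if (!any(use))
        stop("no gene has nonzero counts in every sample; filter first")
    sf <- apply(object[use, , drop = FALSE], 2, function(cnts)
        median(exp(log(cnts) - logGeo[use])))
    sf <- sf / exp(mean(log(sf)))      # rescale to geometric mean 1
    names(sf) <- colnames(object)
    sf
})

#' @rdname sizeFactors
#' @export
setMethod("sizeFactors", "TrapExperiment", function(object) {
    sizeFactors(assay(object, "counts"))
})

.rowVars <- function(x) {
    n <- ncol(x)
    if (n < 2L) return(rep(NA_real_, nrow(x)))
    m <- rowMeans(x)
    rowSums((x - m)^2) / (n - 1)
}

#' Method-of-moments dispersion with trend shrinkage
#'
#' Per gene, the NB dispersion alpha (variance mu + alpha mu^2) is
#' estimated by method of moments on size-factor-normalized counts pooled
#' within condition levels, floored at 1e-8, then shrunk 50/50 toward a
#' fitted mean-dispersion trend alpha(m) = a0 + a1/m (coefficients
#' clamped non-negative).
#'
#' @param counts count matrix (genes x samples)
#' @param sf size factors
#' @param groups factor/character of the same length as samples
#' @return list with \code{alpha} (final), \code{raw}, \code{trend},
#'   \code{baseMean}
#' @export
estimateDispersionsMoM <- function(counts, sf, groups) {
    Z <- sweep(counts, 2, sf, "/")
    baseMean <- rowMeans(Z)
    lv <- unique(as.character(groups))
    num <- 0; den <- 0
    for (l in lv) {
        j <- which(groups == l)
        if (length(j) < 2L) next
        m <- rowMeans(Z[, j, drop = FALSE])
        v <- .rowVars(Z[, j, drop = FALSE])
        # Var(c/s) ~ m * mean(1/s) + alpha m^2 under the NB model
        a <- (v - m * mean(1 / sf[j])) / m^2
        w <- length(j) - 1
        a[!is.finite(a)] <- NA
        num <- num + ifelse(is.na(a), 0, w * a)
        den <- den + ifelse(is.na(a), 0, w)
    }
    raw <- ifelse(den > 0, num / pmax(den, 1), NA)
    raw <- pmax(raw, 1e-8)
    fitOK <- !is.na(raw) & baseMean > 0
    trend <- rep(1e-8, length(raw))
    if (sum(fitOK) >= 10) {
        fit <- lm(raw[fitOK] ~ I(1 / baseMean[fitOK]))
        a0 <- max(coef(fit)[1], 1e-8)
        a1 <- max(coef(fit)[2], 0)
        trend <- a0 + a1 / pmax(baseMean, 1e-8)
    } else if (any(fitOK)) {
        trend <- rep(max(median(raw[fitOK]), 1e-8), length(raw))
    }
    alpha <- pmax(0.5 * ifelse(is.na(raw), trend, raw) + 0.5 * trend, 1e-8)
    list(alpha = alpha, raw = raw, trend = trend, baseMean = baseMean)
}

# One-group NB GLM with log link and size-factor offsets, Fisher scoring,
# vectorized over genes. Returns eta (log normalized mean), its variance
# (inverse expected information) and a convergence flag.
.fitGroupNB <- function(Y, sf, alpha, maxit = 100L, tol = 1e-10) {
    eta <- log(pmax(rowMeans(sweep(Y, 2, sf, "/")), 1e-8))
    step <- rep(Inf, nrow(Y))
    for (it in seq_len(maxit)) {
        MU <- exp(eta) %o% sf
        denom <- 1 + alpha * MU
        U <- rowSums((Y - MU) / denom)
        info <- rowSums(MU / denom)
        step <- pmin(pmax(U / info, -5), 5)
        eta <- eta + step
        if (max(abs(step)) < tol) break
    }
    MU <- exp(eta) %o% sf
    info <- rowSums(MU / (1 + alpha * MU))
    list(eta = eta, var = 1 / info, converged = abs(step) < 1e-6)
}

#' Negative-binomial Wald differential expression
#'
#' A documented two-group NB GLM Wald test: median-of-ratios size factors
#' as offsets, method-of-moments dispersion with 50/50 trend shrinkage
#' (\code{\link{estimateDispersionsMoM}}), per-group log-mean fit by
#' Fisher scoring, \code{log2FC = (eta_A - eta_B)/log 2}, standard error
#' from the summed inverse expected information, two-sided normal p and
#' Benjamini-Hochberg adjustment. Genes with all-zero counts in one level
#' get a 0.5-count continuity correction (flagged \code{"zero_level"});
#' non-converged genes are flagged with p = NA and excluded from the BH
#' denominator. An optional TpM floor (mean TpM across the stratum
#' samples) excludes genes before testing and before BH.
#'
#' @param object a \linkS4class{TrapExperiment}
#' @param contrast a \linkS4class{ContrastSpec}
#' @param minMeanTpm TpM floor (0 = no floor; requires gene lengths when
#'   positive)
#' @return a \linkS4class{DEResult}
#' @export
fitNBWald <- function(object, contrast, minMeanTpm = 0) {
    stopifnot(is(object, "TrapExperiment"), is(contrast, "ContrastSpec"))
    cd <- colData(object)
    keep <- rep(TRUE, ncol(object))
    for (fld in names(contrast@stratum))
        keep <- keep & as.character(cd[[fld]]) == contrast@stratum[[fld]]
    fac <- as.character(cd[[contrast@factor]])
    jA <- which(keep & fac == contrast@levelA)
    jB <- which(keep & fac == contrast@levelB)
    if (length(jA) < 2L || length(jB) < 2L)
        stop("need >= 2 replicates per level after stratum filter (got ",
             length(jA), " vs ", length(jB), ")")
    cnt <- assay(object, "counts")[, c(jA, jB), drop = FALSE]
    grp <- rep(c("A", "B"), c(length(jA), length(jB)))
    sf <- sizeFactors(cnt)

    tpmMean <- rep(NA_real_, nrow(cnt))
    if (!is.null(geneLengths(object)))
        tpmMean <- rowMeans(computeTPM(cnt, geneLengths(object)))
    if (minMeanTpm > 0) {
        if (all(is.na(tpmMean)))
            stop("TpM floor requested but gene lengths are missing")
        pass <- tpmMean >= minMeanTpm
    } else pass <- rep(TRUE, nrow(cnt))
    Y <- cnt[pass, , drop = FALSE]
    tpmMean <- tpmMean[pass]

    flag <- rep("", nrow(Y))
    zeroLevel <- rowSums(Y[, grp == "A", drop = FALSE]) == 0 |
                 rowSums(Y[, grp == "B", drop = FALSE]) == 0
    flag[zeroLevel] <- "zero_level"
    Yc <- Y
    Yc[zeroLevel, ] <- Y[zeroLevel, ] + 0.5

    disp <- estimateDispersionsMoM(Yc, sf, grp)
    fa <- .fitGroupNB(Yc[, grp == "A", drop = FALSE], sf[grp == "A"],
                      disp$alpha)
    fb <- .fitGroupNB(Yc[, grp == "B", drop = FALSE], sf[grp == "B"],
                      disp$alpha)
    log2FC <- (fa$eta - fb$eta) / log(2)
    se <- sqrt(fa$var + fb$var) / log(2)
    z <- log2FC / se
    p <- 2 * pnorm(-abs(z))
    conv <- fa$converged & fb$converged
    flag[!conv] <- paste0(flag[!conv], ifelse(nzchar(flag[!conv]), ";", ""),
                          "nonconverged")
    p[!conv] <- NA
    res <- DataFrame(gene_id = rownames(Y), baseMean = unname(disp$baseMean),
                     baseMeanTpm = unname(tpmMean), log2FC = unname(log2FC),
                     se = unname(se), z = unname(z), p = unname(p),
                     padj = unname(bhAdjust(p)), flag = flag)
    rownames(res) <- res$gene_id
    out <- new("DEResult", res)
    metadata(out) <- list(contrast = contrast, minMeanTpm = minMeanTpm,
                          n = c(A = length(jA), B = length(jB)),
                          sizeFactors = sf, dispersion = disp$alpha)
    out
}
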
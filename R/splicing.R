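#' Intron clustering and read-support filtering
#'
#' Junctions sharing a splice-site boundary (identical start or identical
#' end coordinate, on the same chromosome and strand, transitively) form
#' a cluster. Singleton junctions sharing no boundary are dropped, and
#' clusters whose split reads summed over all junctions and samples fall
#' below \code{minClusterReads} are removed (the threshold is on the
#' all-sample total, the usual intron-clustering semantics).
#'
#' @param jset a \linkS4class{JunctionSet}
#' @param minClusterReads minimum total split reads per cluster (50)
#' @return the filtered \linkS4class{JunctionSet} with
#'   \code{rowData()$cluster_id}
#' @export
clusterFilter <- function(jset, minClusterReads = 50L) {
    gr <- rowRanges(jset)
    if (!length(gr)) return(jset)
    pre <- paste(as.character(seqnames(gr)), as.character(strand(gr)))
    donorKey <- paste(pre, "S", start(gr))
    accKey <- paste(pre, "E", end(gr))
    jid <- paste0("j", seq_along(gr))
    edges <- rbind(data.frame(from = jid, to = donorKey),
                   data.frame(from = jid, to = accKey))
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    comp <- igraph::components(g)$membership[jid]
    sizes <- table(comp)
    keepMulti <- sizes[as.character(comp)] >= 2L      # drop singletons
    clTotal <- tapply(rowSums(assay(jset, "counts")), comp, sum)
    keepReads <- clTotal[as.character(comp)] >= minClusterReads
    keep <- as.vector(keepMulti & keepReads)
    out <- jset[keep, ]
    cl <- as.integer(factor(comp[keep]))
    rowData(out)$cluster_id <- sprintf("clu%04d", cl)
    out
}

.eventCounts <- function(events, jset) {
    cnt <- assay(jset, "counts")
    key <- paste(as.character(seqnames(rowRanges(jset))),
                 start(rowRanges(jset)), end(rowRanges(jset)), sep = ":")
    lookup <- function(gr) {
        k <- paste(as.character(seqnames(gr)), start(gr), end(gr), sep = ":")
        i <- match(k, key)
        m <- matrix(0, length(gr), ncol(cnt),
                    dimnames = list(names(gr), colnames(cnt)))
        ok <- !is.na(i)
        m[ok, ] <- cnt[i[ok], , drop = FALSE]
        m
    }
    list(i1 = lookup(eventJunctions(events, "i1")),
         i2 = lookup(eventJunctions(events, "i2")),
         e = lookup(eventJunctions(events, "e")))
}

#' Percent spliced in from junction counts
#'
#' The standard skipped-exon estimator: with inclusion junction reads i1,
#' i2 and exclusion reads e, \code{psi = ((i1+i2)/2) / ((i1+i2)/2 + e)}
#' (symmetric in i1/i2). Samples whose event coverage
#' \code{(i1+i2)/2 + e} falls below \code{minCoverage} get NA. Junctions
#' absent from the table count 0.
#'
#' @param events an \linkS4class{ExonEventSet}
#' @param jset a \linkS4class{JunctionSet}
#' @param minCoverage per-sample coverage floor for a defined PSI (10)
#' @return a \linkS4class{PsiExperiment}
#' @export
computePsi <- function(events, jset, minCoverage = 10) {
    ec <- .eventCounts(events, jset)
    inc <- (ec$i1 + ec$i2) / 2
    cov <- inc + ec$e
    psi <- ifelse(cov > 0, inc / cov, NA)
    psi[cov < minCoverage] <- NA
    se <- SummarizedExperiment(
        assays = SimpleList(i1 = ec$i1, i2 = ec$i2, e = ec$e, psi = psi))
    out <- new("PsiExperiment", se)
    metadata(out) <- list(minCoverage = minCoverage)
    out
}

# Beta-binomial log likelihood for successes k of n at mean psi,
# overdispersion rho (rho -> 0 reduces to the binomial).
.bbLogLik <- function(k, n, psi, rho) {
    if (psi <= 0) return(if (all(k == 0)) 0 else -Inf)
    if (psi >= 1) return(if (all(k == n)) 0 else -Inf)
    if (rho < 1e-9)
        return(sum(lchoose(n, k) + k * log(psi) + (n - k) * log(1 - psi)))
    a <- psi * (1 - rho) / rho
    b <- (1 - psi) * (1 - rho) / rho
    sum(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
}

.logit <- function(p) log(p / (1 - p))
.expit <- function(x) 1 / (1 + exp(-x))

.clampP <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

# Joint null fit: common psi and shared rho, maximized over (0,1)^2 with a
# binomial (rho = 0) fallback when the boundary fits better.
.bbFitNull <- function(k, n) {
    pooled <- .clampP(sum(k) / sum(n))
    binLL <- .bbLogLik(k, n, pooled, 0)
    fn <- function(par) -.bbLogLik(k, n, .expit(par[1]),
                                   .clampP(.expit(par[2]), 1e-8))
    opt <- optim(c(.logit(pooled), .logit(0.05)), fn,
                 method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-10))
    if (-opt$value >= binLL)
        list(ll = -opt$value, psi = .expit(opt$par[1]),
             rho = .expit(opt$par[2]))
    else list(ll = binLL, psi = pooled, rho = 0)
}

# Profile psi at a fixed shared rho (1-D; rho = 0 has the closed form).
.bbProfilePsi <- function(k, n, rho) {
    if (rho < 1e-9) {
        psi <- .clampP(sum(k) / sum(n))
        return(list(ll = .bbLogLik(k, n, psi, 0), psi = psi))
    }
    o <- optimize(function(ps) -.bbLogLik(k, n, ps, rho),
                  c(1e-6, 1 - 1e-6), tol = 1e-9)
    list(ll = -o$objective, psi = o$minimum)
}

#' Beta-binomial delta-PSI test
#'
#' Per event, inclusion successes \code{round((i1+i2)/2)} out of trials
#' \code{successes + e} per sample enter a beta-binomial likelihood with
#' a dispersion shared between groups; the likelihood-ratio test of a
#' common inclusion level against group-specific levels is referred to
#' chi-squared with one degree of freedom. The shared dispersion is
#' maximized numerically on (0,1) under the null and held fixed in both
#' profile fits (the usual nuisance-under-the-null construction, which
#' keeps the small-sample test calibrated), with a binomial (rho = 0)
#' fallback. \code{dpsi = psi_a - psi_b} (group MLEs at the shared
#' dispersion). Events without two coverage-defined samples per group get
#' NA and are excluded from the BH denominator.
#'
#' @param pe a \linkS4class{PsiExperiment}
#' @param groupA,groupB sample-id (or logical) selectors
#' @return DataFrame: event_id, psi_a, psi_b, dpsi, rho, stat, p, padj
#' @export
dpsiTest <- function(pe, groupA, groupB) {
    a <- .resolveSamples(assay(pe, "psi"), groupA, "groupA")
    b <- .resolveSamples(assay(pe, "psi"), groupB, "groupB")
    i1 <- assay(pe, "i1"); i2 <- assay(pe, "i2"); e <- assay(pe, "e")
    psi <- assay(pe, "psi")
    nEv <- nrow(pe)
    psiA <- psiB <- rho <- stat <- p <- rep(NA_real_, nEv)
    for (ev in seq_len(nEv)) {
        okA <- a[!is.na(psi[ev, a])]
        okB <- b[!is.na(psi[ev, b])]
        if (length(okA) < 2L || length(okB) < 2L) next
        sel <- c(okA, okB)
        k <- round((i1[ev, sel] + i2[ev, sel]) / 2)
        n <- k + e[ev, sel]
        inA <- seq_along(okA)
        h0 <- .bbFitNull(k, n)
        p0 <- .bbProfilePsi(k, n, h0$rho)
        pa <- .bbProfilePsi(k[inA], n[inA], h0$rho)
        pb <- .bbProfilePsi(k[-inA], n[-inA], h0$rho)
        # reported group PSIs are the pooled per-group estimates (unbiased
        # under the alternative); the LRT uses the profile likelihoods
        psiA[ev] <- sum(k[inA]) / sum(n[inA])
        psiB[ev] <- sum(k[-inA]) / sum(n[-inA])
        rho[ev] <- h0$rho
        stat[ev] <- max(0, 2 * (pa$ll + pb$ll - p0$ll))
        p[ev] <- pchisq(stat[ev], df = 1, lower.tail = FALSE)
    }
    res <- DataFrame(event_id = rownames(pe), psi_a = psiA, psi_b = psiB,
                     dpsi = psiA - psiB, rho = rho, stat = stat, p = p,
                     padj = bhAdjust(p))
    rownames(res) <- res$event_id
    res
}

#' Per-event z-scored PSI across samples
#'
#' Row-standardizes the PSI matrix: \code{(psi - mean)/sd} per event,
#' computed over non-NA samples (NAs propagate). Constant rows get zeros
#' and are flagged in \code{attr(, "flat")}.
#'
#' @param pe a \linkS4class{PsiExperiment} (or a PSI matrix)
#' @return z-score matrix, events x samples
#' @export
psiZscores <- function(pe) {
    psi <- if (is(pe, "PsiExperiment")) assay(pe, "psi") else as.matrix(pe)
    z <- psi
    flat <- logical(nrow(psi))
    for (i in seq_len(nrow(psi))) {
        v <- psi[i, ]
        ok <- !is.na(v)
        if (sum(ok) < 2L) {
            z[i, ok] <- NA
            next
        }
        s <- sd(v[ok])
        if (s == 0) {
            z[i, ok] <- 0
            flat[i] <- TRUE
        } else z[i, ok] <- (v[ok] - mean(v[ok])) / s
    }
    attr(z, "flat") <- flat
    z
}
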
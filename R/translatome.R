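#' DeltaResult: ribosome-vs-total translational shift ranking
#'
#' A \linkS4class{DFrame} with one row per gene shared by the two input
#' contrasts: \code{lfc_ribo}, \code{lfc_total}, \code{delta} (ribo minus
#' total), \code{se_delta} (variances summed), \code{z}, \code{p},
#' \code{padj} and the signed \code{rank} by delta (1 = most positive;
#' ties broken by gene id).
#'
#' @export
setClass("DeltaResult", contains = "DFrame")

#' Ribosome-vs-total delta statistic
#'
#' For a common condition contrast computed separately in the ribosomal
#' (TRAP) and total fractions, the delta statistic
#' \code{delta = lfc_ribo - lfc_total} ranks genes by translational
#' rather than transcriptional regulation. The two contrasts come from
#' different animals, so their variances are summed:
#' \code{se_delta = sqrt(se_r^2 + se_t^2)}; \code{z = delta/se_delta},
#' two-sided normal p, BH adjustment. The TpM floor (default 100) is
#' applied to the mean TpM across the samples of both fractions; genes
#' present in only one contrast are excluded.
#'
#' @param deRibo,deTotal \linkS4class{DEResult}s for the same condition
#'   comparison in the two fractions
#' @param minMeanTpm TpM floor (default 100; 0 disables; requires
#'   baseMeanTpm in the inputs when positive)
#' @return a \linkS4class{DeltaResult}
#' @examples
#' # delta 0.8 with se 0.2828 gives z 2.83, p ~ 0.0047
#' @export
riboTotalDelta <- function(deRibo, deTotal, minMeanTpm = 100) {
    shared <- intersect(deRibo$gene_id, deTotal$gene_id)
    if (!length(shared))
        stop("empty gene intersection between the two contrasts")
    r <- deRibo[match(shared, deRibo$gene_id), ]
    t <- deTotal[match(shared, deTotal$gene_id), ]
    meanTpm <- rowMeans(cbind(r$baseMeanTpm, t$baseMeanTpm))
    if (minMeanTpm > 0) {
        if (all(is.na(meanTpm)))
            stop("TpM floor requested but baseMeanTpm is missing")
        keep <- !is.na(meanTpm) & meanTpm >= minMeanTpm
        r <- r[keep, ]; t <- t[keep, ]; meanTpm <- meanTpm[keep]
    }
    delta <- r$log2FC - t$log2FC
    seD <- sqrt(r$se^2 + t$se^2)
    z <- delta / seD
    p <- 2 * pnorm(-abs(z))
    ord <- order(-delta, r$gene_id)
    rank <- integer(length(delta))
    rank[ord] <- seq_along(ord)
    res <- DataFrame(gene_id = r$gene_id, lfc_ribo = r$log2FC,
                     lfc_total = t$log2FC, delta = delta, se_delta = seD,
                     z = z, p = p, padj = bhAdjust(p),
                     mean_tpm = meanTpm, rank = rank)
    rownames(res) <- res$gene_id
    out <- new("DeltaResult", res)
    metadata(out) <- list(minMeanTpm = minMeanTpm)
    out
}

#' Top-N genes by signed delta
#'
#' @param delta a \linkS4class{DeltaResult}
#' @param n number of genes (default 300)
#' @param direction "up" (most positive delta) or "down"
#' @return character vector of gene ids, ordered from most extreme;
#'   ties broken lexicographically by gene id
#' @export
topNByDelta <- function(delta, n = 300L, direction = c("up", "down")) {
    direction <- match.arg(direction)
    if (n > nrow(delta))
        stop("n (", n, ") exceeds the gene universe (", nrow(delta), ")")
    d <- if (direction == "up") -delta$delta else delta$delta
    ord <- order(d, delta$gene_id)
    delta$gene_id[head(ord, n)]
}

#' Concordance of the flow response with the knockout response
#'
#' Selects genes responsive to low flow in the wild-type TRAP contrast
#' (p < \code{ldfPThresh}), splits them by LFC sign, and within each
#' group computes the fraction whose knockout-vs-wild-type TRAP LFC lies
#' beyond \code{+eckoLfcThresh} (for flow-up genes) or below
#' \code{-eckoLfcThresh} (for flow-down genes). Genes between the
#' thresholds count in the denominators but in neither concordant nor
#' discordant class; the Fisher exact test associates flow direction with
#' beyond-threshold knockout direction, excluding between-threshold
#' genes. Full quadrant gene lists are returned.
#'
#' @param deLdf \linkS4class{DEResult}: LDF vs contralateral in WT TRAP
#' @param deEcko \linkS4class{DEResult}: ECKO vs WT in TRAP
#' @param ldfPThresh p threshold selecting flow-responsive genes (0.05)
#' @param eckoLfcThresh LFC magnitude threshold on the knockout contrast
#'   (0.5)
#' @param useAdjusted select flow-responsive genes on padj instead of p
#' @param eckoPThresh optional additional p filter on the knockout
#'   contrast (NULL = threshold-only, the default)
#' @return list with counts, \code{frac_up_further_up},
#'   \code{frac_down_further_down}, \code{fisher_p}, the 2x2
#'   \code{table}, and \code{quadrants} (gene lists)
#' @export
concordanceShift <- function(deLdf, deEcko, ldfPThresh = 0.05,
                             eckoLfcThresh = 0.5, useAdjusted = FALSE,
                             eckoPThresh = NULL) {
    shared <- intersect(deLdf$gene_id, deEcko$gene_id)
    a <- deLdf[match(shared, deLdf$gene_id), ]
    b <- deEcko[match(shared, deEcko$gene_id), ]
    sel <- if (useAdjusted) a$padj else a$p
    resp <- !is.na(sel) & sel < ldfPThresh & a$log2FC != 0
    if (!any(resp))
        stop("no LDF-responsive genes at the requested threshold")
    okE <- rep(TRUE, length(shared))
    if (!is.null(eckoPThresh))
        okE <- !is.na(b$p) & b$p < eckoPThresh
    up <- resp & a$log2FC > 0
    dn <- resp & a$log2FC < 0
    furtherUp <- okE & b$log2FC > eckoLfcThresh
    furtherDn <- okE & b$log2FC < -eckoLfcThresh
    quad <- list(up_further_up = shared[up & furtherUp],
                 up_further_down = shared[up & furtherDn],
                 up_between = shared[up & !furtherUp & !furtherDn],
                 down_further_down = shared[dn & furtherDn],
                 down_further_up = shared[dn & furtherUp],
                 down_between = shared[dn & !furtherUp & !furtherDn])
    tab <- matrix(c(sum(up & furtherUp), sum(up & furtherDn),
                    sum(dn & furtherUp), sum(dn & furtherDn)),
                  2, 2, byrow = TRUE,
                  dimnames = list(ldf = c("up", "down"),
                                  ecko = c("further_up", "further_down")))
    fisherP <- if (all(rowSums(tab) > 0))
        fisher.test(tab)$p.value else NA_real_
    list(n_up_ldf = sum(up), n_down_ldf = sum(dn),
         frac_up_further_up = sum(up & furtherUp) / sum(up),
         frac_down_further_down = sum(dn & furtherDn) / sum(dn),
         fisher_p = fisherP, table = tab, quadrants = quad)
}

#' Correlation of two contrasts' fold changes
#'
#' @param deA,deB \linkS4class{DEResult}s (or anything with gene_id and
#'   log2FC)
#' @param method "pearson" or "r_squared" (squared Pearson)
#' @param minMeanTpm optional TpM floor on the shared universe
#' @return a single correlation value
#' @export
responseCorrelation <- function(deA, deB, method = c("pearson", "r_squared"),
                                minMeanTpm = 0) {
    method <- match.arg(method)
    shared <- intersect(deA$gene_id, deB$gene_id)
    a <- deA[match(shared, deA$gene_id), ]
    b <- deB[match(shared, deB$gene_id), ]
    if (minMeanTpm > 0) {
        mt <- rowMeans(cbind(a$baseMeanTpm, b$baseMeanTpm))
        keep <- !is.na(mt) & mt >= minMeanTpm
        a <- a[keep, ]; b <- b[keep, ]
    }
    if (nrow(a) < 3L) stop("need >= 3 shared genes")
    if (sd(a$log2FC) == 0 || sd(b$log2FC) == 0)
        stop("correlation undefined for a constant LFC vector")
    r <- cor(a$log2FC, b$log2FC)
    if (method == "pearson") r else r^2
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric p for each gene set: the probability of
#' observing at least the seen overlap between the query and the set
#' within the universe; BH adjustment across sets.
#'
#' @param query gene set of interest (must be a subset of the universe)
#' @param universe background gene universe
#' @param geneSets named list of gene-id vectors (e.g. from
#'   \code{\link{readGMT}})
#' @return DataFrame with overlap k, set size K, query size n, universe
#'   size N, p and q per set
#' @export
hypergeomORA <- function(query, universe, geneSets) {
    universe <- unique(universe)
    if (!length(universe)) stop("empty universe")
    query <- unique(query)
    bad <- setdiff(query, universe)
    if (length(bad))
        stop("query gene(s) outside the universe: ",
             paste(head(bad, 5), collapse = ", "))
    N <- length(universe); n <- length(query)
    rows <- lapply(names(geneSets), function(nm) {
        set <- intersect(unique(geneSets[[nm]]), universe)
        K <- length(set)
        k <- length(intersect(set, query))
        p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        DataFrame(set = nm, k = k, K = K, n = n, N = N, p = min(p, 1))
    })
    out <- do.call(rbind, rows)
    out$q <- bhAdjust(out$p)
    rownames(out) <- out$set
    out[order(out$p, out$set), ]
}
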
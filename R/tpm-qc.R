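#' Transcripts-per-million quantification
#'
#' \eqn{TpM_{gj} = 10^6 (c_{gj}/L_g) / \sum_g (c_{gj}/L_g)}: length-
#' normalized counts scaled so every sample sums to one million. An
#' all-zero sample yields an all-zero column with a warning.
#'
#' @param object a \linkS4class{TrapExperiment} with
#'   \code{rowData()$gene_length}, or a count matrix (then supply
#'   \code{lengths})
#' @param lengths per-gene lengths (bp) when \code{object} is a matrix
#' @return numeric matrix of TpM values, same dimnames as the counts
#' @examples
#' m <- matrix(c(100, 400), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' computeTPM(m, lengths = c(a = 1000, b = 2000))
#' @export
computeTPM <- function(object, lengths = NULL) {
    if (is(object, "TrapExperiment")) {
        cnt <- assay(object, "counts")
        lengths <- geneLengths(object)
    } else {
        cnt <- as.matrix(object)
    }
    if (is.null(lengths))
        stop("gene lengths are required for TpM")
    if (!is.null(names(lengths)))
        lengths <- lengths[rownames(cnt)]
    if (any(is.na(lengths)) || any(lengths <= 0))
        stop("gene lengths must be present and strictly positive for all genes")
    rate <- cnt / lengths
    tot <- colSums(rate)
    zero <- tot == 0
    if (any(zero)) {
        warning("all-zero sample(s): ",
                paste(colnames(cnt)[zero], collapse = ", "))
        tot[zero] <- 1   # leaves the column all-zero
    }
    sweep(rate, 2, tot, "/") * 1e6
}

.resolveSamples <- function(tpm, sel, what) {
    ids <- if (is.logical(sel)) colnames(tpm)[sel] else as.character(sel)
    bad <- setdiff(ids, colnames(tpm))
    if (length(bad))
        stop(what, ": unknown sample(s) ", paste(bad, collapse = ", "))
    if (!length(ids)) stop(what, ": empty sample selector")
    ids
}

#' Marker-panel fraction-purity QC
#'
#' For each marker panel (e.g. Smtn for mural cells; Cd68 and Adgre1/F4-80
#' for myeloid cells) reports the panel mean TpM in two sample groups
#' (typically ribosomal pulldown vs total flush), their log2 ratio with a
#' pseudocount, and whether the observed direction matches the panel's
#' expectation. The panel statistic is the mean of per-gene mean TpM
#' (panels here are small, 1-3 genes).
#'
#' @param tpm TpM matrix from \code{\link{computeTPM}}
#' @param panels list of panels, each a list with \code{name},
#'   \code{genes} (character) and \code{direction} ("enriched" or
#'   "depleted" in group A vs group B)
#' @param groupA,groupB sample selectors (ids or logical over columns)
#' @param pseudocount TpM pseudocount before the log ratio (default 0.5)
#' @param allowMissing drop panel genes absent from the matrix (default
#'   FALSE: error listing them)
#' @return data.frame with per-panel means, log2 ratio, observed/expected
#'   direction and a flag; per-gene values in
#'   \code{attr(, "perGene")}
#' @export
markerQC <- function(tpm, panels, groupA, groupB, pseudocount = 0.5,
                     allowMissing = FALSE) {
    a <- .resolveSamples(tpm, groupA, "groupA")
    b <- .resolveSamples(tpm, groupB, "groupB")
    perGene <- list()
    rows <- lapply(panels, function(p) {
        stopifnot(!is.null(p$name), length(p$genes) >= 1L)
        miss <- setdiff(p$genes, rownames(tpm))
        if (length(miss) && !allowMissing)
            stop("panel '", p$name, "': gene(s) absent from matrix: ",
                 paste(miss, collapse = ", "))
        genes <- setdiff(p$genes, miss)
        if (!length(genes))
            stop("panel '", p$name, "': no panel genes present")
        gA <- rowMeans(tpm[genes, a, drop = FALSE])
        gB <- rowMeans(tpm[genes, b, drop = FALSE])
        perGene[[p$name]] <<- data.frame(gene_id = genes, mean_a = gA,
                                         mean_b = gB, row.names = NULL)
        mA <- mean(gA); mB <- mean(gB)
        ratio <- log2((mA + pseudocount) / (mB + pseudocount))
        obs <- if (abs(ratio) < .Machine$double.eps^0.5) "no change"
               else if (ratio > 0) "enriched" else "depleted"
        data.frame(panel = p$name, n_genes = length(genes),
                   mean_tpm_a = mA, mean_tpm_b = mB, log2_ratio = ratio,
                   expected = p$direction, observed = obs,
                   flag = if (obs == "no change") "no change"
                          else if (obs == p$direction) "ok"
                          else "direction mismatch",
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "perGene") <- perGene
    out
}

#' Per-gene ribosome-binding report
#'
#' Descriptive comparison of a gene's TpM between the ribosome-bound
#' pulldown and the unbound flow-through (no test): per-fraction means and
#' their ratio.
#'
#' @param tpm TpM matrix
#' @param sampleMeta data.frame with \code{sample_id} and \code{fraction}
#'   (or a \linkS4class{TrapExperiment})
#' @param gene gene id
#' @param fractions the two fractions to compare (numerator first)
#' @return list with \code{means} (named per-fraction mean TpM) and
#'   \code{ratio}
#' @export
fractionBindingReport <- function(tpm, sampleMeta, gene,
                                  fractions = c("ribosomal", "unbound")) {
    if (is(sampleMeta, "TrapExperiment"))
        sampleMeta <- data.frame(sample_id = colnames(sampleMeta),
                                 fraction = fraction(sampleMeta))
    if (!gene %in% rownames(tpm))
        stop("gene absent from matrix: ", gene)
    means <- vapply(fractions, function(f) {
        ids <- sampleMeta$sample_id[sampleMeta$fraction == f]
        ids <- intersect(ids, colnames(tpm))
        if (!length(ids))
            stop("no samples in fraction '", f, "'")
        mean(tpm[gene, ids])
    }, numeric(1))
    list(gene = gene, means = means,
         ratio = unname(means[1] / means[2]))
}
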
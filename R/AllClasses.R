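#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   rowData<- colData colData<- rowRanges rowRanges<-
#' @importFrom GenomicRanges GRanges start end strand seqnames width
#' @importFrom IRanges IRanges
#' @importFrom BiocGenerics counts
NULL

.FRACTIONS <- c("total", "ribosomal", "unbound")
.CONDITIONS <- c("LDF", "contralateral")
.GENOTYPES <- c("WT", "ECKO")
.SEXES <- c("M", "F", "unknown")

#' TrapExperiment: a TRAP-seq count container
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding raw
#' gene-level integer counts (genes x samples) together with the three
#' experimental factors of a TRAP study: \code{fraction} (total mRNA from a
#' Trizol flush, ribosome-bound mRNA from the TRAP pulldown, or the unbound
#' flow-through), \code{condition} (low/disturbed flow, \code{"LDF"}, vs the
#' normal-flow \code{"contralateral"} artery) and \code{genotype}
#' (\code{"WT"} vs endothelial knockout \code{"ECKO"}). Optional per-gene
#' lengths (bp) live in \code{rowData()$gene_length} and feed TpM
#' computation.
#'
#' Validity requires: a \code{"counts"} assay of non-negative whole numbers,
#' unique gene and sample identifiers, factor columns restricted to the
#' tokens above, and \code{pair_id} (when present) linking exactly two
#' samples of the same genotype and fraction (the ligated and contralateral
#' arteries of one animal).
#'
#' @export
setClass("TrapExperiment", contains = "SummarizedExperiment")

.validTrapExperiment <- function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    cnt <- assay(object, "counts")
    if (any(is.na(cnt)))
        msg <- c(msg, "counts contain NA")
    else {
        if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
        if (any(cnt != floor(cnt))) msg <- c(msg, "non-integer count")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene_id")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample_id")
    cd <- colData(object)
    for (fld in c("fraction", "condition", "genotype")) {
        if (!fld %in% names(cd)) {
            msg <- c(msg, sprintf("colData column '%s' is required", fld))
            next
        }
        ok <- switch(fld,
            fraction = .FRACTIONS, condition = .CONDITIONS,
            genotype = .GENOTYPES)
        bad <- setdiff(unique(as.character(cd[[fld]])), ok)
        if (length(bad))
            msg <- c(msg, sprintf("invalid %s value(s): %s", fld,
                                  paste(bad, collapse = ", ")))
    }
    if ("sex" %in% names(cd)) {
        bad <- setdiff(unique(as.character(cd$sex)), .SEXES)
        if (length(bad))
            msg <- c(msg, sprintf("invalid sex value(s): %s",
                                  paste(bad, collapse = ", ")))
    }
    if ("pair_id" %in% names(cd) && all(c("genotype", "fraction") %in% names(cd))) {
        pid <- as.character(cd$pair_id)
        for (p in unique(pid[!is.na(pid) & pid != ""])) {
            i <- which(pid == p)
            if (length(i) != 2L)
                msg <- c(msg, sprintf("pair_id '%s' links %d samples (expected 2)",
                                      p, length(i)))
            else if (length(unique(cd$genotype[i])) != 1L ||
                     length(unique(cd$fraction[i])) != 1L)
                msg <- c(msg, sprintf(
                    "pair_id '%s' links samples of different genotype/fraction", p))
        }
    }
    gl <- rowData(object)$gene_length
    if (!is.null(gl) && any(!is.na(gl) & gl <= 0))
        msg <- c(msg, "gene_length must be strictly positive")
    if (length(msg)) msg else TRUE
}
setValidity("TrapExperiment", .validTrapExperiment)

#' Construct a TrapExperiment
#'
#' @param counts integer matrix, genes x samples, with row and column names.
#' @param colData data.frame or DataFrame of sample metadata with at least
#'   \code{fraction}, \code{condition} and \code{genotype}; row names (or a
#'   \code{sample_id} column) must match the count columns.
#' @param geneLengths optional named numeric vector of per-gene lengths (bp).
#' @return A \linkS4class{TrapExperiment}.
#' @examples
#' cnt <- matrix(rpois(8, 50), 4, 2,
#'               dimnames = list(paste0("g", 1:4), c("s1", "s2")))
#' cd <- data.frame(fraction = "total", condition = c("LDF", "contralateral"),
#'                  genotype = "WT", row.names = c("s1", "s2"))
#' TrapExperiment(cnt, cd)
#' @export
TrapExperiment <- function(counts, colData, geneLengths = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    colData <- as(colData, "DataFrame")
    if ("sample_id" %in% names(colData) && is.null(rownames(colData)))
        rownames(colData) <- colData$sample_id
    if (is.null(rownames(colData)))
        stop("colData needs sample identifiers (row names or sample_id)")
    if (!identical(colnames(counts), rownames(colData))) {
        missing <- setdiff(colnames(counts), rownames(colData))
        if (length(missing))
            stop("sample(s) missing from metadata: ",
                 paste(missing, collapse = ", "))
        counts <- counts[, rownames(colData), drop = FALSE]
    }
    rd <- DataFrame(row.names = rownames(counts))
    if (!is.null(geneLengths))
        rd$gene_length <- unname(geneLengths[rownames(counts)])
    se <- SummarizedExperiment(assays = SimpleList(counts = counts),
                               colData = colData, rowData = rd)
    new("TrapExperiment", se)
}

#' @describeIn TrapExperiment-accessors fraction labels
#' @export
fraction <- function(object) as.character(colData(object)$fraction)

#' Accessors for TrapExperiment metadata
#'
#' \code{fraction}, \code{condition2} and \code{genotype} return the three
#' design factors as character vectors; \code{geneLengths} returns per-gene
#' lengths or NULL.
#'
#' @param object a \linkS4class{TrapExperiment}
#' @name TrapExperiment-accessors
#' @export
condition2 <- function(object) as.character(colData(object)$condition)

#' @describeIn TrapExperiment-accessors genotype labels
#' @export
genotype <- function(object) as.character(colData(object)$genotype)

#' @describeIn TrapExperiment-accessors per-gene lengths (bp), or NULL
#' @export
geneLengths <- function(object) {
    gl <- rowData(object)$gene_length
    if (is.null(gl)) return(NULL)
    names(gl) <- rownames(object)
    gl
}

setMethod("show", "TrapExperiment", function(object) {
    callNextMethod()
    cat("fractions:  ", paste(sort(unique(fraction(object))), collapse = ", "), "\n")
    cat("conditions: ", paste(sort(unique(condition2(object))), collapse = ", "), "\n")
    cat("genotypes:  ", paste(sort(unique(genotype(object))), collapse = ", "), "\n")
})

#' DEResult: one differential-expression contrast
#'
#' A \linkS4class{DFrame} subclass with one row per tested gene and columns
#' \code{gene_id}, \code{baseMean} (mean of normalized counts),
#' \code{baseMeanTpm} (mean TpM, NA without gene lengths), \code{log2FC}
#' (Wald MLE log2 fold change, level A over level B), \code{se},
#' \code{z} (= log2FC/se), \code{p} (two-sided normal), \code{padj}
#' (Benjamini-Hochberg) and \code{flag} (e.g. zero-level continuity
#' correction, non-convergence). The contrast definition is stored in
#' \code{metadata()}.
#'
#' @export
setClass("DEResult", contains = "DFrame")

.validDEResult <- function(object) {
    need <- c("gene_id", "baseMean", "log2FC", "se", "z", "p", "padj")
    miss <- setdiff(need, colnames(object))
    if (length(miss))
        return(paste("missing column(s):", paste(miss, collapse = ", ")))
    p <- object$p
    if (any(!is.na(p) & (p < 0 | p > 1)))
        return("p outside [0,1]")
    ok <- !is.na(p) & !is.na(object$padj)
    if (any(object$padj[ok] < p[ok] - 1e-12))
        return("padj < p")
    TRUE
}
setValidity("DEResult", .validDEResult)

setMethod("show", "DEResult", function(object) {
    ct <- metadata(object)$contrast
    if (!is.null(ct))
        cat(sprintf("DEResult: %s %s vs %s%s\n", ct@factor, ct@levelA, ct@levelB,
                    if (length(ct@stratum))
                        paste0(" [", paste(names(ct@stratum), unlist(ct@stratum),
                                           sep = "=", collapse = ", "), "]")
                    else ""))
    cat(sprintf("%d genes; %d with padj < 0.05\n", nrow(object),
                sum(object$padj < 0.05, na.rm = TRUE)))
    callNextMethod()
})

#' ContrastSpec: a two-level contrast within an optional stratum
#'
#' @slot factor metadata column to contrast (e.g. \code{"condition"})
#' @slot levelA,levelB the two levels; the reported log2FC is A over B
#' @slot stratum named list of fixed metadata filters
#'   (e.g. \code{list(fraction = "ribosomal", genotype = "WT")})
#' @export
setClass("ContrastSpec", representation(factor = "character",
                                        levelA = "character",
                                        levelB = "character",
                                        stratum = "list"))

setValidity("ContrastSpec", function(object) {
    if (object@levelA == object@levelB) return("levelA must differ from levelB")
    TRUE
})

#' @rdname ContrastSpec-class
#' @param factor,levelA,levelB,stratum see slots
#' @export
contrastSpec <- function(factor, levelA, levelB, stratum = list()) {
    new("ContrastSpec", factor = factor, levelA = as.character(levelA),
        levelB = as.character(levelB), stratum = stratum)
}

setMethod("show", "ContrastSpec", function(object) {
    cat(sprintf("ContrastSpec: %s %s vs %s\n", object@factor, object@levelA,
                object@levelB))
    if (length(object@stratum))
        cat("stratum:", paste(names(object@stratum), unlist(object@stratum),
                              sep = "=", collapse = ", "), "\n")
})

#' ExonEventSet: cassette (skipped) exon events
#'
#' Three parallel \linkS4class{GRanges} (upstream, cassette, downstream
#' exon) sharing names (event ids), seqnames and strand. Genomic order is
#' upstream < cassette < downstream irrespective of strand; transcript
#' orientation is applied only at flank extraction. The three diagnostic
#' junctions are derived: inclusion junction i1 spans the upstream intron,
#' i2 the downstream intron, and the exclusion junction e joins the two
#' flanking exons.
#'
#' @export
setClass("ExonEventSet", representation(upstream = "GRanges",
                                        cassette = "GRanges",
                                        downstream = "GRanges"))

setValidity("ExonEventSet", function(object) {
    u <- object@upstream; ca <- object@cassette; d <- object@downstream
    if (length(u) != length(ca) || length(ca) != length(d))
        return("upstream/cassette/downstream must be parallel")
    if (length(ca) == 0L) return(TRUE)
    if (is.null(names(ca)) || anyDuplicated(names(ca)))
        return("events need unique names (event ids)")
    if (!identical(names(u), names(ca)) || !identical(names(d), names(ca)))
        return("names must agree across the three exon sets")
    if (!all(as.character(seqnames(u)) == as.character(seqnames(ca))) ||
        !all(as.character(seqnames(d)) == as.character(seqnames(ca))))
        return("all three exons of an event must share a chromosome")
    if (!all(as.character(strand(ca)) %in% c("+", "-")))
        return("strand must be + or -")
    if (!all(as.character(strand(u)) == as.character(strand(ca))) ||
        !all(as.character(strand(d)) == as.character(strand(ca))))
        return("all three exons of an event must share a strand")
    if (any(end(u) >= start(ca)) || any(end(ca) >= start(d)))
        return("exon order violated: need upstream < cassette < downstream")
    TRUE
})

#' @rdname ExonEventSet-class
#' @param upstream,cassette,downstream parallel named GRanges
#' @export
ExonEventSet <- function(upstream, cassette, downstream) {
    new("ExonEventSet", upstream = upstream, cassette = cassette,
        downstream = downstream)
}

#' @describeIn ExonEventSet-class number of events
#' @param x,object an ExonEventSet
#' @export
setMethod("length", "ExonEventSet", function(x) length(x@cassette))

#' @describeIn ExonEventSet-class event ids
#' @export
setMethod("names", "ExonEventSet", function(x) names(x@cassette))

setMethod("[", "ExonEventSet", function(x, i, j, ..., drop = TRUE) {
    ExonEventSet(x@upstream[i], x@cassette[i], x@downstream[i])
})

#' @describeIn ExonEventSet-class cassette exon ranges
#' @export
cassetteExons <- function(object) object@cassette

#' @describeIn ExonEventSet-class upstream exon ranges
#' @export
upstreamExons <- function(object) object@upstream

#' @describeIn ExonEventSet-class downstream exon ranges
#' @export
downstreamExons <- function(object) object@downstream

#' Derived junctions of cassette-exon events
#'
#' Returns the intron intervals (1-based closed, as GRanges) supporting
#' inclusion (i1: upstream intron, i2: downstream intron) and exclusion
#' (e: upstream exon end to downstream exon start) of each cassette exon.
#'
#' @param events an \linkS4class{ExonEventSet}
#' @param which one of "i1", "i2", "e"
#' @return GRanges parallel to \code{events}
#' @export
eventJunctions <- function(events, which = c("i1", "i2", "e")) {
    which <- match.arg(which)
    u <- events@upstream; ca <- events@cassette; d <- events@downstream
    gr <- switch(which,
        i1 = GRanges(seqnames(ca), IRanges(end(u) + 1L, start(ca) - 1L),
                     strand = strand(ca)),
        i2 = GRanges(seqnames(ca), IRanges(end(ca) + 1L, start(d) - 1L),
                     strand = strand(ca)),
        e  = GRanges(seqnames(ca), IRanges(end(u) + 1L, start(d) - 1L),
                     strand = strand(ca)))
    names(gr) <- names(ca)
    gr
}

setMethod("show", "ExonEventSet", function(object) {
    cat(sprintf("ExonEventSet with %d cassette-exon events on %d sequence(s)\n",
                length(object),
                length(unique(as.character(seqnames(object@cassette))))))
})

#' JunctionSet: split-read junction counts
#'
#' A \linkS4class{RangedSummarizedExperiment} whose rowRanges are intron
#' intervals (1-based closed; converted from 0-based half-open BED / STAR
#' SJ.out.tab coordinates at the I/O boundary) with strand + or -, and
#' whose \code{"counts"} assay holds per-sample unique split-read counts.
#' After \code{\link{clusterFilter}} the rowData carries \code{cluster_id}.
#'
#' @export
setClass("JunctionSet", contains = "RangedSummarizedExperiment")

setValidity("JunctionSet", function(object) {
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    if (!all(as.character(strand(rowRanges(object))) %in% c("+", "-")))
        return("junction strand must be + or -")
    cnt <- assay(object, "counts")
    if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != floor(cnt)))
        return("junction counts must be non-negative integers")
    TRUE
})

#' @rdname JunctionSet-class
#' @param ranges GRanges of intron intervals (strand + or -)
#' @param counts integer matrix, junctions x samples
#' @export
JunctionSet <- function(ranges, counts) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    se <- SummarizedExperiment(assays = SimpleList(counts = counts),
                               rowRanges = ranges)
    new("JunctionSet", se)
}

setMethod("show", "JunctionSet", function(object) {
    cat(sprintf("JunctionSet: %d junctions x %d samples", nrow(object),
                ncol(object)))
    cl <- rowData(object)$cluster_id
    if (!is.null(cl))
        cat(sprintf("; %d clusters", length(unique(cl))))
    cat("\n")
})

#' PsiExperiment: per-event inclusion/exclusion counts and PSI
#'
#' A \linkS4class{SummarizedExperiment} with assays \code{i1}, \code{i2}
#' (inclusion junction reads), \code{e} (exclusion junction reads) and
#' \code{psi} (percent spliced in; NA below the coverage floor), rows =
#' cassette events, columns = samples.
#'
#' @export
setClass("PsiExperiment", contains = "SummarizedExperiment")

setValidity("PsiExperiment", function(object) {
    need <- c("i1", "i2", "e", "psi")
    miss <- setdiff(need, SummarizedExperiment::assayNames(object))
    if (length(miss))
        return(paste("missing assay(s):", paste(miss, collapse = ", ")))
    psi <- assay(object, "psi")
    if (any(!is.na(psi) & (psi < 0 | psi > 1)))
        return("psi outside [0,1]")
    TRUE
})

setMethod("show", "PsiExperiment", function(object) {
    psi <- assay(object, "psi")
    cat(sprintf("PsiExperiment: %d events x %d samples (%.1f%% PSI values below coverage floor)\n",
                nrow(object), ncol(object), 100 * mean(is.na(psi))))
})
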
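suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(GenomicRanges)
    library(S4Vectors)
    library(Biostrings)
})

# A tiny two-fraction, two-condition experiment with fixed counts.
toyExperiment <- function(counts = NULL, nGenes = 4, lengths = NULL) {
    samples <- c("t_L1", "t_L2", "t_C1", "t_C2",
                 "r_L1", "r_L2", "r_C1", "r_C2")
    if (is.null(counts)) {
        set.seed(99)
        counts <- matrix(rpois(nGenes * 8, 100), nGenes, 8)
    }
    dimnames(counts) <- list(sprintf("g%02d", seq_len(nrow(counts))), samples)
    cd <- data.frame(
        fraction = rep(c("total", "ribosomal"), each = 4),
        condition = rep(rep(c("LDF", "contralateral"), each = 2), 2),
        genotype = "WT", row.names = samples)
    TrapExperiment(counts, cd, geneLengths = lengths)
}

# A single cassette-exon event with hand-picked coordinates (1-based):
# upstream [11,40], cassette [101,140], downstream [201,230] on chrT.
toyEvents <- function(strand = "+", chrom = "chrT") {
    mk <- function(s, e) {
        gr <- GRanges(chrom, IRanges(s, e), strand = strand)
        names(gr) <- "ev1"
        gr
    }
    ExonEventSet(mk(11, 40), mk(101, 140), mk(201, 230))
}

# JunctionSet holding given i1/i2/e counts for toyEvents() across samples.
toyJunctions <- function(i1, i2, e, samples = paste0("s", seq_along(i1))) {
    ev <- toyEvents()
    gr <- c(eventJunctions(ev, "i1"), eventJunctions(ev, "i2"),
            eventJunctions(ev, "e"))
    names(gr) <- paste(as.character(seqnames(gr)), start(gr), end(gr),
                       sep = ":")
    cnt <- rbind(i1, i2, e)
    dimnames(cnt) <- list(names(gr), samples)
    JunctionSet(gr, cnt)
}

# Build a PsiExperiment directly from inclusion successes k out of trials n
# (i1 = i2 = k so that (i1+i2)/2 = k and trials = k + e).
psiFromDraws <- function(k, n, minCoverage = 0) {
    e <- n - k
    events <- GRanges("chr1", IRanges(seq_len(nrow(k)) * 1000,
                                      width = 100))
    se <- SummarizedExperiment(assays = SimpleList(
        i1 = k, i2 = k, e = e,
        psi = ifelse(n >= minCoverage & n > 0, k / n, NA)))
    rownames(se) <- rownames(k)
    new("PsiExperiment", se)
}

randomDNA <- function(n, len = 200) {
    vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = ""), character(1))
}
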
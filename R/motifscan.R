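#' Strand-aware flank extraction around cassette exons
#'
#' Returns the \code{window} bp immediately upstream and downstream of
#' each cassette exon in transcript (pre-mRNA 5'->3') orientation: on the
#' plus strand the upstream flank precedes the exon start and the
#' downstream flank follows the exon end; on the minus strand the roles
#' swap and both sequences are reverse-complemented. Windows are clipped
#' at contig bounds (\code{clipped = TRUE}); events left with a
#' zero-length flank are dropped with a warning.
#'
#' @param events an \linkS4class{ExonEventSet}
#' @param genome named \linkS4class{DNAStringSet} (chromosome ->
#'   sequence)
#' @param window flank width in bp (default 200)
#' @return DataFrame: event_id, upstream, downstream (character),
#'   clipped (logical)
#' @export
extractFlanks <- function(events, genome, window = 200L) {
    ca <- cassetteExons(events)
    chrom <- as.character(seqnames(ca))
    miss <- setdiff(unique(chrom), names(genome))
    if (length(miss))
        stop("chromosome(s) missing from genome: ",
             paste(miss, collapse = ", "))
    chromLen <- setNames(Biostrings::width(genome), names(genome))[chrom]
    minus <- as.character(strand(ca)) == "-"
    # genomic windows flanking the cassette exon (1-based closed)
    lS <- pmax(start(ca) - window, 1L); lE <- start(ca) - 1L
    rS <- end(ca) + 1L; rE <- pmin(end(ca) + window, chromLen)
    clipped <- (start(ca) - window < 1L) | (end(ca) + window > chromLen)
    getSeq1 <- function(s, e) {
        out <- character(length(s))
        ok <- e >= s
        for (ch in unique(chrom)) {
            i <- which(chrom == ch & ok)
            if (length(i))
                out[i] <- as.character(subseq(rep(genome[ch], length(i)),
                                              start = s[i], end = e[i]))
        }
        out
    }
    left <- getSeq1(lS, lE)
    right <- getSeq1(rS, rE)
    rc <- function(x) {
        out <- character(length(x))
        nz <- nzchar(x)
        out[nz] <- as.character(reverseComplement(DNAStringSet(x[nz])))
        out
    }
    up <- ifelse(minus, rc(right), left)
    down <- ifelse(minus, rc(left), right)
    keep <- nzchar(up) & nzchar(down)
    if (!all(keep))
        warning(sum(!keep), " event(s) dropped: zero-length flank")
    DataFrame(event_id = names(ca)[keep], upstream = up[keep],
              downstream = down[keep], clipped = clipped[keep])
}

#' Exhaustive k-mer counting over sequences
#'
#' Counts every overlapping k-mer window; windows containing any
#' non-ACGT letter (e.g. N) are skipped and excluded from the scanned
#' position total.
#'
#' @param seqs character vector or \linkS4class{DNAStringSet}
#' @param k word length (default 6)
#' @return list with \code{counts} (named integer vector over all 4^k
#'   k-mers) and \code{positions} (total valid windows scanned)
#' @examples
#' countKmers("AAAAAAA")$counts[["AAAAAA"]]  # 2 overlapping occurrences
#' @export
countKmers <- function(seqs, k = 6L) {
    stopifnot(k >= 1L)
    if (!methods::is(seqs, "DNAStringSet")) {
        seqs <- seqs[nzchar(seqs)]
        seqs <- DNAStringSet(seqs)
    }
    if (!length(seqs)) {
        kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
        return(list(counts = setNames(integer(4^k), kmers), positions = 0L))
    }
    m <- oligonucleotideFrequency(seqs, width = k)
    counts <- colSums(m)
    list(counts = counts, positions = sum(counts))
}

#' Expression-matched background selection
#'
#' Implements the "detected at a similar level but not regulated"
#' comparison: regulated (foreground) events are binned into quantile
#' bins of a detection-level covariate (mean junction-cluster coverage),
#' and up to \code{ratio} times each bin's foreground count is sampled
#' without replacement from the unregulated candidates falling in the
#' same bin. Candidates outside the foreground level range are never
#' selected; bins short of candidates take all available and the deficit
#' is reported in \code{attr(, "deficit")}.
#'
#' @param regulated foreground event ids
#' @param candidates candidate background event ids (disjoint from
#'   \code{regulated})
#' @param level named numeric detection level covering both sets
#' @param bins number of quantile bins (10)
#' @param ratio target background:foreground ratio (3)
#' @param seed RNG seed (mandatory: selection is sampling)
#' @return character vector of selected background event ids
#' @export
matchBackground <- function(regulated, candidates, level, bins = 10L,
                            ratio = 3L, seed) {
    if (missing(seed)) stop("seed is mandatory")
    if (length(intersect(regulated, candidates)))
        stop("candidates must be disjoint from regulated events")
    if (!length(candidates)) stop("no candidate background events")
    miss <- setdiff(c(regulated, candidates), names(level))
    if (length(miss))
        stop("level missing for event(s): ", paste(head(miss, 5),
                                                   collapse = ", "))
    fg <- level[regulated]
    breaks <- unique(quantile(fg, probs = seq(0, 1, length.out = bins + 1)))
    binOf <- function(x) {
        b <- findInterval(x, breaks, rightmost.closed = TRUE)
        b[x < breaks[1] | x > breaks[length(breaks)]] <- NA
        b
    }
    fgBin <- binOf(fg)
    candBin <- binOf(level[candidates])
    withSeed(seed, {
        sel <- character(0)
        deficit <- 0L
        for (b in sort(unique(fgBin))) {
            want <- ratio * sum(fgBin == b)
            pool <- candidates[!is.na(candBin) & candBin == b]
            pool <- sort(pool)
            if (length(pool) <= want) {
                sel <- c(sel, pool)
                deficit <- deficit + (want - length(pool))
            } else sel <- c(sel, sample(pool, want))
        }
        if (deficit > 0)
            warning("background deficit: ", deficit,
                    " event(s) short of the requested ratio")
        structure(sel, deficit = deficit)
    })
}

.kmerTable2 <- function(fgSeqs, bgSeqs, k, region, mode) {
    if (mode == "occurrence") {
        f <- countKmers(fgSeqs, k)
        b <- countKmers(bgSeqs, k)
        fgC <- f$counts; fgP <- f$positions
        bgC <- b$counts; bgP <- b$positions
    } else {
        fm <- oligonucleotideFrequency(DNAStringSet(fgSeqs), width = k) > 0
        bm <- oligonucleotideFrequency(DNAStringSet(bgSeqs), width = k) > 0
        fgC <- colSums(fm); fgP <- length(fgSeqs)
        bgC <- colSums(bm); bgP <- length(bgSeqs)
    }
    if (fgP == 0) stop("no scannable foreground positions")
    DataFrame(kmer = names(fgC), region = region,
              fg_count = unname(fgC), fg_positions = fgP,
              bg_count = unname(bgC), bg_positions = bgP)
}

#' Per-6-mer enrichment in foreground vs background flanks
#'
#' For every k-mer, a 2x2 table of occurrences vs scanned positions
#' (foreground and background) is tested with the two-sided Fisher exact
#' test; the odds ratio gets a 0.5 Haldane correction when any cell is
#' zero. The default tests the upstream and downstream flank regions
#' separately, with BH spanning both regions' tests (2 * 4^k); "both"
#' pools the two flanks first. A presence/absence mode (events carrying
#' the k-mer vs not) is available.
#'
#' @param fg,bg flank tables from \code{\link{extractFlanks}}
#' @param region "separate" (default), "upstream", "downstream" or
#'   "both"
#' @param k word length (default 6)
#' @param mode "occurrence" (position-level counts, default) or
#'   "presence" (per-event)
#' @return DataFrame with counts, odds_ratio, log2_enrichment, zscore,
#'   fisher_p, neglog10_p, bh_q; sorted by p
#' @export
kmerEnrichment <- function(fg, bg, region = c("separate", "upstream",
                                              "downstream", "both"),
                           k = 6L, mode = c("occurrence", "presence")) {
    region <- match.arg(region)
    mode <- match.arg(mode)
    if (!nrow(fg) || !nrow(bg)) stop("empty foreground or background")
    pick <- function(tbl, what) switch(what,
        upstream = tbl$upstream, downstream = tbl$downstream,
        both = c(tbl$upstream, tbl$downstream))
    regions <- if (region == "separate") c("upstream", "downstream")
               else region
    tab <- do.call(rbind, lapply(regions, function(rg)
        .kmerTable2(pick(fg, rg), pick(bg, rg), k, rg, mode)))
    a <- tab$fg_count; b <- tab$fg_positions - tab$fg_count
    c <- tab$bg_count; d <- tab$bg_positions - tab$bg_count
    tab$odds_ratio <- .sampleOddsRatio(a, b, c, d)
    rateF <- (a + 0.5) / (tab$fg_positions + 1)
    rateB <- (c + 0.5) / (tab$bg_positions + 1)
    tab$log2_enrichment <- log2(rateF / rateB)
    pPool <- (a + c) / (tab$fg_positions + tab$bg_positions)
    seP <- sqrt(pPool * (1 - pPool) *
                (1 / tab$fg_positions + 1 / tab$bg_positions))
    tab$zscore <- ifelse(seP > 0,
                         (a / tab$fg_positions - c / tab$bg_positions) / seP,
                         0)
    tab$fisher_p <- fisherPTwoSided(a, b, c, d)
    tab$neglog10_p <- -log10(pmax(tab$fisher_p, .Machine$double.xmin))
    tab$bh_q <- bhAdjust(tab$fisher_p)
    tab <- tab[order(tab$fisher_p, tab$kmer), ]
    rownames(tab) <- NULL
    tab
}

#' Aggregate k-mer enrichment to RNA-binding proteins
#'
#' Scores each RBP motif set by the minimum BH q over its k-mers
#' (primary) and the mean -log10 Fisher p (secondary); k-mers absent
#' from the table contribute q = 1 / p = 1. RBPs are ranked by primary
#' then secondary score, ties broken alphabetically.
#'
#' @param table enrichment table from \code{\link{kmerEnrichment}}
#' @param motifSets named list of k-mer vectors (see
#'   \code{\link{readMotifConfig}})
#' @return DataFrame: rbp, best_kmer, best_q, mean_neglog10_p, rank
#' @export
rbpAggregate <- function(table, motifSets) {
    if (!length(motifSets)) stop("empty motif set list")
    bad <- setdiff(unique(unlist(motifSets)), unique(table$kmer))
    rows <- lapply(names(motifSets), function(nm) {
        km <- motifSets[[nm]]
        sub <- table[table$kmer %in% km, , drop = FALSE]
        if (nrow(sub)) {
            i <- order(sub$bh_q, sub$fisher_p, sub$kmer)[1]
            bestQ <- sub$bh_q[i]; bestK <- sub$kmer[i]
        } else {
            bestQ <- 1; bestK <- NA_character_
        }
        pByK <- tapply(sub$fisher_p, sub$kmer, min)
        pAll <- setNames(rep(1, length(km)), km)
        pAll[names(pByK)] <- pByK
        DataFrame(rbp = nm, best_kmer = bestK, best_q = bestQ,
                  mean_neglog10_p = mean(-log10(pmax(pAll,
                                                     .Machine$double.xmin))))
    })
    out <- do.call(rbind, rows)
    ord <- order(out$best_q, -out$mean_neglog10_p, out$rbp)
    out <- out[ord, ]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- out$rbp
    out
}
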
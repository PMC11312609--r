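flankDF <- function(up, down, ids = paste0("e", seq_along(up))) {
    DataFrame(event_id = ids, upstream = up, downstream = down,
              clipped = FALSE)
}

test_that("flank extraction follows the stated strand convention", {
    # chrom AACCGGTT, cassette exon 0-based [4,6) = 1-based [5,6], window 2
    genome <- DNAStringSet(c(chrM = "AACCGGTT"))
    mkEv <- function(strand) {
        mk <- function(s, e) {
            gr <- GRanges("chrM", IRanges(s, e), strand = strand)
            names(gr) <- "ev"
            gr
        }
        ExonEventSet(mk(1, 2), mk(5, 6), mk(8, 8))
    }
    plus <- extractFlanks(mkEv("+"), genome, window = 2)
    expect_equal(plus$upstream, "CC")     # genome[2,4) 0-based
    expect_equal(plus$downstream, "TT")
    minus <- extractFlanks(mkEv("-"), genome, window = 2)
    expect_equal(minus$upstream, "AA")    # revcomp(genome[6,8)) = rc("TT")
    expect_equal(minus$downstream, "GG")  # revcomp(genome[2,4)) = rc("CC")
    expect_error(extractFlanks(mkEv("+"),
                               DNAStringSet(c(other = "AACCGGTT")), 2),
                 "missing")
})

test_that("windows are clipped at contig bounds and flagged", {
    genome <- DNAStringSet(c(c1 = paste(rep("ACGT", 20), collapse = "")))
    mk <- function(s, e, strand = "+") {
        gr <- GRanges("c1", IRanges(s, e), strand = strand)
        names(gr) <- "ev"
        gr
    }
    # cassette exon at 0-based start 1 (1-based 2): one upstream base left
    ev <- ExonEventSet(mk(1, 1), mk(2, 10), mk(70, 75))
    fl <- extractFlanks(ev, genome, window = 200)
    expect_true(fl$clipped)
    expect_equal(nchar(fl$upstream), 1L)
    expect_equal(nchar(fl$downstream), 80L - 10L)
})

test_that("flanks of mirrored events are identical across strands", {
    set.seed(8)
    s <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
    rc <- as.character(reverseComplement(DNAStringSet(s)))
    genomeF <- DNAStringSet(c(g = s)); genomeR <- DNAStringSet(c(g = rc))
    L <- 2000
    mirror <- function(s1, e1) c(L - e1 + 1, L - s1 + 1)
    mk <- function(u, ca, d, strand) {
        g <- function(x) {
            gr <- GRanges("g", IRanges(x[1], x[2]), strand = strand)
            names(gr) <- "ev"
            gr
        }
        ExonEventSet(g(u), g(ca), g(d))
    }
    evF <- mk(c(500, 550), c(800, 850), c(1100, 1150), "+")
    evR <- mk(mirror(1100, 1150), mirror(800, 850), mirror(500, 550), "-")
    fF <- extractFlanks(evF, genomeF, 100)
    fR <- extractFlanks(evR, genomeR, 100)
    expect_identical(fF$upstream, fR$upstream)
    expect_identical(fF$downstream, fR$downstream)
})

test_that("k-mer counting handles overlaps and N windows", {
    a <- countKmers("AAAAAAA")
    expect_equal(unname(a$counts["AAAAAA"]), 2)
    expect_equal(a$positions, 2)
    b <- countKmers("ACGTACGTA")
    expect_equal(b$positions, 4)
    expect_equal(sum(b$counts > 0), 4L)
    expect_true(all(b$counts[b$counts > 0] == 1))
    n <- countKmers("AANAAA")
    expect_equal(n$positions, 0)
    expect_equal(sum(n$counts), 0)
    # conservation: occurrences sum to scanned positions on N-free input
    set.seed(9)
    seqs <- randomDNA(10, 57)
    ck <- countKmers(seqs)
    expect_equal(ck$positions, 10 * (57 - 6 + 1))
    expect_equal(sum(ck$counts), ck$positions)
})

test_that("background matching is seeded, level-balanced and range-bound", {
    set.seed(10)
    lvl <- c(setNames(runif(40, 80, 100), paste0("r", 1:40)),
             setNames(runif(400, 0, 100), paste0("c", 1:400)))
    reg <- paste0("r", 1:40); cand <- paste0("c", 1:400)
    bg1 <- suppressWarnings(matchBackground(reg, cand, lvl, ratio = 3,
                                            seed = 5))
    bg2 <- suppressWarnings(matchBackground(reg, cand, lvl, ratio = 3,
                                            seed = 5))
    expect_warning(matchBackground(reg, cand, lvl, ratio = 3, seed = 5),
                   "deficit")
    expect_identical(as.character(bg1), as.character(bg2))
    # foreground entirely in the top of the candidate range: every selected
    # candidate lies within the foreground level range
    expect_true(all(lvl[bg1] >= min(lvl[reg])))
    # per-bin balance: mean levels agree within half a bin width
    brks <- quantile(lvl[reg], seq(0, 1, 0.1))
    halfBin <- max(diff(brks)) / 2
    expect_lt(abs(mean(lvl[bg1]) - mean(lvl[reg])), halfBin)
    # exact-level candidates at ratio one reproduce the foreground profile
    lvl2 <- c(lvl[reg], setNames(lvl[reg], paste0("m", 1:40)))
    bgx <- matchBackground(reg, paste0("m", 1:40), lvl2, ratio = 1, seed = 1)
    expect_equal(length(bgx), 40L)
    expect_error(matchBackground(reg, reg, lvl, seed = 1), "disjoint")
    expect_error(matchBackground(reg, character(0), lvl, seed = 1),
                 "candidate")
})

test_that("k-mer enrichment tables have sound stats and edge behavior", {
    set.seed(11)
    fg <- flankDF(randomDNA(10), randomDNA(10))
    bg <- flankDF(randomDNA(10), randomDNA(10), paste0("b", 1:10))
    tab <- kmerEnrichment(fg, bg, region = "both")
    expect_equal(nrow(tab), 4096L)
    expect_true(all(tab$fisher_p >= 0 & tab$fisher_p <= 1))
    expect_true(all(tab$bh_q >= tab$fisher_p - 1e-12))
    absent <- tab[tab$fg_count == 0 & tab$bg_count == 0, ]
    expect_gt(nrow(absent), 0)
    expect_true(all(absent$fisher_p == 1))
    # Haldane-corrected odds ratio is ~1 for equal-size scanned universes
    expect_true(all(abs(log(absent$odds_ratio)) < 0.1))
    # separate mode spans both regions' tests in one BH family
    sep <- kmerEnrichment(fg, bg)
    expect_equal(nrow(sep), 8192L)
    expect_setequal(unique(sep$region), c("upstream", "downstream"))
    expect_error(kmerEnrichment(fg[0, ], bg), "empty")
})

test_that("the vectorized Fisher p matches stats::fisher.test", {
    expect_equal(riboshift:::fisherPTwoSided(3, 1, 1, 3), 34 / 70,
                 tolerance = 1e-12)
    set.seed(12)
    for (i in 1:40) {
        a <- rpois(1, 5); b <- rpois(1, 50)
        c <- rpois(1, 5); d <- rpois(1, 50)
        expect_equal(riboshift:::fisherPTwoSided(a, b, c, d),
                     fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value,
                     tolerance = 1e-9)
    }
})

test_that("a planted 6-mer dominates the enrichment table", {
    set.seed(13)
    motif <- "TGCATG"
    plant <- function(x) {
        off <- sample(195, 1)
        substr(x, off, off + 5) <- motif
        x
    }
    fg <- flankDF(vapply(randomDNA(25), plant, character(1)),
                  vapply(randomDNA(25), plant, character(1)))
    bg <- flankDF(randomDNA(75), randomDNA(75))
    tab <- kmerEnrichment(fg, bg, region = "both")
    expect_equal(tab$kmer[1], motif)
    expect_gt(tab$odds_ratio[1], 2)
    rbp <- rbpAggregate(tab, list(Hit = motif,
                                  Decoy = c("CCCCCC", "GGGGGG")))
    expect_equal(rbp$rbp[rbp$rank == 1], "Hit")
})

test_that("RBP aggregation is deterministic with alphabetical tie-breaks", {
    set.seed(14)
    fg <- flankDF(randomDNA(5), randomDNA(5))
    bg <- flankDF(randomDNA(15), randomDNA(15))
    tab <- kmerEnrichment(fg, bg, region = "both")
    rbp <- rbpAggregate(tab, list(Beta = "AAAAAA", Alpha = "AAAAAA"))
    expect_equal(rbp$best_q, rep(rbp$best_q[1], 2))
    expect_equal(rbp$rbp, c("Alpha", "Beta"))
    expect_error(rbpAggregate(tab, list()), "empty")
})
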
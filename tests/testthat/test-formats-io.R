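test_that("count tables round-trip through TSV exactly", {
    te <- toyExperiment(lengths = c(g01 = 1000, g02 = 1500, g03 = 2000,
                                    g04 = 900))
    cp <- tempfile(fileext = ".tsv"); mp <- tempfile(fileext = ".tsv")
    writeCountsTSV(te, cp, mp)
    te2 <- readCountsTSV(cp, mp)
    expect_identical(assay(te2, "counts"), assay(te, "counts"))
    expect_identical(geneLengths(te2), geneLengths(te))
    expect_identical(fraction(te2), fraction(te))
    expect_identical(condition2(te2), condition2(te))
})

test_that("an all-zero count matrix is valid input", {
    m <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
    cd <- data.frame(fraction = rep("total", 2), condition = "LDF",
                     genotype = "WT", row.names = c("s1", "s2"))
    expect_s4_class(TrapExperiment(m, cd), "TrapExperiment")
})

test_that("count validation rejects bad tables with named errors", {
    dir <- tempfile(); dir.create(dir)
    mp <- file.path(dir, "md.tsv")
    writeLines(c("sample_id\tfraction\tcondition\tgenotype",
                 "s1\ttotal\tLDF\tWT", "s2\ttotal\tcontralateral\tWT"), mp)
    cp <- file.path(dir, "counts.tsv")
    writeLines(c("gene_id\ts1\ts2", "a\t1\t2", "b\t3.7\t4"), cp)
    expect_error(readCountsTSV(cp, mp), "non-integer")
    writeLines(c("gene_id\ts1\ts2", "a\t1\t2", "a\t3\t4"), cp)
    expect_error(readCountsTSV(cp, mp), "duplicate gene_id: a")
    writeLines(c("gene_id\ts1\ts2\ts3", "a\t1\t2\t3"), cp)
    expect_error(readCountsTSV(cp, mp), "missing from metadata: s3")
    file.create(file.path(dir, "empty.tsv"))
    expect_error(readCountsTSV(file.path(dir, "empty.tsv"), mp), "empty")
})

test_that("SJ.out.tab coordinates and strand codes convert correctly", {
    f <- tempfile()
    # 1-based inclusive intron 101..200, strand code 1 (+), 7 unique reads
    writeLines(c("chr1\t101\t200\t1\t1\t0\t7\t0\t20",
                 "chr1\t301\t400\t2\t2\t0\t5\t0\t20"), f)
    js <- readJunctions(f, dialect = "sj_tab", sampleNames = "s1")
    gr <- rowRanges(js)
    # internal 1-based closed [101,200] == 0-based half-open [100,200)
    expect_equal(start(gr)[1], 101)
    expect_equal(end(gr)[1], 200)
    expect_equal(as.character(strand(gr))[1], "+")
    expect_equal(as.character(strand(gr))[2], "-")
    expect_equal(unname(assay(js, "counts")[, "s1"]), c(7, 5))
})

test_that("junctions absent from a sample get count zero", {
    f1 <- tempfile(); f2 <- tempfile()
    writeLines("chr1\t101\t200\t1\t1\t0\t7\t0\t20", f1)
    writeLines("chr1\t501\t600\t1\t1\t0\t3\t0\t20", f2)
    js <- readJunctions(c(a = f1, b = f2), dialect = "sj_tab")
    cnt <- assay(js, "counts")
    expect_equal(unname(cnt[paste("chr1", 101, 200, sep = ":"), ]), c(7, 0))
    expect_equal(unname(cnt[paste("chr1", 501, 600, sep = ":"), ]), c(0, 3))
})

test_that("undefined and inconsistent junction strands are handled", {
    f <- tempfile()
    writeLines(c("chr1\t101\t200\t0\t0\t0\t7\t0\t20",
                 "chr1\t301\t400\t1\t1\t0\t5\t0\t20"), f)
    expect_warning(js <- readJunctions(f, dialect = "sj_tab",
                                       sampleNames = "s1"), "undefined")
    expect_equal(nrow(js), 1L)
    expect_error(readJunctions(f, dialect = "sj_tab", sampleNames = "s1",
                               undefinedStrand = "error"), "undefined")
    f2 <- tempfile()
    writeLines("chr1\t301\t400\t2\t2\t0\t5\t0\t20", f2)
    expect_error(suppressWarnings(
        readJunctions(c(f, f2), dialect = "sj_tab",
                      sampleNames = c("a", "b"))), "inconsistent strand")
})

test_that("BED junction output re-reads unchanged (coordinate involution)", {
    js <- toyJunctions(i1 = c(5, 7), i2 = c(6, 2), e = c(1, 0))
    dir <- tempfile(); dir.create(dir)
    paths <- file.path(dir, paste0(colnames(js), ".bed"))
    writeJunctionsBED(js, paths)
    js2 <- readJunctions(paths, dialect = "bed_like",
                         sampleNames = colnames(js))
    key <- rownames(js)
    expect_setequal(rownames(js2), key)
    expect_equal(start(rowRanges(js2)[key]), start(rowRanges(js)))
    expect_equal(end(rowRanges(js2)[key]), end(rowRanges(js)))
    expect_equal(assay(js2, "counts")[key, ], assay(js, "counts"))
    # normalization is a single pass: another write/read changes nothing
    paths2 <- file.path(dir, paste0(colnames(js), "_2.bed"))
    paths3 <- file.path(dir, paste0(colnames(js), "_3.bed"))
    writeJunctionsBED(js2, paths2)
    js3 <- readJunctions(paths2, dialect = "bed_like",
                         sampleNames = colnames(js2))
    writeJunctionsBED(js3, paths3)
    expect_identical(readLines(paths3[1]), readLines(paths2[1]))
})

test_that("multi-line FASTA records are concatenated and names trimmed", {
    f <- tempfile(fileext = ".fa")
    writeLines(c(">chr1 some description", "ACGT", "ACGT"), f)
    x <- readFasta(f)
    expect_identical(names(x), "chr1")
    expect_identical(as.character(x[[1]]), "ACGTACGT")
})

test_that("GMT files round-trip and reject empty sets", {
    sets <- list(a = c("g1", "g2"), b = "g3")
    f <- tempfile(fileext = ".gmt")
    writeGMT(sets, f)
    got <- readGMT(f)
    expect_identical(got$a, sets$a)
    expect_identical(got$b, sets$b)
    writeLines("badset\tdesc", f)
    expect_error(readGMT(f), "badset")
})

test_that("motif config maps RNA to DNA and validates k-mers", {
    f <- tempfile()
    writeLines("Elavl1: UUUAUU,UUUUUU", f)
    got <- readMotifConfig(f)
    expect_identical(got$Elavl1, c("TTTATT", "TTTTTT"))
    writeLines("Short: UUU", f)
    expect_error(readMotifConfig(f), "Short")
    writeLines("BadAlpha: ABCDEF", f)
    expect_error(readMotifConfig(f), "BadAlpha")
})

test_that("exon events round-trip through the 9-column TSV and BED12", {
    ev <- toyEvents(strand = "-")
    f <- tempfile(fileext = ".tsv")
    writeExonEventsTSV(ev, f)
    ev2 <- readExonEventsTSV(f)
    expect_equal(start(cassetteExons(ev2)), start(cassetteExons(ev)))
    expect_equal(end(downstreamExons(ev2)), end(downstreamExons(ev)))
    expect_equal(as.character(strand(cassetteExons(ev2))), "-")
    # same event as BED12: chromStart 10 (0-based), three blocks
    b <- tempfile(fileext = ".bed")
    writeLines(paste(c("chrT", 10, 230, "ev1", 0, "-", 10, 230, "0",
                       3, "30,40,30", "0,90,190"), collapse = "\t"), b)
    ev3 <- readExonEventsBED12(b)
    expect_equal(start(upstreamExons(ev3)), start(upstreamExons(ev)))
    expect_equal(end(cassetteExons(ev3)), end(cassetteExons(ev)))
    expect_equal(start(downstreamExons(ev3)), start(downstreamExons(ev)))
})

test_that("derived event junctions span the introns", {
    ev <- toyEvents()
    expect_equal(start(eventJunctions(ev, "i1")), 41)
    expect_equal(end(eventJunctions(ev, "i1")), 100)
    expect_equal(start(eventJunctions(ev, "i2")), 141)
    expect_equal(end(eventJunctions(ev, "e")), 200)
})

test_that("results tables round-trip with commented headers", {
    df <- data.frame(gene_id = c("a", "b"), x = c(1.5, -2.25))
    f <- tempfile(fileext = ".tsv")
    writeResultsTable(df, f, params = list(alpha = 0.1))
    expect_true(startsWith(readLines(f, 1), "#"))
    expect_equal(readResultsTable(f), df)
})
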
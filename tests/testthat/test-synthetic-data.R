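baseConfig <- function(...) {
    simulationConfig(nGenes = 200, nEvents = 20, nTranscriptionalUp = 10,
                     nTranscriptionalDown = 10, nTEUp = 5, seed = 42, ...)
}

test_that("simulated counts are a pure function of the seed", {
    a <- simulateCounts(baseConfig())
    b <- simulateCounts(baseConfig())
    expect_identical(assay(a$experiment, "counts"),
                     assay(b$experiment, "counts"))
    c <- simulateCounts(simulationConfig(nGenes = 200, nEvents = 20,
                                         nTranscriptionalUp = 10,
                                         nTranscriptionalDown = 10,
                                         nTEUp = 5, seed = 43))
    expect_false(identical(assay(a$experiment, "counts"),
                           assay(c$experiment, "counts")))
})

test_that("truth tables cover every gene exactly once", {
    sim <- simulateCounts(baseConfig())
    expect_identical(sort(sim$truth$genes$gene_id),
                     sort(rownames(sim$experiment)))
    expect_false(anyDuplicated(sim$truth$genes$gene_id) > 0)
})

test_that("dispersion zero gives the Poisson limit", {
    cfg <- simulationConfig(nGenes = 500, nEvents = 1, repsPerArm = 5,
                            dispersion = 0, muRange = c(100, 100),
                            sizeFactorSdLog = 0,
                            nTranscriptionalUp = 0, nTranscriptionalDown = 0,
                            nTEUp = 0,
                            contamination = c(total = 0, ribosomal = 0,
                                              unbound = 0),
                            includeUnbound = FALSE, genotypes = "WT",
                            seed = 7)
    cnt <- assay(simulateCounts(cfg)$experiment, "counts")
    cnt <- cnt[!rownames(cnt) %in% c("Smtn", "Cd68", "Adgre1", "Icam2"), ]
    x <- as.vector(cnt)            # 10000 draws at mu = 100
    expect_gte(length(x), 10000)
    expect_gt(var(x) / mean(x), 0.95)
    expect_lt(var(x) / mean(x), 1.05)
})

test_that("the all-null generator calibrates a two-sample t-test", {
    cfg <- simulationConfig(nGenes = 2000, repsPerArm = 6, nEvents = 1,
                            nTranscriptionalUp = 0, nTranscriptionalDown = 0,
                            nTEUp = 0,
                            contamination = c(total = 0, ribosomal = 0,
                                              unbound = 0),
                            sizeFactorSdLog = 0,
                            includeUnbound = FALSE, genotypes = "WT",
                            seed = 13)
    te <- simulateCounts(cfg)$experiment
    sel <- fraction(te) == "ribosomal"
    cnt <- log(assay(te, "counts")[, sel] + 1)
    grp <- condition2(te)[sel] == "LDF"
    pv <- apply(cnt, 1, function(y) stats::t.test(y[grp], y[!grp])$p.value)
    expect_gt(mean(pv < 0.05), 0.03)
    expect_lt(mean(pv < 0.05), 0.07)
})

test_that("a translation-only effect appears in the ribosomal fraction only", {
    eff <- data.frame(gene_id = sprintf("gene%04d", 1:50),
                      lfc_ribo_cond = 1)
    cfg <- simulationConfig(nGenes = 500, nEvents = 1, repsPerArm = 5,
                            muRange = c(200, 2000), effects = eff,
                            contamination = c(total = 0, ribosomal = 0,
                                              unbound = 0),
                            includeUnbound = FALSE, genotypes = "WT",
                            seed = 8)
    sim <- simulateCounts(cfg)
    te <- sim$experiment
    sf <- sim$truth$sizeFactors
    ratio <- function(frac) {
        sel <- fraction(te) == frac
        z <- sweep(assay(te, "counts")[, sel], 2, sf[colnames(te)[sel]], "/")
        ldf <- condition2(te)[sel] == "LDF"
        rowMeans(z[1:50, ldf]) / rowMeans(z[1:50, !ldf])
    }
    expect_gt(mean(ratio("ribosomal")), 1.8)
    expect_lt(mean(ratio("ribosomal")), 2.2)
    expect_gt(mean(ratio("total")), 0.9)
    expect_lt(mean(ratio("total")), 1.1)
})

test_that("simulated marginal means match the model means", {
    cfg <- baseConfig()
    sim <- simulateCounts(cfg)
    tg <- sim$truth$genes
    te <- sim$experiment
    null <- tg$gene_id[tg$lfc_total_cond == 0 & tg$lfc_ribo_cond == 0 &
                       tg$lfc_ribo_geno == 0 & tg$lfc_ribo_base == 0]
    sel <- fraction(te) == "total"
    mu <- outer(tg$baseline[match(null, tg$gene_id)] *
                    (1 - sim$truth$contamination["total"]) +
                sim$truth$contamination["total"] *
                    sim$truth$contaminantProfile[null],
                sim$truth$sizeFactors[colnames(te)[sel]])
    y <- assay(te, "counts")[null, sel]
    # z-test on the pooled standardized residual means (NB variance)
    z <- sum(y - mu) / sqrt(sum(mu + 0.1 * mu^2))
    expect_lt(abs(z), 4)
})

test_that("splicing boundaries behave: psi 1 gives no exclusion reads", {
    pb <- data.frame(event_id = sprintf("event%04d", 1:5),
                     psi0 = 1, dpsi = 0)
    cfg <- simulationConfig(nGenes = 10, nEvents = 5,
                            nTranscriptionalUp = 0, nTranscriptionalDown = 0,
                            nTEUp = 0, psiBlock = pb, plantedMotif = "",
                            seed = 3)
    spl <- simulateSplicing(cfg)
    ec <- assay(computePsi(spl$events, spl$junctions), "e")
    expect_true(all(ec == 0))
})

test_that("pooled PSI estimates recover the planted level at high coverage", {
    pb <- data.frame(event_id = sprintf("event%04d", 1:30),
                     psi0 = 0.5, dpsi = 0)
    cfg <- simulationConfig(nGenes = 10, nEvents = 30,
                            nTranscriptionalUp = 0, nTranscriptionalDown = 0,
                            nTEUp = 0, psiBlock = pb, psiRho = 0,
                            eventCoverage = 1000, dispersion = 0,
                            plantedMotif = "", seed = 5)
    spl <- simulateSplicing(cfg)
    pe <- computePsi(spl$events, spl$junctions)
    pooled <- rowMeans(assay(pe, "psi"))
    expect_true(all(abs(pooled - 0.5) < 0.05))
})

test_that("motif insertion probability one plants the 6-mer in every flank", {
    cfg <- simulationConfig(nGenes = 10, nEvents = 20,
                            nTranscriptionalUp = 0, nTranscriptionalDown = 0,
                            nTEUp = 0, nRegulatedEvents = 10,
                            motifProb = 1, seed = 6)
    spl <- simulateSplicing(cfg)
    fl <- extractFlanks(spl$events, spl$genome, cfg@flankWindow)
    reg <- spl$truth$events$event_id[spl$truth$events$regulated]
    i <- match(reg, fl$event_id)
    expect_true(all(grepl("TTTATT", fl$upstream[i], fixed = TRUE)))
    expect_true(all(grepl("TTTATT", fl$downstream[i], fixed = TRUE)))
    # truth records two insertions per regulated event
    expect_equal(nrow(spl$truth$insertions), 2L * length(reg))
})

test_that("emitDataset is deterministic and hash-consistent", {
    d1 <- tempfile(); d2 <- tempfile()
    m1 <- emitDataset(baseConfig(), d1)
    m2 <- emitDataset(baseConfig(), d2)
    f <- list.files(d1, recursive = TRUE)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
    expect_identical(m1$config_md5,
                     unname(tools::md5sum(file.path(d1, "config.yaml"))))
    expect_error(emitDataset(baseConfig(), d1), "force")
    d3 <- tempfile()
    emitDataset(simulationConfig(nGenes = 200, nEvents = 20,
                                 nTranscriptionalUp = 10,
                                 nTranscriptionalDown = 10, nTEUp = 5,
                                 seed = 99), d3)
    expect_false(identical(
        unname(tools::md5sum(file.path(d1, "counts.tsv"))),
        unname(tools::md5sum(file.path(d3, "counts.tsv")))))
})

test_that("configs reject invalid designs", {
    expect_error(simulationConfig(nGenes = 100), "seed")
    expect_error(simulationConfig(
        nGenes = 100, seed = 1,
        effects = data.frame(gene_id = "nope", lfc_ribo_cond = 1)),
        "unknown gene")
    expect_error(simulationConfig(nGenes = 500, seed = 1,
                                  plantedMotif = "TTT"), "6-mer")
})
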
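#' Pipeline configuration
#'
#' A single configuration object carries every stated analysis constant:
#' the flow-response significance threshold (p < 0.05), the knockout LFC
#' threshold (|log2FC| > 0.5), the TpM floor for the delta ranking (100),
#' the top-N size (300), the minimum split reads per intron cluster (50),
#' the flank window (200 bp) and the motif word size (6). Thresholds are
#' config-only; every stochastic stage derives its stream from
#' \code{seed}.
#'
#' @param outdir output directory (data/ and results/ are created inside)
#' @param seed master seed
#' @param nGenes,nEvents,repsPerArm synthetic design size
#' @param ldf_p,ecko_lfc,tpm_floor,top_n,min_cluster_reads,window,k,
#'   min_coverage,bins,ratio analysis constants (see description)
#' @param stages stages to run, in dependency order
#' @param force overwrite existing outputs
#' @return a list of class \code{riboshift_config}
#' @export
pipelineConfig <- function(outdir, seed, nGenes = 2000L, nEvents = 400L,
                           repsPerArm = 5L, ldf_p = 0.05, ecko_lfc = 0.5,
                           tpm_floor = 100, top_n = 300L,
                           min_cluster_reads = 50L, window = 200L, k = 6L,
                           min_coverage = 10, bins = 10L, ratio = 3L,
                           stages = c("simulate", "qc", "de", "delta",
                                      "concordance", "splice", "motifs",
                                      "ora"),
                           force = FALSE) {
    cfg <- list(outdir = outdir, seed = as.integer(seed), nGenes = nGenes,
                nEvents = nEvents, repsPerArm = repsPerArm, ldf_p = ldf_p,
                ecko_lfc = ecko_lfc, tpm_floor = tpm_floor, top_n = top_n,
                min_cluster_reads = min_cluster_reads, window = window,
                k = k, min_coverage = min_coverage, bins = bins,
                ratio = ratio, stages = stages, force = force)
    num <- c("ldf_p", "ecko_lfc", "tpm_floor", "top_n", "min_cluster_reads",
             "window", "k", "min_coverage", "bins", "ratio")
    if (any(unlist(cfg[num]) <= 0))
        stop("all thresholds must be positive")
    if (is.na(cfg$seed)) stop("seed is required")
    class(cfg) <- "riboshift_config"
    cfg
}

#' @rdname pipelineConfig
#' @param path YAML file with any subset of the configuration fields
#'   (must include outdir and seed)
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    if (is.null(y$outdir) || is.null(y$seed))
        stop("pipeline config needs at least outdir and seed")
    do.call(pipelineConfig, y)
}

.logCount <- function(stage, what, before, after) {
    message(sprintf("[%s] %s: %d -> %d", stage, what, before, after))
}

#' Run the full synthetic walkthrough
#'
#' Executes the stages in dependency order: simulate (synthetic dataset
#' with truth) -> qc (TpM + marker depletion) -> de (four NB Wald
#' contrasts: condition within each fraction in WT, genotype within each
#' fraction under LDF) -> delta (ribosome-vs-total ranking, top-N) ->
#' concordance (flow direction vs knockout direction) -> splice (cluster
#' filter, PSI, delta-PSI, z-scores) -> motifs (matched-background 6-mer
#' enrichment, RBP ranking) -> ora (truth-derived gene sets against the
#' top delta genes). Every output is a pure function of the config, so a
#' rerun is byte-identical; a JSON manifest records parameters, row
#' counts and output checksums. A failing stage aborts with its name.
#'
#' @param config from \code{\link{pipelineConfig}}
#' @return invisibly, the manifest list
#' @export
runAll <- function(config) {
    stopifnot(inherits(config, "riboshift_config"))
    dataDir <- file.path(config$outdir, "data")
    resDir <- file.path(config$outdir, "results")
    # validation first: without the simulate stage all inputs must exist
    if (!"simulate" %in% config$stages) {
        need <- file.path(dataDir, c("counts.tsv", "metadata.tsv",
                                     "events.tsv", "genome.fa",
                                     "motifs.txt", "gene_sets.gmt"))
        miss <- need[!file.exists(need)]
        if (length(miss))
            stop("missing input file(s) with simulate stage disabled: ",
                 paste(basename(miss), collapse = ", "))
    }
    dir.create(resDir, recursive = TRUE, showWarnings = FALSE)
    counts <- list()   # row counts for the manifest
    outputs <- character(0)
    stage <- function(name, expr) {
        if (!name %in% config$stages) return(NULL)
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }
    emit <- function(tbl, file, params = NULL) {
        path <- file.path(resDir, file)
        writeResultsTable(as.data.frame(tbl), path, params = params)
        outputs <<- c(outputs, path)
        path
    }

    stage("simulate", {
        emitDataset(simulationConfig(nGenes = config$nGenes,
                                     nEvents = config$nEvents,
                                     repsPerArm = config$repsPerArm,
                                     flankWindow = config$window,
                                     seed = config$seed),
                    dataDir, force = TRUE)
    })
    te <- readCountsTSV(file.path(dataDir, "counts.tsv"),
                        file.path(dataDir, "metadata.tsv"))
    tpm <- computeTPM(te)

    stage("qc", {
        wt <- genotype(te) == "WT"
        panels <- list(
            list(name = "mural_Smtn", genes = "Smtn", direction = "depleted"),
            list(name = "myeloid_Cd68_Adgre1", genes = c("Cd68", "Adgre1"),
                 direction = "depleted"),
            list(name = "endothelial_Icam2", genes = "Icam2",
                 direction = "enriched"))
        qc <- markerQC(tpm, panels,
                       groupA = colnames(te)[wt & fraction(te) == "ribosomal"],
                       groupB = colnames(te)[wt & fraction(te) == "total"])
        emit(qc, "qc_markers.tsv")
        if ("unbound" %in% fraction(te)) {
            fb <- fractionBindingReport(tpm, te, "Icam2")
            emit(data.frame(gene = fb$gene, fraction = names(fb$means),
                            mean_tpm = unname(fb$means), ratio = fb$ratio),
                 "qc_icam2_binding.tsv")
        }
    })

    de <- list()
    stage("de", {
        specs <- list(
            ribo_ldf_wt = contrastSpec("condition", "LDF", "contralateral",
                                       list(fraction = "ribosomal",
                                            genotype = "WT")),
            total_ldf_wt = contrastSpec("condition", "LDF", "contralateral",
                                        list(fraction = "total",
                                             genotype = "WT")),
            ribo_ecko_ldf = contrastSpec("genotype", "ECKO", "WT",
                                         list(fraction = "ribosomal",
                                              condition = "LDF")),
            total_ecko_ldf = contrastSpec("genotype", "ECKO", "WT",
                                          list(fraction = "total",
                                               condition = "LDF")))
        for (nm in names(specs)) {
            de[[nm]] <- fitNBWald(te, specs[[nm]])
            counts[[paste0("de_", nm, "_sig")]] <-
                sum(de[[nm]]$padj < config$ldf_p, na.rm = TRUE)
            emit(de[[nm]], paste0("de_", nm, ".tsv"),
                 params = list(contrast = nm))
        }
    })

    delta <- NULL
    stage("delta", {
        delta <- riboTotalDelta(de$ribo_ldf_wt, de$total_ldf_wt,
                                 minMeanTpm = config$tpm_floor)
        .logCount("delta", "genes passing TpM floor",
                  nrow(de$ribo_ldf_wt), nrow(delta))
        counts$delta_genes <- nrow(delta)
        emit(delta, "delta.tsv", params = list(tpm_floor = config$tpm_floor))
        nTop <- min(config$top_n, nrow(delta))
        emit(data.frame(gene_id = topNByDelta(delta, nTop, "up")),
             "delta_top_up.tsv")
        emit(data.frame(gene_id = topNByDelta(delta, nTop, "down")),
             "delta_top_down.tsv")
    })

    stage("concordance", {
        cc <- concordanceShift(de$ribo_ldf_wt, de$ribo_ecko_ldf,
                               ldfPThresh = config$ldf_p,
                               eckoLfcThresh = config$ecko_lfc)
        counts$concordance_up <- cc$n_up_ldf
        counts$concordance_down <- cc$n_down_ldf
        jsonlite::write_json(
            list(n_up_ldf = cc$n_up_ldf, n_down_ldf = cc$n_down_ldf,
                 frac_up_further_up = cc$frac_up_further_up,
                 frac_down_further_down = cc$frac_down_further_down,
                 fisher_p = cc$fisher_p),
            file.path(resDir, "concordance.json"), auto_unbox = TRUE,
            digits = 10)
        outputs <- c(outputs, file.path(resDir, "concordance.json"))
        quads <- do.call(rbind, lapply(names(cc$quadrants), function(q)
            if (length(cc$quadrants[[q]]))
                data.frame(quadrant = q, gene_id = cc$quadrants[[q]])))
        emit(quads, "concordance_quadrants.tsv")
    })

    pe <- NULL; dps <- NULL
    stage("splice", {
        jdir <- file.path(dataDir, "junctions")
        paths <- sort(list.files(jdir, pattern = "\\.bed$",
                                 full.names = TRUE))
        jset <- readJunctions(paths, dialect = "bed_like")
        jf <- clusterFilter(jset, config$min_cluster_reads)
        .logCount("splice", "junctions passing the cluster filter",
                  nrow(jset), nrow(jf))
        events <- readExonEventsTSV(file.path(dataDir, "events.tsv"))
        # keep events whose exclusion junction survived clustering
        eKey <- paste(as.character(seqnames(eventJunctions(events, "e"))),
                      start(eventJunctions(events, "e")),
                      end(eventJunctions(events, "e")), sep = ":")
        jKey <- paste(as.character(seqnames(rowRanges(jf))),
                      start(rowRanges(jf)), end(rowRanges(jf)), sep = ":")
        keep <- eKey %in% jKey
        .logCount("splice", "events in retained clusters",
                  length(events), sum(keep))
        events <- events[keep]
        pe <- computePsi(events, jf, minCoverage = config$min_coverage)
        grpA <- grep("_LDF_", colnames(pe), value = TRUE)
        grpB <- grep("_contralateral_", colnames(pe), value = TRUE)
        dps <- dpsiTest(pe, grpA, grpB)
        counts$splice_sig <- sum(dps$p < config$ldf_p, na.rm = TRUE)
        .logCount("splice", "events with a defined test",
                  nrow(dps), sum(!is.na(dps$p)))
        emit(cbind(as.data.frame(dps),
                   as.data.frame(assay(pe, "psi"))), "dpsi.tsv")
        emit(as.data.frame(psiZscores(pe)), "psi_zscores.tsv")
    })

    stage("motifs", {
        genomePath <- file.path(dataDir, "genome.fa")
        if (!file.exists(genomePath))
            stop("genome FASTA not found: ", genomePath)
        genome <- readFasta(genomePath)
        events <- readExonEventsTSV(file.path(dataDir, "events.tsv"))
        ok <- !is.na(dps$p)
        reg <- dps$event_id[ok & dps$p < config$ldf_p]
        cand <- dps$event_id[ok & dps$p >= config$ldf_p]
        level <- rowMeans((assay(pe, "i1") + assay(pe, "i2")) / 2 +
                          assay(pe, "e"))
        bg <- matchBackground(reg, cand, level, bins = config$bins,
                              ratio = config$ratio,
                              seed = subSeed(config$seed, "background"))
        .logCount("motifs", "foreground/background events",
                  length(reg), length(bg))
        fgF <- extractFlanks(events[match(reg, names(events))], genome,
                             config$window)
        bgF <- extractFlanks(events[match(bg, names(events))], genome,
                             config$window)
        enr <- kmerEnrichment(fgF, bgF, region = "separate", k = config$k)
        emit(enr, "kmer_enrichment.tsv",
             params = list(window = config$window, k = config$k,
                           ratio = config$ratio))
        motifs <- readMotifConfig(file.path(dataDir, "motifs.txt"),
                                  k = config$k)
        emit(rbpAggregate(enr, motifs), "rbp_ranking.tsv")
    })

    stage("ora", {
        sets <- readGMT(file.path(dataDir, "gene_sets.gmt"))
        nTop <- min(config$top_n, nrow(delta))
        emit(hypergeomORA(topNByDelta(delta, nTop, "up"),
                          delta$gene_id, sets), "ora_top_up.tsv")
    })

    manifest <- list(
        seed = config$seed,
        parameters = config[setdiff(names(config), c("outdir", "stages",
                                                     "force"))],
        stages = config$stages,
        row_counts = counts,
        outputs = as.list(tools::md5sum(sort(unique(outputs)))))
    names(manifest$outputs) <- basename(names(manifest$outputs))
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = 10)
    invisible(manifest)
}
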
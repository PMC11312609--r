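#' SimulationConfig: the synthetic study design
#'
#' Captures the generative counterpart of every quantity the pipeline
#' estimates: negative-binomial gene counts with per-sample size factors
#' and fraction-specific contamination, condition effects that may differ
#' between the total and ribosomal fractions (translational shifts), a
#' genotype effect confined to the ribosomal fraction with a planted
#' concordance structure, beta-binomial cassette-exon inclusion with a
#' planted delta-PSI, and a 6-mer motif inserted into the flanks of
#' regulated exons. All randomness derives from \code{seed}.
#'
#' The defaults emulate the deposited two-fraction (plus unbound
#' flow-through), two-condition, two-genotype carotid-ligation design with
#' five animals per arm, shared NB dispersion 0.1, log-uniform baseline
#' means, 10\%/1\% contaminant mixing into the total/ribosomal fractions,
#' unit-LFC transcriptional and translational effect blocks, a 0.4
#' delta-PSI in regulated exons, and an AU-rich 6-mer planted at
#' probability 0.6 per regulated flank.
#'
#' @export
setClass("SimulationConfig", representation(
    nGenes = "integer", nEvents = "integer", repsPerArm = "integer",
    dispersion = "numeric", muRange = "numeric", sizeFactorSdLog = "numeric",
    effects = "data.frame", contamination = "numeric",
    markerGenes = "character", includeUnbound = "logical",
    genotypes = "character", psiBlock = "data.frame",
    eventCoverage = "numeric", psiRho = "numeric",
    plantedMotif = "character", motifProb = "numeric",
    flankWindow = "integer", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "seed is mandatory")
    if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
    if (any(object@contamination < 0 | object@contamination > 1))
        msg <- c(msg, "contamination proportions must lie in [0,1]")
    if (object@motifProb < 0 || object@motifProb > 1)
        msg <- c(msg, "motifProb must lie in [0,1]")
    if (!all(is.finite(as.matrix(object@effects[-1]))))
        msg <- c(msg, "effect LFCs must be finite")
    with(object@psiBlock, {
        if (any(psi0 < 0 | psi0 > 1) || any(psi0 + dpsi < 0 | psi0 + dpsi > 1))
            msg <<- c(msg, "psi values must stay in [0,1]")
    })
    if (length(msg)) msg else TRUE
})

#' @rdname SimulationConfig-class
#'
#' @param nGenes number of bulk genes (marker genes are appended)
#' @param nEvents number of cassette-exon events
#' @param repsPerArm animals per arm (5 by default; the deposited design
#'   varies between 4 and 6 per assay)
#' @param dispersion shared NB dispersion alpha (variance mu + alpha mu^2);
#'   0 gives the Poisson limit
#' @param muRange log-uniform range of baseline expected counts
#' @param sizeFactorSdLog sd(log) of the log-normal per-sample size factors
#' @param effects optional data.frame(gene_id, lfc_total_cond,
#'   lfc_ribo_cond, lfc_ribo_geno, lfc_ribo_base); built from the block
#'   arguments when NULL
#' @param nTranscriptionalUp,nTranscriptionalDown genes with the condition
#'   effect in both fractions (transcriptional response)
#' @param nTEUp genes with the condition effect in the ribosomal fraction
#'   only (translational shift)
#' @param effectLfc magnitude (log2) of the planted condition effects
#' @param concordUp,concordDown fraction of ribosome-up (-down) responders
#'   whose ECKO effect is concordant (+1 for up, -1 for down); the
#'   remainder get the discordant sign
#' @param contamination named mixing proportions per fraction
#' @param includeUnbound also simulate the TRAP flow-through fraction
#' @param genotypes genotypes to simulate
#' @param psiBlock optional data.frame(event_id, psi0, dpsi); built from
#'   \code{nRegulatedEvents}/\code{dpsiPlanted} when NULL
#' @param nRegulatedEvents events receiving \code{dpsiPlanted} under LDF
#' @param dpsiPlanted planted change in inclusion under LDF
#' @param eventCoverage mean junction-read coverage per event cluster
#' @param psiRho beta-binomial overdispersion of per-sample inclusion
#' @param plantedMotif 6-mer inserted into regulated-event flanks ("" to
#'   disable)
#' @param motifProb per-flank insertion probability
#' @param flankWindow flank width (bp) sized into the synthetic genome
#' @param seed mandatory RNG seed
#' @export
simulationConfig <- function(nGenes = 2000L, nEvents = 400L, repsPerArm = 5L,
                             dispersion = 0.1, muRange = c(20, 2000),
                             sizeFactorSdLog = 0.15, effects = NULL,
                             nTranscriptionalUp = 100L,
                             nTranscriptionalDown = 100L, nTEUp = 50L,
                             effectLfc = 1, concordUp = 0.80,
                             concordDown = 0.86,
                             contamination = c(total = 0.10,
                                               ribosomal = 0.01,
                                               unbound = 0.10),
                             includeUnbound = TRUE,
                             genotypes = c("WT", "ECKO"), psiBlock = NULL,
                             nRegulatedEvents = min(60L, nEvents),
                             dpsiPlanted = 0.4,
                             eventCoverage = 100, psiRho = 0.05,
                             plantedMotif = "TTTATT", motifProb = 0.6,
                             flankWindow = 200L, seed) {
    if (missing(seed)) stop("seed is mandatory")
    markers <- c("Smtn", "Cd68", "Adgre1", "Icam2")
    geneIds <- c(sprintf("gene%04d", seq_len(nGenes)), markers)
    if (is.null(effects)) {
        nUp <- nTranscriptionalUp; nDn <- nTranscriptionalDown; nTE <- nTEUp
        stopifnot(nUp + nDn + nTE <= nGenes)
        eff <- data.frame(gene_id = geneIds,
                          lfc_total_cond = 0, lfc_ribo_cond = 0,
                          lfc_ribo_geno = 0, lfc_ribo_base = 0)
        iUp <- seq_len(nUp)
        iDn <- nUp + seq_len(nDn)
        iTE <- nUp + nDn + seq_len(nTE)
        eff$lfc_total_cond[iUp] <- effectLfc
        eff$lfc_ribo_cond[iUp] <- effectLfc
        eff$lfc_total_cond[iDn] <- -effectLfc
        eff$lfc_ribo_cond[iDn] <- -effectLfc
        eff$lfc_ribo_cond[iTE] <- effectLfc
        riboUp <- c(iUp, iTE)
        nConc <- round(concordUp * length(riboUp))
        eff$lfc_ribo_geno[riboUp] <- rep(c(effectLfc, -effectLfc),
                                         c(nConc, length(riboUp) - nConc))
        nConcD <- round(concordDown * length(iDn))
        eff$lfc_ribo_geno[iDn] <- rep(c(-effectLfc, effectLfc),
                                      c(nConcD, length(iDn) - nConcD))
        # Icam2-like illustration: constitutively ribosome-enriched 2.4x
        eff$lfc_ribo_base[eff$gene_id == "Icam2"] <- log2(2.4)
        effects <- eff
    } else {
        bad <- setdiff(effects$gene_id, geneIds)
        if (length(bad))
            stop("effect references unknown gene(s): ",
                 paste(bad, collapse = ", "))
        base <- data.frame(gene_id = geneIds, lfc_total_cond = 0,
                           lfc_ribo_cond = 0, lfc_ribo_geno = 0,
                           lfc_ribo_base = 0)
        i <- match(effects$gene_id, base$gene_id)
        for (colnm in setdiff(names(effects), "gene_id"))
            base[[colnm]][i] <- effects[[colnm]]
        effects <- base
    }
    if (is.null(psiBlock)) {
        stopifnot(nRegulatedEvents <= nEvents)
        eid <- sprintf("event%04d", seq_len(nEvents))
        reg <- seq_len(nRegulatedEvents)
        psi0 <- rep(0.5, nEvents)
        dpsi <- rep(0, nEvents)
        # alternate inclusion-gain / inclusion-loss among regulated events
        psi0[reg] <- ifelse(reg %% 2L == 1L, 0.3, 0.7)
        dpsi[reg] <- ifelse(reg %% 2L == 1L, dpsiPlanted, -dpsiPlanted)
        psiBlock <- data.frame(event_id = eid, psi0 = psi0, dpsi = dpsi)
    }
    if (nzchar(plantedMotif)) {
        plantedMotif <- chartr("U", "T", toupper(plantedMotif))
        if (nchar(plantedMotif) != 6L || grepl("[^ACGT]", plantedMotif))
            stop("plantedMotif must be a DNA 6-mer")
    }
    new("SimulationConfig", nGenes = as.integer(nGenes),
        nEvents = as.integer(nEvents), repsPerArm = as.integer(repsPerArm),
        dispersion = dispersion, muRange = as.numeric(muRange),
        sizeFactorSdLog = sizeFactorSdLog, effects = effects,
        contamination = contamination, markerGenes = markers,
        includeUnbound = includeUnbound, genotypes = genotypes,
        psiBlock = psiBlock, eventCoverage = eventCoverage, psiRho = psiRho,
        plantedMotif = plantedMotif, motifProb = motifProb,
        flankWindow = as.integer(flankWindow), seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(paste0("SimulationConfig: %d genes, %d events, %d reps/arm, ",
                       "alpha=%g, seed=%d\n"),
                object@nGenes, object@nEvents, object@repsPerArm,
                object@dispersion, object@seed))
})

.rnbOrPois <- function(n, mu, alpha) {
    if (alpha <= 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / alpha)
}

#' Simulate the gene-count arm of the design
#'
#' Counts are drawn gene-wise from a negative binomial with mean
#' \eqn{\mu_{gj} = s_j [ q_g 2^{\sum effects(j)} (1 - c_{f(j)}) +
#' c_{f(j)} \, contaminant_g ]} and variance \eqn{\mu + \alpha \mu^2},
#' where \eqn{s_j} is a log-normal size factor, the effect sum collects
#' the condition/genotype/fraction LFCs applying to sample j's labels, and
#' the fraction-specific contaminant admixture carries the mural/myeloid
#' marker profile. Fully reproducible from the config seed.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @return list with \code{experiment} (a \linkS4class{TrapExperiment})
#'   and \code{truth} (per-gene planted LFCs, translational-shift and
#'   concordance flags, size factors, contamination)
#' @export
simulateCounts <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    withSeed(subSeed(config@seed, "counts"), {
        eff <- config@effects
        geneIds <- eff$gene_id
        nG <- length(geneIds)
        markers <- config@markerGenes
        contaminantMarkers <- setdiff(markers, "Icam2")
        q <- exp(runif(nG, log(config@muRange[1]), log(config@muRange[2])))
        names(q) <- geneIds
        q["Icam2"] <- 500
        q[contaminantMarkers] <- 2       # near-absent in endothelium
        lens <- round(runif(nG, 500, 3000))
        names(lens) <- geneIds
        # contaminant profile: bulk background plus strong marker expression
        cont <- q
        cont[contaminantMarkers] <- 0.02 * sum(q)
        cont <- cont * sum(q) / sum(cont)

        fractions <- c("total", "ribosomal",
                       if (config@includeUnbound) "unbound")
        design <- expand.grid(rep = seq_len(config@repsPerArm),
                              condition = .CONDITIONS,
                              fraction = fractions,
                              genotype = config@genotypes,
                              stringsAsFactors = FALSE)
        design$sample_id <- with(design, paste(genotype, fraction, condition,
                                               sprintf("r%d", rep), sep = "_"))
        design$pair_id <- with(design, paste(genotype, fraction,
                                             sprintf("m%d", rep), sep = "_"))
        design$sex <- c("M", "F")[design$rep %% 2L + 1L]
        nS <- nrow(design)
        sf <- rlnorm(nS, 0, config@sizeFactorSdLog)
        names(sf) <- design$sample_id

        lfc <- matrix(0, nG, nS)
        isLDF <- design$condition == "LDF"
        isRibo <- design$fraction == "ribosomal"
        isTotalLike <- !isRibo     # total and unbound share the total response
        isECKO <- design$genotype == "ECKO"
        lfc[, isLDF & isTotalLike] <- eff$lfc_total_cond
        lfc[, isLDF & isRibo] <- eff$lfc_ribo_cond
        lfc[, isRibo] <- lfc[, isRibo] + eff$lfc_ribo_base
        lfc[, isRibo & isECKO] <- lfc[, isRibo & isECKO] + eff$lfc_ribo_geno
        cfrac <- config@contamination[design$fraction]
        mu <- (q * 2^lfc) %*% diag(1 - cfrac) + cont %*% t(cfrac)
        mu <- mu %*% diag(sf)
        counts <- matrix(.rnbOrPois(length(mu), as.vector(mu),
                                    config@dispersion),
                         nG, nS, dimnames = list(geneIds, design$sample_id))

        cd <- design[, c("sample_id", "fraction", "condition", "genotype",
                         "sex", "pair_id")]
        rownames(cd) <- cd$sample_id
        te <- TrapExperiment(counts, cd, geneLengths = lens)
        truthGenes <- data.frame(
            gene_id = geneIds, baseline = unname(q),
            gene_length = unname(lens),
            eff[-1],
            te_shift = eff$lfc_ribo_cond != eff$lfc_total_cond,
            stringsAsFactors = FALSE)
        list(experiment = te,
             truth = list(genes = truthGenes,
                          sizeFactors = sf,
                          contamination = config@contamination,
                          contaminantProfile = cont))
    })
}

# genomic layout of one synthetic event (gap | U | intron | C | intron | D)
.eventLayout <- function(config) {
    W <- config@flankWindow
    list(gap = 2L * W, uLen = 100L, intron = W + 100L, cLen = 120L,
         dLen = 100L)
}

#' Simulate the splicing arm: events, junction counts, genome
#'
#' Cassette-exon events are laid out on a synthetic uniform-i.i.d. DNA
#' chromosome with introns wide enough to host the flank window. Per
#' sample, cluster junction-read coverage T is negative binomial; the
#' inclusion-read count is beta-binomial out of T with read-level
#' inclusion fraction 2*psi/(1+psi) (an included isoform carries two
#' junctions), so the standard SE-event estimator
#' psi = ((i1+i2)/2)/((i1+i2)/2+e) is consistent; i1/i2 split the
#' inclusion reads by a fair binomial. Regulated events receive the
#' planted delta-PSI under LDF, and their flanks carry the planted 6-mer
#' (inserted in transcript orientation at a uniform offset) with the
#' configured probability; every insertion is recorded in the truth.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @param nPerGroup samples per condition arm (default \code{repsPerArm})
#' @return list with \code{events} (\linkS4class{ExonEventSet}),
#'   \code{junctions} (\linkS4class{JunctionSet}), \code{genome}
#'   (\linkS4class{DNAStringSet}), \code{samples} (data.frame) and
#'   \code{truth} (per-event psi by arm, regulated flags, insertions)
#' @export
simulateSplicing <- function(config, nPerGroup = config@repsPerArm) {
    stopifnot(is(config, "SimulationConfig"), config@nEvents >= 1L)
    validObject(config)
    withSeed(subSeed(config@seed, "splicing"), {
        L <- .eventLayout(config)
        span <- L$gap + L$uLen + L$intron + L$cLen + L$intron + L$dLen
        nE <- config@nEvents
        chromLen <- nE * span + L$gap
        genome <- paste(sample(c("A", "C", "G", "T"), chromLen,
                               replace = TRUE), collapse = "")

        off <- (seq_len(nE) - 1L) * span + L$gap          # 0-based event start
        uS <- off; uE <- uS + L$uLen
        cS <- uE + L$intron; cE <- cS + L$cLen
        dS <- cE + L$intron; dE <- dS + L$dLen
        if (any(dE + config@flankWindow > chromLen))
            stop("event flanks would run off the chromosome")
        std <- ifelse(seq_len(nE) %% 2L == 1L, "+", "-")
        eid <- config@psiBlock$event_id
        mk <- function(s, e) {
            gr <- GRanges("chrS", IRanges(s + 1L, e), strand = std)
            names(gr) <- eid
            gr
        }
        events <- ExonEventSet(mk(uS, uE), mk(cS, cE), mk(dS, dE))

        samples <- expand.grid(rep = seq_len(nPerGroup),
                               condition = .CONDITIONS,
                               stringsAsFactors = FALSE)
        samples$sample_id <- with(samples, sprintf("ribo_%s_r%d", condition, rep))
        nS <- nrow(samples)

        psiArm <- cbind(LDF = config@psiBlock$psi0 + config@psiBlock$dpsi,
                        contralateral = config@psiBlock$psi0)
        i1 <- i2 <- e <- matrix(0, nE, nS,
                                dimnames = list(eid, samples$sample_id))
        rho <- config@psiRho
        for (j in seq_len(nS)) {
            psi <- psiArm[, samples$condition[j]]
            Tj <- .rnbOrPois(nE, config@eventCoverage, config@dispersion)
            pstar <- 2 * psi / (1 + psi)
            p <- pstar
            if (rho > 0) {
                mid <- pstar > 0 & pstar < 1
                p[mid] <- rbeta(sum(mid), pstar[mid] * (1 - rho) / rho,
                                (1 - pstar[mid]) * (1 - rho) / rho)
            }
            incl <- rbinom(nE, Tj, p)
            i1[, j] <- rbinom(nE, incl, 0.5)
            i2[, j] <- incl - i1[, j]
            e[, j] <- Tj - incl
        }
        jun <- rbind(
            cbind(chrom = "chrS", start = uE + 1L, end = cS, kind = "i1"),
            cbind(chrom = "chrS", start = cE + 1L, end = dS, kind = "i2"),
            cbind(chrom = "chrS", start = uE + 1L, end = dS, kind = "e"))
        gr <- GRanges(jun[, "chrom"],
                      IRanges(as.integer(jun[, "start"]),
                              as.integer(jun[, "end"])),
                      strand = rep(std, 3L))
        names(gr) <- paste(as.character(seqnames(gr)), start(gr), end(gr),
                           sep = ":")
        jcnt <- rbind(i1, i2, e)
        rownames(jcnt) <- names(gr)
        jset <- JunctionSet(gr, jcnt)

        regulated <- config@psiBlock$dpsi != 0
        insertions <- data.frame(event_id = character(), side = character(),
                                 offset = integer(), stringsAsFactors = FALSE)
        if (nzchar(config@plantedMotif) && any(regulated)) {
            W <- config@flankWindow
            k <- nchar(config@plantedMotif)
            rc <- as.character(reverseComplement(
                DNAStringSet(config@plantedMotif)))
            for (i in which(regulated)) {
                for (side in c("upstream", "downstream")) {
                    if (runif(1) > config@motifProb) next
                    # genomic window of this flank (0-based half-open)
                    win <- if (std[i] == "+") {
                        if (side == "upstream") c(cS[i] - W, cS[i])
                        else c(cE[i], cE[i] + W)
                    } else {
                        if (side == "upstream") c(cE[i], cE[i] + W)
                        else c(cS[i] - W, cS[i])
                    }
                    offTx <- sample.int(W - k + 1L, 1L)   # transcript offset
                    gStart <- if (std[i] == "+") win[1] + offTx
                              else win[2] - offTx - k + 2L
                    ins <- if (std[i] == "+") config@plantedMotif else rc
                    substr(genome, gStart, gStart + k - 1L) <- ins
                    insertions <- rbind(insertions, data.frame(
                        event_id = eid[i], side = side, offset = offTx,
                        stringsAsFactors = FALSE))
                }
            }
        }
        genomeSet <- DNAStringSet(setNames(genome, "chrS"))
        truthEvents <- data.frame(event_id = eid,
                                  psi_contra = psiArm[, "contralateral"],
                                  psi_ldf = psiArm[, "LDF"],
                                  dpsi = config@psiBlock$dpsi,
                                  regulated = regulated,
                                  stringsAsFactors = FALSE)
        list(events = events, junctions = jset, genome = genomeSet,
             samples = samples[, c("sample_id", "condition")],
             truth = list(events = truthEvents, insertions = insertions))
    })
}

#' Write a complete synthetic dataset to disk
#'
#' Emits the count and metadata TSVs, per-sample junction BEDs, the event
#' table, the genome FASTA, an RBP motif config (the planted AU-rich 6-mer
#' under Elavl1, a CU-rich decoy under Ptbp1 -- illustrative sets, not
#' measured ground truth), truth-derived GMT gene sets for ORA, the truth
#' tables, and a manifest recording the seed and a config hash. Outputs
#' are byte-identical for identical configs.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @param outdir output directory
#' @param force overwrite an existing directory
#' @return invisibly, the manifest as a list
#' @export
emitDataset <- function(config, outdir, force = FALSE) {
    if (dir.exists(outdir) && length(dir(outdir)) && !force)
        stop("output directory exists (use force = TRUE): ", outdir)
    dir.create(file.path(outdir, "junctions"), recursive = TRUE,
               showWarnings = FALSE)
    cnt <- simulateCounts(config)
    spl <- simulateSplicing(config)
    p <- function(...) file.path(outdir, ...)
    writeCountsTSV(cnt$experiment, p("counts.tsv"), p("metadata.tsv"))
    jPaths <- p("junctions", paste0(colnames(spl$junctions), ".bed"))
    writeJunctionsBED(spl$junctions, jPaths)
    writeExonEventsTSV(spl$events, p("events.tsv"))
    writeFasta(spl$genome, p("genome.fa"))
    motifs <- list(Elavl1 = unique(c(config@plantedMotif[nzchar(config@plantedMotif)],
                                     "TTTTTT", "ATTTTA")),
                   Ptbp1 = c("TCTTCT", "CTTCTT", "TTCTCT"))
    writeMotifConfig(motifs, p("motifs.txt"))
    tg <- cnt$truth$genes
    sets <- list(planted_te_up = tg$gene_id[tg$te_shift],
                 planted_transcriptional_up =
                     tg$gene_id[tg$lfc_total_cond > 0 & tg$lfc_ribo_cond > 0],
                 planted_transcriptional_down =
                     tg$gene_id[tg$lfc_total_cond < 0],
                 unperturbed_tail = utils::tail(
                     tg$gene_id[tg$lfc_total_cond == 0 &
                                tg$lfc_ribo_cond == 0], 100))
    attr(sets, "description") <- rep("synthetic truth-derived set",
                                     length(sets))
    writeGMT(sets, p("gene_sets.gmt"))
    writeResultsTable(tg, p("truth_genes.tsv"))
    writeResultsTable(spl$truth$events, p("truth_events.tsv"))
    writeResultsTable(spl$truth$insertions, p("truth_insertions.tsv"))
    cfgYaml <- yaml::as.yaml(.configAsList(config))
    writeLines(cfgYaml, p("config.yaml"))
    manifest <- list(seed = config@seed,
                     config_md5 = unname(tools::md5sum(p("config.yaml"))),
                     files = as.list(tools::md5sum(sort(c(
                         p(c("counts.tsv", "metadata.tsv", "events.tsv",
                             "genome.fa", "motifs.txt", "gene_sets.gmt",
                             "truth_genes.tsv", "truth_events.tsv",
                             "truth_insertions.tsv")), jPaths)))))
    names(manifest$files) <- basename(names(manifest$files))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    invisible(manifest)
}

.configAsList <- function(config) {
    sl <- methods::slotNames(config)
    out <- lapply(sl, function(s) {
        v <- methods::slot(config, s)
        if (is.data.frame(v)) as.list(v) else v
    })
    names(out) <- sl
    out
}
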
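#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement oligonucleotideFrequency subseq
NULL

.readTsv <- function(path, header = TRUE, colClasses = NA) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (file.size(path) == 0L) stop("empty file: ", path)
    df <- read.delim(path, header = header, comment.char = "#",
                     stringsAsFactors = FALSE, check.names = FALSE,
                     colClasses = colClasses)
    if (nrow(df) == 0L) stop("no records in ", path)
    df
}

#' Read a gene-level count table and its sample metadata
#'
#' The count TSV has a \code{gene_id} first column, an optional
#' \code{length} column (gene length in bp) and one column per sample; the
#' metadata TSV has columns \code{sample_id}, \code{fraction},
#' \code{condition}, \code{genotype} and optionally \code{sex},
#' \code{pair_id}. Sample order in the returned object follows the metadata
#' file. Counts must be non-negative whole numbers.
#'
#' @param path count TSV
#' @param metadataPath sample metadata TSV
#' @return a \linkS4class{TrapExperiment}
#' @export
readCountsTSV <- function(path, metadataPath) {
    df <- .readTsv(path)
    md <- .readTsv(metadataPath)
    if (!"gene_id" %in% names(df))
        stop("count table needs a gene_id column")
    if (!"sample_id" %in% names(md))
        stop("metadata needs a sample_id column")
    if (anyDuplicated(df$gene_id))
        stop("duplicate gene_id: ",
             paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
    gl <- NULL
    if ("length" %in% names(df)) {
        gl <- setNames(as.numeric(df$length), df$gene_id)
        df$length <- NULL
    }
    sampleCols <- setdiff(names(df), "gene_id")
    missingMd <- setdiff(sampleCols, md$sample_id)
    if (length(missingMd))
        stop("sample(s) missing from metadata: ",
             paste(missingMd, collapse = ", "))
    missingCnt <- setdiff(md$sample_id, sampleCols)
    if (length(missingCnt))
        stop("sample(s) missing from count table: ",
             paste(missingCnt, collapse = ", "))
    cnt <- as.matrix(df[, md$sample_id, drop = FALSE])
    if (!is.numeric(cnt)) stop("non-integer count (non-numeric cell)")
    .assertWholeNonNeg(cnt)
    rownames(cnt) <- df$gene_id
    cd <- md
    rownames(cd) <- md$sample_id
    TrapExperiment(cnt, cd, geneLengths = gl)
}

#' Write a TrapExperiment as count + metadata TSVs
#'
#' @param object a \linkS4class{TrapExperiment}
#' @param path,metadataPath output TSV paths
#' @export
writeCountsTSV <- function(object, path, metadataPath) {
    cnt <- assay(object, "counts")
    df <- data.frame(gene_id = rownames(cnt), check.names = FALSE)
    gl <- geneLengths(object)
    if (!is.null(gl)) df$length <- unname(gl)
    df <- cbind(df, as.data.frame(cnt, check.names = FALSE))
    .writeTsvWithHeader(df, path)
    md <- as.data.frame(colData(object))
    md <- cbind(sample_id = rownames(md), md)
    rownames(md) <- NULL
    md$sample_id <- as.character(md$sample_id)
    .writeTsvWithHeader(md, metadataPath)
    invisible(c(path, metadataPath))
}

.writeTsvWithHeader <- function(df, path, params = NULL) {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(.toolHeader(params), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write (and read back) a generic results table
#'
#' Writers emit tab-separated UTF-8 with commented header lines recording
#' the tool version and any parameters; \code{readResultsTable} skips them.
#'
#' @param table data.frame-like
#' @param path TSV path
#' @param params optional named list recorded in the header
#' @export
writeResultsTable <- function(table, path, params = NULL) {
    .writeTsvWithHeader(as.data.frame(table), path, params)
    invisible(path)
}

#' @rdname writeResultsTable
#' @export
readResultsTable <- function(path) .readTsv(path)

.SJ_STRAND <- c("0" = "*", "1" = "+", "2" = "-")

#' Read per-sample junction tables
#'
#' Supports two dialects: \code{"sj_tab"} (STAR SJ.out.tab: 1-based
#' inclusive intron coordinates, strand code 0/1/2, unique split-read
#' counts in column 7) and \code{"bed_like"} (BED6 with the count in the
#' score column, 0-based half-open). Coordinates are normalized once, at
#' this boundary, to the internal 1-based closed GRanges convention.
#' Junctions absent from a sample get count 0. Junctions with undefined
#' strand (SJ code 0) are dropped with a warning by default.
#'
#' @param paths character vector of per-sample files
#' @param dialect "sj_tab" or "bed_like"
#' @param sampleNames sample ids (default: names of \code{paths} or base
#'   file names)
#' @param undefinedStrand "drop" (default, with warning) or "error"
#' @return a \linkS4class{JunctionSet}
#' @export
readJunctions <- function(paths, dialect = c("sj_tab", "bed_like"),
                          sampleNames = NULL,
                          undefinedStrand = c("drop", "error")) {
    dialect <- match.arg(dialect)
    undefinedStrand <- match.arg(undefinedStrand)
    if (is.null(sampleNames))
        sampleNames <- if (!is.null(names(paths))) names(paths)
                       else sub("\\.[^.]*$", "", basename(paths))
    stopifnot(length(sampleNames) == length(paths))
    recs <- lapply(seq_along(paths), function(i) {
        df <- read.delim(paths[i], header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
        if (dialect == "sj_tab") {
            # STAR: chrom, start(1-based), end(1-based incl), strand 0/1/2,
            # motif, annotated, unique reads, multimapped, overhang
            strand <- .SJ_STRAND[as.character(df[[4]])]
            data.frame(chrom = df[[1]],
                       start = as.integer(df[[2]]),     # already 1-based
                       end = as.integer(df[[3]]),
                       strand = unname(strand),
                       count = as.numeric(df[[7]]),
                       stringsAsFactors = FALSE)
        } else {
            # BED6: 0-based half-open -> 1-based closed
            data.frame(chrom = df[[1]],
                       start = as.integer(df[[2]]) + 1L,
                       end = as.integer(df[[3]]),
                       strand = as.character(df[[6]]),
                       count = as.numeric(df[[5]]),
                       stringsAsFactors = FALSE)
        }
    })
    all <- do.call(rbind, Map(cbind, recs,
                              sample = as.list(sampleNames)))
    .assertWholeNonNeg(all$count, "junction count")
    undef <- all$strand %in% c("*", ".", "0")
    if (any(undef)) {
        if (undefinedStrand == "error")
            stop(sum(undef), " junction record(s) with undefined strand")
        warning(sum(undef), " junction record(s) with undefined strand dropped")
        all <- all[!undef, , drop = FALSE]
    }
    key <- paste(all$chrom, all$start, all$end, sep = ":")
    byInterval <- split(all$strand, key)
    bad <- names(byInterval)[vapply(byInterval, function(s)
        length(unique(s)) > 1L, logical(1))]
    if (length(bad))
        stop("inconsistent strand across samples for junction(s): ",
             paste(bad, collapse = ", "))
    ukey <- !duplicated(key)
    gr <- GRanges(all$chrom[ukey],
                  IRanges(all$start[ukey], all$end[ukey]),
                  strand = all$strand[ukey])
    names(gr) <- key[ukey]
    ord <- order(as.character(seqnames(gr)), start(gr), end(gr))
    gr <- gr[ord]
    cnt <- matrix(0, length(gr), length(sampleNames),
                  dimnames = list(names(gr), sampleNames))
    cnt[cbind(match(key, names(gr)), match(all$sample, sampleNames))] <-
        all$count
    JunctionSet(gr, cnt)
}

#' Write junctions as per-sample BED6 (count in score, 0-based half-open)
#'
#' @param jset a \linkS4class{JunctionSet}
#' @param paths output paths, one per sample
#' @export
writeJunctionsBED <- function(jset, paths) {
    stopifnot(length(paths) == ncol(jset))
    gr <- rowRanges(jset)
    cnt <- assay(jset, "counts")
    for (i in seq_along(paths)) {
        df <- data.frame(chrom = as.character(seqnames(gr)),
                         start = start(gr) - 1L,   # back to 0-based half-open
                         end = end(gr),
                         name = names(gr),
                         score = cnt[, i],
                         strand = as.character(strand(gr)))
        write.table(df, paths[i], sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
    }
    invisible(paths)
}

#' Read a (multi-line) FASTA into an uppercase DNAStringSet
#'
#' Sequence names are truncated at the first whitespace.
#'
#' @param path FASTA file
#' @return \linkS4class{DNAStringSet}
#' @export
readFasta <- function(path) {
    x <- readDNAStringSet(path)
    names(x) <- sub("\\s.*$", "", names(x))
    x
}

#' @rdname readFasta
#' @param seqs named DNAStringSet (or named character vector)
#' @export
writeFasta <- function(seqs, path) {
    if (!methods::is(seqs, "DNAStringSet"))
        seqs <- DNAStringSet(seqs)
    writeXStringSet(seqs, path, width = 70L)
    invisible(path)
}

#' Read a GMT gene-set file
#'
#' Each line: set name, description, then one or more gene ids, all
#' tab-separated. A set with zero genes is an error.
#'
#' @param path GMT file
#' @return named list of character vectors; descriptions in
#'   \code{attr(, "description")}
#' @export
readGMT <- function(path) {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("empty file: ", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- vapply(parts, length, integer(1)) < 3L
    if (any(bad))
        stop("GMT set with no genes: ",
             paste(vapply(parts[bad], `[`, character(1), 1), collapse = ", "))
    sets <- lapply(parts, function(p) p[-(1:2)])
    names(sets) <- vapply(parts, `[`, character(1), 1)
    attr(sets, "description") <- vapply(parts, `[`, character(1), 2)
    sets
}

#' @rdname readGMT
#' @param sets named list of gene-id vectors
#' @export
writeGMT <- function(sets, path) {
    desc <- attr(sets, "description")
    if (is.null(desc)) desc <- rep("na", length(sets))
    writeLines(vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t"),
        character(1)), path)
    invisible(path)
}

#' Read an RBP 6-mer motif configuration
#'
#' One RBP per line: a name, then comma-separated k-mers (\code{name:
#' KMER1,KMER2} or tab-separated). RNA alphabet (U) is accepted and mapped
#' to DNA (T) immediately; k-mers must then be length-\code{k} words over
#' ACGT, otherwise a hard error names the offending RBP.
#'
#' @param path config file
#' @param k expected k-mer length (default 6)
#' @return named list of character vectors of DNA k-mers
#' @export
readMotifConfig <- function(path, k = 6L) {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines)) stop("empty motif config: ", path)
    out <- list()
    for (ln in lines) {
        m <- regmatches(ln, regexec("^([^:\t]+)[:\t]\\s*(.+)$", ln))[[1]]
        if (length(m) != 3L) stop("malformed motif line: ", ln)
        name <- trimws(m[2])
        kmers <- toupper(trimws(strsplit(m[3], ",", fixed = TRUE)[[1]]))
        kmers <- chartr("U", "T", kmers)
        if (any(nchar(kmers) != k))
            stop("RBP '", name, "': k-mer of wrong length (expected ", k, ")")
        if (any(grepl("[^ACGT]", kmers)))
            stop("RBP '", name, "': k-mer outside the ACGT alphabet")
        out[[name]] <- unique(kmers)
    }
    out
}

#' @rdname readMotifConfig
#' @param motifSets named list of k-mer vectors
#' @export
writeMotifConfig <- function(motifSets, path) {
    writeLines(vapply(seq_along(motifSets), function(i)
        sprintf("%s: %s", names(motifSets)[i],
                paste(motifSets[[i]], collapse = ",")), character(1)), path)
    invisible(path)
}

#' Read/write cassette-exon events as a 9-column TSV
#'
#' Columns: \code{event_id, chrom, strand, u_start, u_end, c_start, c_end,
#' d_start, d_end} with 0-based half-open exon coordinates (BED
#' convention) on disk, converted once to the internal 1-based GRanges
#' representation.
#'
#' @param path TSV path
#' @return an \linkS4class{ExonEventSet}
#' @export
readExonEventsTSV <- function(path) {
    df <- .readTsv(path)
    need <- c("event_id", "chrom", "strand", "u_start", "u_end",
              "c_start", "c_end", "d_start", "d_end")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("event table missing column(s): ", paste(miss, collapse = ", "))
    mk <- function(s, e) {
        gr <- GRanges(df$chrom, IRanges(df[[s]] + 1L, df[[e]]),
                      strand = df$strand)
        names(gr) <- df$event_id
        gr
    }
    ExonEventSet(mk("u_start", "u_end"), mk("c_start", "c_end"),
                 mk("d_start", "d_end"))
}

#' @rdname readExonEventsTSV
#' @param events an \linkS4class{ExonEventSet}
#' @export
writeExonEventsTSV <- function(events, path) {
    u <- events@upstream; ca <- events@cassette; d <- events@downstream
    df <- data.frame(event_id = names(ca),
                     chrom = as.character(seqnames(ca)),
                     strand = as.character(strand(ca)),
                     u_start = start(u) - 1L, u_end = end(u),
                     c_start = start(ca) - 1L, c_end = end(ca),
                     d_start = start(d) - 1L, d_end = end(d))
    .writeTsvWithHeader(df, path)
    invisible(path)
}

#' Read cassette-exon events from BED12
#'
#' Each record must have exactly three blocks (upstream, cassette,
#' downstream exon in genomic order); the name column is the event id.
#'
#' @param path BED12 file
#' @return an \linkS4class{ExonEventSet}
#' @export
readExonEventsBED12 <- function(path) {
    df <- read.delim(path, header = FALSE, comment.char = "#",
                     stringsAsFactors = FALSE)
    if (ncol(df) < 12L) stop("BED12 requires 12 columns")
    nb <- as.integer(df[[10]])
    if (any(nb != 3L))
        stop("cassette-exon BED12 records must have exactly 3 blocks")
    chromStart <- as.integer(df[[2]])     # 0-based
    sizes <- lapply(strsplit(as.character(df[[11]]), ","), as.integer)
    starts <- lapply(strsplit(as.character(df[[12]]), ","), as.integer)
    mk <- function(b) {
        s <- chromStart + vapply(starts, `[`, integer(1), b)  # 0-based
        w <- vapply(sizes, `[`, integer(1), b)
        gr <- GRanges(df[[1]], IRanges(s + 1L, s + w), strand = df[[6]])
        names(gr) <- df[[4]]
        gr
    }
    ExonEventSet(mk(1L), mk(2L), mk(3L))
}
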
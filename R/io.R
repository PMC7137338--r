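## Plain-text format adapters.  All interval files are BED-style 0-based
## half-open on disk and GRanges (1-based, closed) in memory; bisulfite
## and gene tables use 1-based positions and say so in their headers.

.checkBedFrame <- function(df, path) {
    if (ncol(df) < 3L)
        stop("BED file ", path, " needs at least 3 columns")
    start0 <- suppressWarnings(as.numeric(df[[2]]))
    end0 <- suppressWarnings(as.numeric(df[[3]]))
    bad <- which(is.na(start0) | is.na(end0))
    if (length(bad))
        stop("malformed BED record at line ", bad[1], " of ", path)
    rev <- which(start0 >= end0)
    if (length(rev))
        stop("BED start >= end at line ", rev[1], " of ", path)
    list(chrom = as.character(df[[1]]), start0 = start0, end0 = end0)
}

#' Read genomic intervals from a BED file
#'
#' @param path BED file (0-based half-open); columns beyond the third are
#'   ignored except a 6th-column strand, which is kept.
#' @param seqlens optional named chromosome lengths for the seqinfo.
#' @return A \code{GRanges}.
#' @export
readBed <- function(path, seqlens = NULL) {
    df <- read.delim(path, header = FALSE, comment.char = "#",
                     stringsAsFactors = FALSE)
    f <- .checkBedFrame(df, path)
    strand <- if (ncol(df) >= 6L && all(df[[6]] %in% c("+", "-", ".")))
        df[[6]] else "*"
    strand[strand == "."] <- "*"
    gr <- GRanges(f$chrom, IRanges(f$start0 + 1L, f$end0), strand = strand)
    if (!is.null(seqlens)) {
        unknown <- setdiff(unique(f$chrom), names(seqlens))
        if (length(unknown))
            stop("chromosome(s) not in genome: ",
                 paste(unknown, collapse = ", "))
        gr <- .withSeqinfo(gr, Seqinfo(names(seqlens),
                                       seqlengths = unname(seqlens)))
    }
    gr
}

#' Write genomic intervals as BED
#'
#' @param gr a \code{GRanges}.
#' @param path output path; written 0-based half-open, 6 columns.
#' @param names optional record names (4th column).
#' @param scores optional scores (5th column).
#' @return Invisibly, \code{path}.
#' @export
writeBed <- function(gr, path, names = NULL, scores = NULL) {
    n <- length(gr)
    strand <- as.character(strand(gr))
    strand[strand == "*"] <- "."
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr),
                     name = if (is.null(names)) rep(".", n) else names,
                     score = if (is.null(scores)) rep(0, n) else scores,
                     strand = strand)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Write DMR regions as BED6+ and read them back
#'
#' Columns: chrom, start, end, name, score (-10 log10 combined p, capped
#' at 10000), strand "."; extra columns n_windows, logFC, simes_p, fdr,
#' direction, significant.
#'
#' @param regions region \code{GRanges} from \code{\link{callDmrs}}.
#' @param path file path.
#' @return Invisibly \code{path} (writer); region \code{GRanges} (reader).
#' @export
writeDmrBed <- function(regions, path) {
    m <- mcols(regions)
    score <- round(pmin(10000, -10 * log10(pmax(m$simes_p, 1e-300))), 2)
    df <- data.frame(chrom = as.character(seqnames(regions)),
                     start = start(regions) - 1L, end = end(regions),
                     name = sprintf("dmr_%05d", seq_along(regions)),
                     score = score, strand = ".",
                     n_windows = m$n_windows, logFC = m$logFC,
                     simes_p = m$simes_p, fdr = m$fdr,
                     direction = m$direction, significant = m$significant)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
    invisible(path)
}

#' @rdname writeDmrBed
#' @export
readDmrBed <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    f <- .checkBedFrame(df, path)
    gr <- GRanges(f$chrom, IRanges(f$start0 + 1L, f$end0))
    for (col in c("n_windows", "logFC", "simes_p", "fdr", "direction",
                  "significant"))
        mcols(gr)[[col]] <- df[[col]]
    gr
}

#' Write / read per-CpG bisulfite count tables
#'
#' TSV with header chrom, pos (1-based C position), methylated, total.
#'
#' @param counts bisulfite \code{GRanges} with mcols \code{methylated},
#'   \code{total}.
#' @param path file path.
#' @return Invisibly \code{path} (writer); \code{GRanges} (reader).
#' @export
writeBisulfiteTsv <- function(counts, path) {
    df <- data.frame(chrom = as.character(seqnames(counts)),
                     pos = start(counts),
                     methylated = mcols(counts)$methylated,
                     total = mcols(counts)$total)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeBisulfiteTsv
#' @export
readBisulfiteTsv <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "methylated", "total")
    if (!all(need %in% colnames(df)))
        stop("bisulfite table ", path, " must have columns ",
             paste(need, collapse = ", "))
    bad <- which(df$methylated > df$total | df$methylated < 0)
    if (length(bad))
        stop("methylated > total at record ", bad[1], " of ", path)
    gr <- GRanges(df$chrom, IRanges(df$pos, width = 1L))
    mcols(gr)$methylated <- df$methylated
    mcols(gr)$total <- df$total
    gr
}

#' Write / read the planted-DMR truth table
#'
#' TSV with chrom, start, end (0-based half-open), direction, delta and
#' affected groups; every planted DMR appears exactly once.
#'
#' @param planted \code{GRanges} from \code{\link{plantedDmrs}}.
#' @param path file path.
#' @return Invisibly \code{path} (writer); \code{GRanges} (reader).
#' @export
writeTruthTsv <- function(planted, path) {
    df <- data.frame(chrom = as.character(seqnames(planted)),
                     start = start(planted) - 1L, end = end(planted),
                     direction = mcols(planted)$direction,
                     delta = mcols(planted)$delta,
                     affected = mcols(planted)$affected)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeTruthTsv
#' @export
readTruthTsv <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
    mcols(gr)$direction <- df$direction
    mcols(gr)$delta <- df$delta
    mcols(gr)$affected <- df$affected
    gr
}

#' Write window-level test results
#'
#' @param results window \code{GRanges} from \code{\link{fitNbGlm}}.
#' @param path file path; TSV with chrom, start (0-based), end, logFC, p.
#' @return Invisibly, \code{path}.
#' @export
writeWindowTsv <- function(results, path) {
    df <- data.frame(chrom = as.character(seqnames(results)),
                     start = start(results) - 1L, end = end(results),
                     logFC = mcols(results)$logFC, p = mcols(results)$p)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a sample sheet
#'
#' @param path TSV with header columns \code{sample}, \code{group} and
#'   optionally \code{path} (per-sample fragment BED).
#' @return A \code{data.frame}.
#' @export
readSampleSheet <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("sample", "group") %in% colnames(df)))
        stop("sample sheet must have 'sample' and 'group' columns")
    df
}

#' Write / read gene models as a feature table
#'
#' TSV (0-based half-open intervals) with chrom, strand, tss, and the
#' 5'UTR / gene body / 3'UTR intervals of each gene.
#'
#' @param genes gene \code{GRanges} as stored in a
#'   \linkS4class{GenomeModel}.
#' @param path file path.
#' @param seqlens optional named chromosome lengths (reader).
#' @return Invisibly \code{path} (writer); gene \code{GRanges} (reader).
#' @export
writeGeneTable <- function(genes, path) {
    m <- mcols(genes)
    df <- data.frame(chrom = as.character(seqnames(genes)),
                     strand = as.character(strand(genes)),
                     tss = m$tss - 1L,
                     utr5_start = start(m$utr5) - 1L, utr5_end = end(m$utr5),
                     body_start = start(m$body) - 1L, body_end = end(m$body),
                     utr3_start = start(m$utr3) - 1L, utr3_end = end(m$utr3))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeGeneTable
#' @export
readGeneTable <- function(path, seqlens = NULL) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    u5 <- IRanges(df$utr5_start + 1L, df$utr5_end)
    u3 <- IRanges(df$utr3_start + 1L, df$utr3_end)
    gr <- GRanges(df$chrom,
                  IRanges(pmin(start(u5), start(u3)), pmax(end(u5), end(u3))),
                  strand = df$strand)
    mcols(gr)$tss <- df$tss + 1L
    mcols(gr)$utr5 <- u5
    mcols(gr)$body <- IRanges(df$body_start + 1L, df$body_end)
    mcols(gr)$utr3 <- u3
    if (!is.null(seqlens))
        gr <- .withSeqinfo(gr, Seqinfo(names(seqlens),
                                       seqlengths = unname(seqlens)))
    gr
}

#' Read a chromosome-sizes table
#'
#' @param path two-column TSV (chromosome name, length in bp), no header.
#' @return Named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L || any(is.na(suppressWarnings(as.integer(df[[2]])))))
        stop("chromosome-sizes file ", path,
             " must have name and integer length columns")
    setNames(as.integer(df[[2]]), as.character(df[[1]]))
}

#' Convert a BAM file to a fragment set
#'
#' Keeps mapped, primary, non-duplicate, non-supplementary records only
#' (matching a de-duplicated single-end alignment stream) and returns
#' their intervals.  Requires the Rsamtools package.
#'
#' @param path indexed BAM file.
#' @return Coordinate-sorted \code{GRanges} of fragment intervals.
#' @export
bamToFragments <- function(path) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
        stop("bamToFragments requires the Rsamtools package")
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isDuplicate = FALSE,
                                   isSupplementaryAlignment = FALSE)
    param <- Rsamtools::ScanBamParam(
        flag = flag, what = c("rname", "pos", "qwidth", "strand"))
    res <- Rsamtools::scanBam(path, param = param)[[1]]
    keep <- !is.na(res$pos)
    gr <- GRanges(res$rname[keep],
                  IRanges(res$pos[keep], width = res$qwidth[keep]),
                  strand = res$strand[keep])
    hdr <- Rsamtools::scanBamHeader(path)[[1]]$targets
    if (length(hdr))
        gr <- .withSeqinfo(gr, Seqinfo(names(hdr), seqlengths = unname(hdr)))
    sort(gr, ignore.strand = TRUE)
}

#' Write a genome's sequences as FASTA
#'
#' @param genome a \linkS4class{GenomeModel}.
#' @param path output FASTA path.
#' @return Invisibly, \code{path}.
#' @export
writeGenomeFasta <- function(genome, path) {
    writeXStringSet(genomeSequences(genome), path)
    invisible(path)
}
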
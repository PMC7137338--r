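## Sliding-window counting, abundance filtering and background-bin TMM
## normalization for capture fragment sets.

## tile one strand of the genome: 0-based starts 0, step, 2*step, ... with
## start + width <= chromosome length
.tileWindows <- function(seqlens, width, step) {
    grs <- lapply(names(seqlens), function(chrom) {
        L <- seqlens[[chrom]]
        if (L < width) return(GRanges())
        starts0 <- seq.int(0L, L - width, by = step)
        GRanges(chrom, IRanges(starts0 + 1L, width = width))
    })
    sinfo <- Seqinfo(names(seqlens), seqlengths = unname(seqlens))
    .withSeqinfo(do.call(c, grs), sinfo)
}

## extend single-end intervals to `ext` bp from their 5' end (strand-aware;
## unstranded intervals are treated as +), then trim to chromosome bounds
.extendFragments <- function(gr, ext) {
    if (is.null(ext) || ext <= 0L) return(gr)
    short <- width(gr) < ext
    if (any(short))
        suppressWarnings(gr[short] <- resize(gr[short], ext, fix = "start"))
    trim(gr)
}

#' Count fragments in sliding genomic windows
#'
#' Tiles every chromosome with windows of \code{width} bp every \code{step}
#' bp (200/10 by default, i.e. 190-bp overlap) and counts, per sample, the
#' fragments sharing at least 1 bp with each window.  Fragments shorter
#' than \code{fragmentExtension} are first extended to that length from
#' their 5' end, reconstructing the sequenced molecule from a single-end
#' read.
#'
#' @param fragments named \code{GRangesList} (or list of \code{GRanges}),
#'   one coordinate-sorted element per sample.
#' @param groups factor or character of group labels, one per sample.
#' @param seqlens named chromosome lengths; defaults to the seqlengths of
#'   the first fragment set.
#' @param width,step window width and spacing in bp.
#' @param fragmentExtension target fragment length in bp (0 disables
#'   extension).
#' @return A \linkS4class{WindowCounts} whose \code{lib.size} column holds
#'   the raw per-sample fragment totals and whose normalization factors are
#'   1 until \code{\link{estimateNormFactors}} is run.
#' @examples
#' fr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 300))
#' wc <- countWindows(list(s1 = fr, s2 = fr[0]), groups = c("a", "b"),
#'                    seqlens = c(chr1 = 1000L))
#' sum(SummarizedExperiment::assay(wc))
#' @export
countWindows <- function(fragments, groups, seqlens = NULL,
                         width = 200L, step = 10L,
                         fragmentExtension = 200L) {
    stopifnot(width > 0L, step > 0L, step <= width)
    fragments <- as(fragments, "GRangesList")
    if (is.null(names(fragments)))
        names(fragments) <- paste0("sample_", seq_along(fragments))
    if (length(groups) != length(fragments))
        stop("need one group label per sample")
    if (is.null(seqlens)) {
        seqlens <- seqlengths(fragments[[1]])
        if (any(is.na(seqlens)))
            stop("seqlens not given and fragment seqlengths incomplete")
    }
    windows <- .tileWindows(seqlens, as.integer(width), as.integer(step))
    counts <- matrix(0L, nrow = length(windows), ncol = length(fragments),
                     dimnames = list(NULL, names(fragments)))
    for (i in seq_along(fragments)) {
        fr <- fragments[[i]]
        unknown <- setdiff(unique(as.character(seqnames(fr))), names(seqlens))
        if (length(unknown))
            stop("fragments on unknown chromosome(s): ",
                 paste(unknown, collapse = ", "))
        o <- order(as.integer(seqnames(fr)), start(fr))
        if (any(o != seq_along(o)))
            stop("fragment set '", names(fragments)[i],
                 "' is not coordinate-sorted")
        fr <- .withSeqinfo(fr, seqinfo(windows))
        fr <- .extendFragments(fr, as.integer(fragmentExtension))
        counts[, i] <- countOverlaps(windows, fr, minoverlap = 1L)
    }
    cd <- DataFrame(sample = names(fragments),
                    group = as.character(groups),
                    lib.size = vapply(fragments, length, integer(1)),
                    norm.factors = rep(1, length(fragments)))
    se <- SummarizedExperiment(assays = list(counts = counts),
                               rowRanges = windows, colData = cd)
    meta <- list(width = as.integer(width), step = as.integer(step),
                 fragmentExtension = as.integer(fragmentExtension))
    metadata(se) <- meta
    new("WindowCounts", se)
}

## average log2 counts-per-million with 0.5/1 stabilizers
.avgLogCpm <- function(counts, effLib) {
    lcpm <- log2(t((t(counts) + 0.5) / (effLib + 1)) * 1e6)
    rowMeans(lcpm)
}

#' Filter windows on abundance and chromosome
#'
#' Keeps windows whose count sum across samples is at least
#' \code{minCountSum}, whose average log2 counts-per-million is at least
#' \code{minAvgLogCpm} (computed per sample as
#' \code{log2(((count + 0.5) / (effective library size + 1)) * 1e6)} and
#' averaged across samples; boundary values are kept), and that do not lie
#' on an excluded chromosome.  Chromosome matching tolerates a "chr"
#' prefix, so \code{"X"} excludes both \code{"X"} and \code{"chrX"}.
#'
#' @param x a \linkS4class{WindowCounts}.
#' @param minCountSum minimum across-sample count sum.
#' @param minAvgLogCpm minimum average logCPM.
#' @param excludedChroms chromosomes to drop (default sex chromosomes).
#' @return The filtered \linkS4class{WindowCounts}.
#' @export
filterWindows <- function(x, minCountSum = 30, minAvgLogCpm = -1,
                          excludedChroms = c("X", "Y")) {
    stopifnot(is(x, "WindowCounts"), ncol(x) >= 1L)
    counts <- assay(x, "counts")
    keep <- rowSums(counts) >= minCountSum
    keep <- keep & .avgLogCpm(counts, effectiveLibSizes(x)) >= minAvgLogCpm
    stripChr <- function(v) sub("^chr", "", v)
    excl <- stripChr(as.character(excludedChroms))
    keep <- keep & !(stripChr(as.character(seqnames(rowRanges(x)))) %in% excl)
    x[keep, ]
}

#' Estimate TMM normalization factors on background bins
#'
#' Composition-aware normalization for enrichment data: counts are
#' aggregated into bins (default 2 kb), the bins are restricted to the
#' low-abundance background (at or below the \code{maxAQuantile} abundance
#' quantile — in capture data the enriched signal lives in the
#' high-abundance bins), trimmed-mean-of-M-values factors are computed on
#' those background bins relative to the raw library sizes, and the
#' factors are rescaled to geometric mean 1.  Effective library size =
#' raw total x factor.  This counters capture competition: when one group
#' gains methylation, its enriched loci soak up a larger share of a fixed
#' sequencing budget and unchanged loci would otherwise appear depleted.
#' The abundance restriction matters because bins that partially overlap
#' differential regions form a continuum of intermediate M-values that
#' plain trimming cannot separate from the background.
#'
#' Bins are assembled from the disjoint subset of the stored window grid
#' (window starts divisible by the window width), so run this on the full,
#' unfiltered matrix.  A fragment spanning a bin boundary can count once on
#' each side; at 200-bp fragments vs multi-kb bins the effect is
#' negligible.
#'
#' @param x a \linkS4class{WindowCounts} (all windows, unfiltered).
#' @param binWidth background bin width in bp.
#' @param maxAQuantile abundance quantile (over nonzero bins) above which
#'   bins are excluded from factor estimation; 1 uses all nonzero bins.
#' @return \code{x} with its normalization factors set.
#' @export
estimateNormFactors <- function(x, binWidth = 2000L, maxAQuantile = 0.6) {
    stopifnot(is(x, "WindowCounts"), maxAQuantile > 0, maxAQuantile <= 1)
    if (ncol(x) < 2L)
        stop("need at least two samples to normalize")
    if (any(libSizes(x) == 0))
        stop("sample(s) with zero total counts: ",
             paste(colData(x)$sample[libSizes(x) == 0], collapse = ", "))
    w <- metadata(x)$width
    rr <- rowRanges(x)
    disjoint <- (start(rr) - 1L) %% w == 0L
    binId <- paste0(seqnames(rr)[disjoint], ":",
                    (start(rr)[disjoint] - 1L) %/% as.integer(binWidth))
    bins <- rowsum(assay(x, "counts")[disjoint, , drop = FALSE], binId)
    libs <- unname(libSizes(x))
    abundance <- rowMeans(t(t(bins) / libs))
    keep <- abundance > 0 &
        abundance <= quantile(abundance[abundance > 0], maxAQuantile)
    if (sum(keep) < 10L)  # degenerate tilings: fall back to all nonzero bins
        keep <- abundance > 0
    f <- edgeR::calcNormFactors(bins[keep, , drop = FALSE], lib.size = libs,
                                method = "TMM")
    normFactors(x) <- f
    x
}
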
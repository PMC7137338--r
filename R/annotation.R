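## Genomic-context layers (regulatory / gene body / 3'UTR; island / shore /
## shelf) and the O:E CpG-density statistic.

#' Build the genic annotation layers
#'
#' \code{regulatory} is the strand-aware 5-kb stretch upstream of each TSS
#' unioned with the 5'UTR; \code{gene_body} spans from the end of the 5'UTR
#' to the beginning of the 3'UTR (exons plus introns); \code{utr3} is taken
#' as given.  Intervals are clipped to chromosome bounds and overlapping
#' intervals within a layer are merged.  Everything outside the three
#' layers is "extragenic".
#'
#' @param genes gene models as returned by \code{\link{genes}}: a
#'   \code{GRanges} with mcols \code{tss}, \code{utr5}, \code{body},
#'   \code{utr3}.
#' @param upstream upstream promoter extent in bp.
#' @return An \linkS4class{AnnotationSet} with the genic layers filled in.
#' @export
buildIntragenicLayers <- function(genes, upstream = 5000L) {
    sinfo <- seqinfo(genes)
    if (!length(genes)) {
        return(new("AnnotationSet",
                   genic = GRangesList(regulatory = GRanges(),
                                       gene_body = GRanges(),
                                       utr3 = GRanges()),
                   cpg = GRangesList()))
    }
    chrom <- as.character(seqnames(genes))
    plus <- as.character(strand(genes)) == "+"
    tss <- mcols(genes)$tss
    up <- GRanges(chrom,
                  IRanges(ifelse(plus, tss - as.integer(upstream), tss),
                          ifelse(plus, tss - 1L, tss + as.integer(upstream) - 1L)))
    u5 <- GRanges(chrom, mcols(genes)$utr5)
    body <- GRanges(chrom, mcols(genes)$body)
    u3 <- GRanges(chrom, mcols(genes)$utr3)
    ## upstream extensions can exceed chromosome bounds by construction;
    ## trim() clipping them is the intended behavior, not a data problem
    fix <- function(gr) reduce(suppressWarnings(trim(.withSeqinfo(gr, sinfo))))
    new("AnnotationSet",
        genic = GRangesList(regulatory = fix(c(up, u5)),
                            gene_body = fix(body),
                            utr3 = fix(u3)),
        cpg = GRangesList())
}

#' Build the composite CpG layers (sSISs)
#'
#' A CpG island together with its flanking shores and shelves forms one
#' composite shelf-shore-island-shore-shelf (sSISs) region: shores are the
#' \code{shoreWidth}-bp flanks of the (merged) islands minus the islands
#' themselves, shelves the next \code{shelfWidth}-bp band outward minus
#' islands and shores.  Flanks of adjacent islands are resolved with
#' precedence island > shore > shelf, so the three layers are pairwise
#' disjoint.  Everything outside them is "extra-sSISs" (open sea).
#'
#' @param islandRanges \code{GRanges} of CpG islands (merged if
#'   overlapping).
#' @param shoreWidth,shelfWidth flank widths in bp.
#' @return An \linkS4class{AnnotationSet} with the CpG layers filled in.
#' @export
buildSsissLayers <- function(islandRanges, shoreWidth = 2000L,
                             shelfWidth = 2000L) {
    isl <- reduce(trim(islandRanges))
    if (!length(isl)) {
        return(new("AnnotationSet", genic = GRangesList(),
                   cpg = GRangesList(island = islandRanges[0],
                                     shore = islandRanges[0],
                                     shelf = islandRanges[0])))
    }
    shoreZone <- trim(isl + as.integer(shoreWidth))
    shelfZone <- trim(isl + as.integer(shoreWidth + shelfWidth))
    shores <- setdiff(shoreZone, isl, ignore.strand = TRUE)
    shelves <- setdiff(shelfZone, reduce(c(isl, shores)),
                       ignore.strand = TRUE)
    new("AnnotationSet", genic = GRangesList(),
        cpg = GRangesList(island = isl, shore = shores, shelf = shelves))
}

#' Combine genic and CpG layers into one annotation set
#'
#' @param genic,cpg \linkS4class{AnnotationSet}s carrying the respective
#'   layers (from \code{\link{buildIntragenicLayers}} and
#'   \code{\link{buildSsissLayers}}).
#' @return A merged \linkS4class{AnnotationSet}.
#' @export
combineAnnotation <- function(genic, cpg) {
    new("AnnotationSet", genic = genicLayers(genic), cpg = cpgLayers(cpg))
}

## overlap width of each region with one layer
.overlapWidth <- function(regions, layer) {
    if (!length(layer)) return(integer(length(regions)))
    hits <- findOverlaps(regions, layer)
    ow <- width(pintersect(regions[queryHits(hits)], layer[subjectHits(hits)]))
    out <- integer(length(regions))
    if (length(hits)) {
        agg <- tapply(ow, queryHits(hits), sum)
        out[as.integer(names(agg))] <- as.integer(agg)
    }
    out
}

#' Classify regions against the annotation layers
#'
#' A region is intragenic (resp. sSISs) if it overlaps any genic (resp.
#' CpG) layer by at least 1 bp; its subclass is the layer with the largest
#' overlap length, ties broken regulatory > gene_body > utr3 and island >
#' shore > shelf.  Regions overlapping nothing are extragenic /
#' extra-sSISs with subclass \code{"none"}.
#'
#' @param regions \code{GRanges} of regions to classify.
#' @param annotation an \linkS4class{AnnotationSet}.
#' @return A \code{data.frame} with columns \code{genic_class},
#'   \code{genic_subclass}, \code{cpg_class}, \code{cpg_subclass}, one row
#'   per region.
#' @export
classifyRegions <- function(regions, annotation) {
    classify <- function(layers, classes) {
        if (!length(layers))
            return(list(cls = rep(classes[2], length(regions)),
                        sub = rep("none", length(regions))))
        ow <- vapply(names(layers), function(nm)
            .overlapWidth(regions, layers[[nm]]),
            integer(length(regions)))
        ow <- matrix(ow, nrow = length(regions),
                     dimnames = list(NULL, names(layers)))
        hasOv <- rowSums(ow) > 0
        ## which.max over the layer order encodes the tie precedence
        subIdx <- apply(ow, 1, which.max)
        sub <- ifelse(hasOv, colnames(ow)[subIdx], "none")
        list(cls = ifelse(hasOv, classes[1], classes[2]), sub = sub)
    }
    g <- classify(genicLayers(annotation), c("intragenic", "extragenic"))
    cg <- classify(cpgLayers(annotation), c("sSISs", "extra_sSISs"))
    data.frame(genic_class = g$cls, genic_subclass = g$sub,
               cpg_class = cg$cls, cpg_subclass = cg$sub,
               stringsAsFactors = FALSE)
}

#' Observed-to-expected CpG ratio of a sequence
#'
#' The classical CpG-density statistic: observed = number of CG
#' dinucleotides; expected = (#C x #G) / length; ratio = observed /
#' expected, defined as 0 when the expected count is 0.  N bases count
#' toward the length but not toward the C/G tallies.
#'
#' @param sequence a \code{DNAString}, \code{DNAStringSet} or character
#'   vector of sequences over A/C/G/T/N.
#' @return Numeric vector of O:E CpG ratios.
#' @examples
#' oeCpGRatio(strrep("CG", 100))   # 2
#' oeCpGRatio(strrep("ACGT", 50))  # 4
#' @export
oeCpGRatio <- function(sequence) {
    if (is(sequence, "DNAString")) sequence <- DNAStringSet(sequence)
    if (is.character(sequence)) sequence <- DNAStringSet(sequence)
    if (!length(sequence) || any(width(sequence) == 0L))
        stop("empty sequence")
    obs <- vcountPattern("CG", sequence)
    cg <- letterFrequency(sequence, c("C", "G"))
    expd <- unname(cg[, "C"] * cg[, "G"]) / width(sequence)
    ifelse(expd == 0, 0, obs / expd)
}

## class from thresholds: low < lowCut <= intermediate < highCut <= high
.densityClass <- function(ratio, lowCut = 0.3, highCut = 0.6) {
    ifelse(ratio < lowCut, "low",
           ifelse(ratio < highCut, "intermediate", "high"))
}

#' Classify CpG-density context of every CpG site
#'
#' Each CpG (C position) is centered in a \code{window}-bp window (clipped
#' at chromosome ends), the O:E CpG ratio of the window sequence is
#' computed, and the site is classed low (< 0.3), intermediate ([0.3,
#' 0.6)) or high (>= 0.6).
#'
#' @param genome a \linkS4class{GenomeModel}.
#' @param window window size in bp (the CpG sits at its center).
#' @param lowCut,highCut class thresholds on the O:E ratio.
#' @return Width-1 CpG \code{GRanges} with mcols \code{oe_ratio} and
#'   \code{density_class}.
#' @export
classifyCpGDensity <- function(genome, window = 200L,
                               lowCut = 0.3, highCut = 0.6) {
    sites <- cpgPositions(genome)
    half <- as.integer(window) %/% 2L
    sl <- chromLengths(genome)
    ratio <- numeric(length(sites))
    for (chrom in names(sl)) {
        idx <- which(as.character(seqnames(sites)) == chrom)
        if (!length(idx)) next
        p0 <- start(sites)[idx] - 1L  # 0-based C position
        s <- pmax(0L, p0 - half) + 1L
        e <- pmin(sl[[chrom]], p0 + half)
        v <- Views(genome@sequences[[chrom]], start = s, end = e)
        ratio[idx] <- oeCpGRatio(as(v, "DNAStringSet"))
    }
    mcols(sites)$oe_ratio <- ratio
    mcols(sites)$density_class <- .densityClass(ratio, lowCut, highCut)
    sites
}
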
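## Central S4 containers.  All genomic intervals are GRanges (1-based,
## closed); BED readers/writers do the 0-based half-open conversion.

#' Simulation configuration
#'
#' Holds every tunable of the synthetic-data generator.  The generator
#' emulates a three-group capture study (normal mucosa, primary tumor,
#' metastasis): CpG-island-anchored promoters that are nearly unmethylated at
#' baseline, a largely methylated open sea, negative-binomially overdispersed
#' per-sample fragment totals, per-molecule MBD capture with affinity
#' \code{captureAffinity} per methylated CpG, and beta-binomial bisulfite
#' counts.
#'
#' @slot chromLengths named integer vector of chromosome lengths (bp).
#' @slot nGenes number of genes to place (each with one promoter CpG island).
#' @slot islandLength length of each promoter island (bp).
#' @slot samplesPerGroup named integer vector over
#'   \code{c("normal","primary","metastasis")}.
#' @slot librarySize expected number of candidate fragments per sample; the
#'   realized total is drawn from a negative binomial around this mean.
#' @slot fragLengthMean,fragLengthSd fragment length distribution (bp);
#'   lengths are truncated at 50 bp.
#' @slot captureAffinity per-methylated-CpG capture probability q in (0, 1];
#'   a molecule carrying k methylated CpGs is retained with probability
#'   1 - (1 - q)^k.
#' @slot nbDispersion negative-binomial dispersion used for fragment totals
#'   and bisulfite coverage.
#' @slot bisCoverage mean bisulfite read coverage per CpG.
#' @slot bbDispersion beta-binomial intra-class correlation for methylated
#'   counts; 0 gives plain binomial sampling.
#' @slot levelJitterSd between-sample methylation-level jitter (sd on the
#'   level scale).
#' @slot tumorDriftSd sd of the regional tumor methylation drift: a
#'   block-level (~1.5 kb) level shift shared by BOTH tumor groups,
#'   emulating the diffuse, regionally coherent methylome remodeling of
#'   neoplastic tissue; 0 disables it.
#' @slot islandLevelRange,openseaLevelRange baseline methylation level ranges
#'   for island and non-island CpGs.
#' @slot seed integer seed; all outputs are bit-identical given the seed, and
#'   per-sample substreams are derived so adding samples never perturbs
#'   earlier ones.
#' @export
setClass("SimulationConfig", representation(
    chromLengths = "integer",
    nGenes = "integer",
    islandLength = "integer",
    samplesPerGroup = "integer",
    librarySize = "numeric",
    fragLengthMean = "numeric",
    fragLengthSd = "numeric",
    captureAffinity = "numeric",
    nbDispersion = "numeric",
    bisCoverage = "numeric",
    bbDispersion = "numeric",
    levelJitterSd = "numeric",
    tumorDriftSd = "numeric",
    islandLevelRange = "numeric",
    openseaLevelRange = "numeric",
    seed = "integer"
))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (length(object@chromLengths) < 1L || is.null(names(object@chromLengths)))
        msg <- c(msg, "chromLengths must be a named vector with >= 1 chromosome")
    if (any(object@chromLengths < 1L))
        msg <- c(msg, "chromosome lengths must be positive")
    if (!all(c("normal", "primary", "metastasis") %in% names(object@samplesPerGroup)))
        msg <- c(msg, "samplesPerGroup must name normal, primary and metastasis")
    if (object@captureAffinity <= 0 || object@captureAffinity > 1)
        msg <- c(msg, "captureAffinity must lie in (0, 1]")
    if (object@nbDispersion <= 0)
        msg <- c(msg, "nbDispersion must be positive")
    if (object@bbDispersion < 0 || object@bbDispersion >= 1)
        msg <- c(msg, "bbDispersion must lie in [0, 1)")
    if (object@librarySize <= 0 || object@bisCoverage <= 0)
        msg <- c(msg, "librarySize and bisCoverage must be positive")
    if (object@levelJitterSd < 0 || object@tumorDriftSd < 0)
        msg <- c(msg, "levelJitterSd and tumorDriftSd must be nonnegative")
    for (nm in c("islandLevelRange", "openseaLevelRange")) {
        r <- slot(object, nm)
        if (length(r) != 2L || any(r < 0) || any(r > 1) || r[1] > r[2])
            msg <- c(msg, paste(nm, "must be an increasing pair in [0, 1]"))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' @param chromLengths named integer vector of chromosome lengths.
#' @param nGenes genes (and promoter islands) to place.
#' @param islandLength promoter island length in bp.
#' @param samplesPerGroup named integer vector over the three groups.
#' @param librarySize expected candidate fragments per sample.
#' @param fragLengthMean,fragLengthSd fragment length mean and sd.
#' @param captureAffinity per-methylated-CpG capture probability.
#' @param nbDispersion NB dispersion for fragment totals and coverage.
#' @param bisCoverage mean bisulfite coverage per CpG.
#' @param bbDispersion beta-binomial dispersion for bisulfite counts.
#' @param levelJitterSd between-sample methylation jitter sd.
#' @param tumorDriftSd regional tumor drift sd (shared by both tumor
#'   groups; 0 disables).
#' @param islandLevelRange,openseaLevelRange baseline level ranges.
#' @param seed integer seed.
#' @return A \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simConfig(seed = 1L)
#' cfg
#' @export
simConfig <- function(chromLengths = c(chr1 = 500000L),
                      nGenes = 30L,
                      islandLength = 1000L,
                      samplesPerGroup = c(normal = 3L, primary = 3L,
                                          metastasis = 3L),
                      librarySize = 600000,
                      fragLengthMean = 200,
                      fragLengthSd = 20,
                      captureAffinity = 0.1,
                      nbDispersion = 0.05,
                      bisCoverage = 30,
                      bbDispersion = 0.02,
                      levelJitterSd = 0.02,
                      tumorDriftSd = 0,
                      islandLevelRange = c(0.05, 0.10),
                      openseaLevelRange = c(0.75, 0.85),
                      seed = 1L) {
    new("SimulationConfig",
        chromLengths = setNames(as.integer(chromLengths), names(chromLengths)),
        nGenes = as.integer(nGenes),
        islandLength = as.integer(islandLength),
        samplesPerGroup = setNames(as.integer(samplesPerGroup),
                                   names(samplesPerGroup)),
        librarySize = librarySize,
        fragLengthMean = fragLengthMean,
        fragLengthSd = fragLengthSd,
        captureAffinity = captureAffinity,
        nbDispersion = nbDispersion,
        bisCoverage = bisCoverage,
        bbDispersion = bbDispersion,
        levelJitterSd = levelJitterSd,
        tumorDriftSd = tumorDriftSd,
        islandLevelRange = islandLevelRange,
        openseaLevelRange = openseaLevelRange,
        seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig\n")
    cat("  chromosomes:", length(object@chromLengths),
        sprintf("(%s bp total)", format(sum(object@chromLengths), big.mark = ",")), "\n")
    cat("  genes/islands:", object@nGenes, "\n")
    cat("  samples:", paste(sprintf("%s=%d", names(object@samplesPerGroup),
                                    object@samplesPerGroup), collapse = ", "), "\n")
    cat("  library size:", object@librarySize,
        " capture affinity q:", object@captureAffinity, "\n")
    cat("  seed:", object@seed, "\n")
})

#' Synthetic genome model
#'
#' A generated genome: chromosome sequences, CpG-island intervals and gene
#' models.  Each gene carries its TSS and 5'UTR / gene-body / 3'UTR
#' subintervals as metadata columns (IRanges), ordered along the strand.
#'
#' @slot sequences \code{DNAStringSet} of chromosome sequences.
#' @slot islands \code{GRanges} of CpG islands.
#' @slot genes \code{GRanges} spanning each gene, with mcols \code{tss}
#'   (integer, 1-based), \code{utr5}, \code{body}, \code{utr3} (IRanges).
#' @export
setClass("GenomeModel", representation(
    sequences = "DNAStringSet",
    islands = "GRanges",
    genes = "GRanges"
))

setValidity("GenomeModel", function(object) {
    msg <- character()
    sl <- setNames(width(object@sequences), names(object@sequences))
    for (nm in c("islands", "genes")) {
        gr <- slot(object, nm)
        if (length(gr)) {
            bad <- !(as.character(seqnames(gr)) %in% names(sl)) |
                start(gr) < 1L |
                end(gr) > sl[as.character(seqnames(gr))]
            if (any(bad))
                msg <- c(msg, paste(nm, "intervals outside chromosome bounds"))
        }
    }
    if (length(object@genes) &&
        !all(c("tss", "utr5", "body", "utr3") %in% colnames(mcols(object@genes))))
        msg <- c(msg, "genes must carry tss, utr5, body and utr3 mcols")
    if (length(msg)) msg else TRUE
})

setMethod("show", "GenomeModel", function(object) {
    cat("GenomeModel with", length(object@sequences), "chromosome(s),",
        format(sum(width(object@sequences)), big.mark = ","), "bp\n")
    cat(" ", length(object@islands), "CpG island(s),",
        length(object@genes), "gene(s)\n")
})

#' @describeIn GenomeModel-class chromosome sequences.
#' @param x,object a \code{GenomeModel}.
#' @export
setGeneric("genomeSequences", function(x) standardGeneric("genomeSequences"))
#' @export
setMethod("genomeSequences", "GenomeModel", function(x) x@sequences)

#' @describeIn GenomeModel-class CpG island intervals.
#' @export
setGeneric("islands", function(x) standardGeneric("islands"))
#' @export
setMethod("islands", "GenomeModel", function(x) x@islands)

#' @describeIn GenomeModel-class gene models.
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @export
setMethod("genes", "GenomeModel", function(x) x@genes)

#' @describeIn GenomeModel-class named chromosome lengths.
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))
#' @export
setMethod("chromLengths", "GenomeModel", function(x)
    setNames(width(x@sequences), names(x@sequences)))

#' Per-group methylation profile
#'
#' Methylation level in [0, 1] at every CpG site (position of the C of each
#' CG dinucleotide) for each of the three study groups.  Outside planted
#' DMRs all groups share the baseline level.
#'
#' @slot sites width-1 \code{GRanges} of CpG C positions.
#' @slot levels numeric matrix, sites x groups, values in [0, 1].
#' @export
setClass("MethylationProfile", representation(
    sites = "GRanges",
    levels = "matrix"
))

setValidity("MethylationProfile", function(object) {
    msg <- character()
    if (nrow(object@levels) != length(object@sites))
        msg <- c(msg, "levels must have one row per CpG site")
    if (is.null(colnames(object@levels)))
        msg <- c(msg, "levels must have group column names")
    if (length(object@levels) && (min(object@levels) < 0 || max(object@levels) > 1))
        msg <- c(msg, "levels must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "MethylationProfile", function(object) {
    cat("MethylationProfile:", length(object@sites), "CpG sites,",
        ncol(object@levels), "groups",
        paste0("(", paste(colnames(object@levels), collapse = ", "), ")\n"))
})

#' @describeIn MethylationProfile-class CpG site positions.
#' @param x a \code{MethylationProfile}.
#' @export
setGeneric("cpgSites", function(x) standardGeneric("cpgSites"))
#' @export
setMethod("cpgSites", "MethylationProfile", function(x) x@sites)

#' @describeIn MethylationProfile-class sites x groups level matrix.
#' @export
setGeneric("methLevels", function(x) standardGeneric("methLevels"))
#' @export
setMethod("methLevels", "MethylationProfile", function(x) x@levels)

#' Window count matrix
#'
#' Windows x samples fragment-overlap counts.  Extends
#' \code{RangedSummarizedExperiment}; \code{colData} carries \code{sample},
#' \code{group}, \code{lib.size} (raw fragment totals) and
#' \code{norm.factors} (TMM factors, geometric mean 1).
#'
#' @export
setClass("WindowCounts", contains = "RangedSummarizedExperiment")

setValidity("WindowCounts", function(object) {
    msg <- character()
    cd <- colData(object)
    need <- c("sample", "group", "lib.size", "norm.factors")
    if (!all(need %in% colnames(cd)))
        msg <- c(msg, paste("colData must contain",
                            paste(setdiff(need, colnames(cd)), collapse = ", ")))
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else if (any(assay(object, "counts") < 0))
        msg <- c(msg, "counts must be nonnegative")
    if ("norm.factors" %in% colnames(cd)) {
        f <- cd$norm.factors
        if (any(f <= 0))
            msg <- c(msg, "norm.factors must be strictly positive")
        else if (abs(mean(log(f))) > 1e-8)
            msg <- c(msg, "norm.factors must have geometric mean 1")
    }
    rr <- rowRanges(object)
    if (length(rr) > 1L && is.unsorted(order(as.integer(seqnames(rr)), start(rr))))
        msg <- c(msg, "windows must be sorted by (chrom, start)")
    if (length(msg)) msg else TRUE
})

setMethod("show", "WindowCounts", function(object) {
    callNextMethod()
    f <- colData(object)$norm.factors
    cat("norm.factors:",
        if (all(f == 1)) "unset (all 1)" else paste(round(f, 3), collapse = " "),
        "\n")
})

#' @describeIn WindowCounts-class raw per-sample fragment totals.
#' @param x a \code{WindowCounts}.
#' @export
setGeneric("libSizes", function(x) standardGeneric("libSizes"))
#' @export
setMethod("libSizes", "WindowCounts", function(x)
    setNames(colData(x)$lib.size, colData(x)$sample))

#' @describeIn WindowCounts-class TMM normalization factors.
#' @export
setGeneric("normFactors", function(x) standardGeneric("normFactors"))
#' @export
setMethod("normFactors", "WindowCounts", function(x)
    setNames(colData(x)$norm.factors, colData(x)$sample))

#' @describeIn WindowCounts-class set normalization factors (rescaled to
#'   geometric mean 1).
#' @param value numeric vector of positive factors, one per sample.
#' @export
setGeneric("normFactors<-", function(x, value) standardGeneric("normFactors<-"))
#' @export
setMethod("normFactors<-", "WindowCounts", function(x, value) {
    stopifnot(length(value) == ncol(x), all(value > 0))
    colData(x)$norm.factors <- value / exp(mean(log(value)))
    validObject(x)
    x
})

#' @describeIn WindowCounts-class effective library sizes
#'   (\code{lib.size * norm.factors}).
#' @export
setGeneric("effectiveLibSizes", function(x) standardGeneric("effectiveLibSizes"))
#' @export
setMethod("effectiveLibSizes", "WindowCounts", function(x)
    setNames(colData(x)$lib.size * colData(x)$norm.factors, colData(x)$sample))

#' @describeIn WindowCounts-class sample group factor.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))
#' @export
setMethod("sampleGroups", "WindowCounts", function(x)
    setNames(as.factor(colData(x)$group), colData(x)$sample))

#' Annotation layer set
#'
#' Labeled interval layers used to place regions in genomic context: the
#' genic layers (\code{regulatory}, \code{gene_body}, \code{utr3}) and the
#' CpG layers (\code{island}, \code{shore}, \code{shelf}).  CpG layers are
#' pairwise disjoint by construction (precedence island > shore > shelf).
#'
#' @slot genic \code{GRangesList} with elements regulatory, gene_body, utr3.
#' @slot cpg \code{GRangesList} with elements island, shore, shelf.
#' @export
setClass("AnnotationSet", representation(
    genic = "GRangesList",
    cpg = "GRangesList"
))

setValidity("AnnotationSet", function(object) {
    msg <- character()
    if (length(object@genic) &&
        !all(names(object@genic) %in% c("regulatory", "gene_body", "utr3")))
        msg <- c(msg, "genic layers must be regulatory, gene_body, utr3")
    if (length(object@cpg)) {
        if (!all(names(object@cpg) %in% c("island", "shore", "shelf")))
            msg <- c(msg, "cpg layers must be island, shore, shelf")
        nm <- names(object@cpg)
        for (i in seq_along(nm)) for (j in seq_along(nm)) {
            if (i < j && length(object@cpg[[i]]) && length(object@cpg[[j]]) &&
                any(overlapsAny(object@cpg[[i]], object@cpg[[j]])))
                msg <- c(msg, sprintf("cpg layers %s and %s overlap",
                                      nm[i], nm[j]))
        }
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "AnnotationSet", function(object) {
    cat("AnnotationSet\n")
    for (nm in names(object@genic))
        cat(sprintf("  genic/%s: %d interval(s)\n", nm,
                    length(object@genic[[nm]])))
    for (nm in names(object@cpg))
        cat(sprintf("  cpg/%s: %d interval(s)\n", nm, length(object@cpg[[nm]])))
})

#' @describeIn AnnotationSet-class genic layers as a GRangesList.
#' @param x an \code{AnnotationSet}.
#' @export
setGeneric("genicLayers", function(x) standardGeneric("genicLayers"))
#' @export
setMethod("genicLayers", "AnnotationSet", function(x) x@genic)

#' @describeIn AnnotationSet-class CpG layers as a GRangesList.
#' @export
setGeneric("cpgLayers", function(x) standardGeneric("cpgLayers"))
#' @export
setMethod("cpgLayers", "AnnotationSet", function(x) x@cpg)

## internal: clamp to [0, 1]
clamp01 <- function(x) pmin(1, pmax(0, x))

## internal: expand a GRanges' seqlevels to a full Seqinfo
.withSeqinfo <- function(gr, sinfo) {
    seqlevels(gr) <- seqlevels(sinfo)
    seqinfo(gr) <- sinfo
    gr
}

## internal: deterministic per-sample substream seed below 2^31.
## Small multiplicative hash over the stream label so that adding samples
## never changes earlier samples' draws.
sampleSeed <- function(seed, ...) {
    label <- paste(c(...), collapse = "/")
    h <- as.numeric(seed) %% 2147483647
    for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483647
    as.integer(h)
}
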
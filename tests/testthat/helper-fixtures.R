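## Shared fixtures, built in code.  The heavier simulated experiment is
## memoized so several test files can reuse it.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
    library(Biostrings)
})

.fixtureCache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
    if (!exists(key, envir = .fixtureCache))
        assign(key, expr, envir = .fixtureCache)
    get(key, envir = .fixtureCache)
}

## construct a WindowCounts directly from a count matrix
makeWC <- function(counts, groups, lib = NULL, width = 200L, step = NULL) {
    counts <- as.matrix(counts)
    if (is.null(step)) step <- width
    n <- nrow(counts)
    L <- as.integer(step * (n - 1) + width + 1000L)
    rr <- GRanges("chr1",
                  IRanges(seq(1L, by = as.integer(step), length.out = n),
                          width = width),
                  seqinfo = Seqinfo("chr1", L))
    if (is.null(lib)) lib <- pmax(colSums(counts), 1)
    cd <- DataFrame(sample = paste0("s", seq_len(ncol(counts))),
                    group = as.character(groups),
                    lib.size = lib,
                    norm.factors = rep(1, ncol(counts)))
    se <- SummarizedExperiment(assays = list(counts = counts),
                               rowRanges = rr, colData = cd)
    S4Vectors::metadata(se) <- list(width = as.integer(width),
                                    step = as.integer(step),
                                    fragmentExtension = 0L)
    new("WindowCounts", se)
}

## a methylation profile over arbitrary sites without a genome
makeProfile <- function(pos, levels, chrom = "chr1", chromLen = NULL) {
    if (is.null(chromLen)) chromLen <- max(pos) + 1000L
    sites <- GRanges(chrom, IRanges(pos, width = 1L),
                     seqinfo = Seqinfo(chrom, as.integer(chromLen)))
    if (is.null(dim(levels)))
        levels <- matrix(levels, nrow = length(pos), ncol = 3,
                         dimnames = list(NULL, c("normal", "primary",
                                                 "metastasis")))
    new("MethylationProfile", sites = sites, levels = levels)
}

## small but complete three-group experiment, shared across files
tinyConfig <- function(seed = 1L)
    simConfig(chromLengths = c(chr1 = 120000L), nGenes = 8L,
              librarySize = 30000,
              samplesPerGroup = c(normal = 2L, primary = 2L,
                                  metastasis = 2L),
              seed = seed)

tinyExperiment <- function() {
    memo("tinyExperiment", {
        cfg <- tinyConfig()
        gm <- simulateGenome(cfg)
        planted <- autoPlantDmrs(gm, nHyper = 3L, nHypo = 4L, seed = 1L)
        sim <- simulateExperiment(cfg, planted, bisulfite = TRUE,
                                  genome = gm)
        wc <- countWindows(sim$fragments, sim$sampleSheet$group,
                           seqlens = chromLengths(gm))
        wc <- estimateNormFactors(wc)
        list(cfg = cfg, genome = gm, planted = planted, sim = sim, wc = wc)
    })
}
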
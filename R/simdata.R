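## Synthetic-data generator: genomes with promoter CpG islands, group-wise
## methylation profiles with planted DMRs, MBD-capture fragment sets and
## bisulfite count tables.  Every operation derives its own RNG substream
## from the config seed, so outputs are bit-identical per seed and adding
## samples never perturbs earlier samples.

#' Describe DMRs to plant in a simulation
#'
#' @param regions \code{GRanges} of the intervals to perturb.
#' @param direction \code{"hyper"} or \code{"hypo"}, recycled.
#' @param delta methylation-level shift in [-1, 1]; must be positive for
#'   hyper and negative for hypo DMRs.  Shifted levels are clamped to [0, 1].
#' @param affected character vector (or list of vectors) naming the affected
#'   tumor groups, a subset of \code{c("primary", "metastasis")}.  The normal
#'   group is never shifted.
#' @return \code{GRanges} with mcols \code{direction}, \code{delta},
#'   \code{affected} (comma-joined).
#' @examples
#' plantedDmrs(GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 2000)),
#'             "hyper", 0.5, c("primary", "metastasis"))
#' @export
plantedDmrs <- function(regions, direction, delta,
                        affected = c("primary", "metastasis")) {
    n <- length(regions)
    direction <- rep_len(direction, n)
    delta <- rep_len(delta, n)
    if (!all(direction %in% c("hyper", "hypo")))
        stop("direction must be 'hyper' or 'hypo'")
    if (any(direction == "hyper" & delta <= 0) ||
        any(direction == "hypo" & delta >= 0))
        stop("hyper DMRs need delta > 0 and hypo DMRs delta < 0")
    if (any(abs(delta) > 1))
        stop("delta must lie in [-1, 1]")
    if (!is.list(affected)) affected <- rep(list(affected), n)
    affected <- rep_len(affected, n)
    ok <- vapply(affected, function(a)
        length(a) >= 1L && all(a %in% c("primary", "metastasis")), logical(1))
    if (!all(ok))
        stop("affected groups must be a nonempty subset of primary/metastasis")
    out <- granges(regions)
    mcols(out)$direction <- direction
    mcols(out)$delta <- delta
    mcols(out)$affected <- vapply(affected, paste, "", collapse = ",")
    out
}

## CpG-density mosaic for the background: alternating "sea" blocks with
## moderate CpG density and CpG-poor "desert" blocks, imposed by thinning
## CG dinucleotides of an i.i.d. draw (the G of a CG is kept with the
## block's keep probability, else mutated to A/T).  Deserts produce the
## capture-free territory that separates captured regions in real data.
.mosaicThinCg <- function(seq, shores = NULL, seaKeep = 0.45,
                          desertKeep = 0.01, shoreKeep = 0.30,
                          seaMean = 1200, desertMean = 3000) {
    L <- length(seq)
    n <- ceiling(L / ((seaMean + desertMean) / 4)) + 4L
    draw <- function() {
        sea <- pmax(400, round(rexp(n, 1 / seaMean)))
        des <- pmax(1000, round(rexp(n, 1 / desertMean)))
        as.vector(rbind(sea, des))
    }
    lens <- draw()
    while (sum(lens) < L) lens <- c(lens, draw())
    states <- rep(c(TRUE, FALSE), length.out = length(lens))
    isSea <- rep(states, lens)[seq_len(L)]
    keepProb <- ifelse(isSea, seaKeep, desertKeep)
    if (!is.null(shores) && length(shores)) {
        ## island flanks get intermediate density, as real shores do
        for (i in seq_along(shores)) {
            idx <- max(1L, start(shores)[i]):min(L, end(shores)[i])
            keepProb[idx] <- shoreKeep
        }
    }
    cgPos <- which(seq[-L] == "C" & seq[-1] == "G")
    if (length(cgPos)) {
        drop <- cgPos[runif(length(cgPos)) >= keepProb[cgPos]]
        seq[drop + 1L] <- sample(c("A", "T"), length(drop), replace = TRUE)
    }
    seq
}

## Markov sampler for CpG-rich island sequence: C is favoured everywhere and
## G strongly favoured after C, giving O:E CpG ratio ~1.5 and G+C ~0.6.
.islandSequence <- function(len) {
    bases <- c("A", "C", "G", "T")
    afterC <- cumsum(c(0.15, 0.25, 0.45, 0.15))
    other <- cumsum(c(0.20, 0.35, 0.25, 0.20))
    out <- character(len)
    prevC <- FALSE
    u <- runif(len)
    for (i in seq_len(len)) {
        p <- if (prevC) afterC else other
        b <- bases[findInterval(u[i], p) + 1L]
        out[i] <- b
        prevC <- b == "C"
    }
    out
}

#' Simulate a genome with promoter CpG islands
#'
#' Background sequence is drawn i.i.d. with G+C fraction ~0.4 and then
#' shaped into a CpG-density mosaic of moderate-density "sea" blocks and
#' CpG-poor "desert" blocks (mean block ~2 kb), so that capture coverage
#' is regionally structured as in real genomes; each gene's promoter
#' carries one CpG-dense island (O:E CpG ratio >= 0.6 and G+C >= 0.5 as
#' generated, verifiable with \code{\link{oeCpGRatio}}).  Genes are
#' laid out on alternating random strands in evenly spaced slots; on the +
#' strand the 5'UTR (200 bp), gene body (2 kb) and 3'UTR (300 bp) follow the
#' TSS in genomic order, mirrored on the - strand.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{GenomeModel}.
#' @examples
#' gm <- simulateGenome(simConfig(chromLengths = c(chr1 = 60000L),
#'                                nGenes = 5L, seed = 7L))
#' gm
#' @export
simulateGenome <- function(config) {
    validObject(config)
    sl <- config@chromLengths
    if (any(sl < 50000L))
        stop("every chromosome must be at least 50 kb long")
    nGenes <- config@nGenes
    ilen <- config@islandLength
    ## genes per chromosome, proportional to length
    ng <- floor(nGenes * sl / sum(sl))
    rem <- nGenes - sum(ng)
    if (rem > 0) {
        o <- order(sl, decreasing = TRUE)
        ng[o[seq_len(rem)]] <- ng[o[seq_len(rem)]] + 1L
    }
    geneSpan <- 2500L
    minSlot <- max(ilen, geneSpan) + 2L * max(ilen, geneSpan)
    set.seed(sampleSeed(config@seed, "genome"))
    seqs <- character(length(sl))
    geneList <- list()
    islandList <- list()
    for (ci in seq_along(sl)) {
        L <- sl[ci]
        chrom <- names(sl)[ci]
        tss <- integer(0)
        if (ng[ci] > 0) {
            slot <- L %/% ng[ci]
            if (slot < minSlot)
                stop(sprintf(
                    "chromosome %s (%d bp) too small to place %d gene(s)",
                    chrom, L, ng[ci]))
            jit <- floor(runif(ng[ci], -slot / 10, slot / 10))
            tss <- as.integer((seq_len(ng[ci]) - 1L) * slot + slot %/% 2 + jit)
            strand <- sample(c("+", "-"), ng[ci], replace = TRUE)
        }
        istart <- tss - ilen %/% 2L
        shores <- if (length(istart))
            IRanges(istart - 2000L, istart + ilen - 1L + 2000L) else NULL
        seq <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                      prob = c(0.3, 0.2, 0.2, 0.3))
        seq <- .mosaicThinCg(seq, shores = shores)
        if (ng[ci] > 0) {
            for (g in seq_len(ng[ci])) {
                isl <- .islandSequence(ilen)
                seq[istart[g]:(istart[g] + ilen - 1L)] <- isl
            }
            islandList[[chrom]] <- GRanges(chrom, IRanges(istart, width = ilen))
            plus <- strand == "+"
            u5 <- IRanges(ifelse(plus, tss, tss - 199L), width = 200L)
            body <- IRanges(ifelse(plus, tss + 200L, tss - 2199L), width = 2000L)
            u3 <- IRanges(ifelse(plus, tss + 2200L, tss - 2499L), width = 300L)
            gr <- GRanges(chrom,
                          IRanges(pmin(start(u5), start(u3)),
                                  pmax(end(u5), end(u3))),
                          strand = strand)
            mcols(gr)$tss <- tss
            mcols(gr)$utr5 <- u5
            mcols(gr)$body <- body
            mcols(gr)$utr3 <- u3
            geneList[[chrom]] <- gr
        }
        seqs[ci] <- paste(seq, collapse = "")
    }
    sinfo <- Seqinfo(names(sl), seqlengths = unname(sl))
    emptyGR <- GRanges(seqinfo = sinfo)
    islandsGR <- if (length(islandList))
        sort(.withSeqinfo(do.call(c, unname(islandList)), sinfo))
    else emptyGR
    genesGR <- if (length(geneList))
        sort(.withSeqinfo(do.call(c, unname(geneList)), sinfo),
             ignore.strand = TRUE)
    else emptyGR
    dna <- DNAStringSet(seqs)
    names(dna) <- names(sl)
    new("GenomeModel", sequences = dna, islands = islandsGR, genes = genesGR)
}

#' Locate CpG sites in a genome
#'
#' @param genome a \linkS4class{GenomeModel}.
#' @return Width-1 \code{GRanges} at the C of every CG dinucleotide.
#' @export
cpgPositions <- function(genome) {
    sl <- chromLengths(genome)
    sinfo <- Seqinfo(names(sl), seqlengths = unname(sl))
    hits <- lapply(names(sl), function(chrom) {
        m <- matchPattern("CG", genome@sequences[[chrom]])
        GRanges(chrom, IRanges(start(m), width = 1L))
    })
    sort(.withSeqinfo(do.call(c, hits), sinfo))
}

#' Simulate a per-group methylation profile with planted DMRs
#'
#' Baseline levels reflect the canonical somatic pattern: CpG-island CpGs are
#' nearly unmethylated and open-sea CpGs largely methylated (ranges set in
#' the config).  On top of the baseline, both tumor groups receive the same
#' regional methylation drift (block-level shifts of sd
#' \code{tumorDriftSd}), emulating the diffuse, regionally coherent
#' methylome remodeling of neoplastic tissue; because the drift is shared,
#' the metastasis-vs-primary comparison stays an exact null outside planted
#' metastasis-only DMRs.  Each planted DMR then shifts the affected tumor
#' groups' levels by its delta, clamped to [0, 1]; the normal group is
#' never shifted.  With \code{tumorDriftSd = 0} and no planted DMRs all
#' three groups are identical.
#'
#' @param genome a \linkS4class{GenomeModel}.
#' @param planted \code{GRanges} from \code{\link{plantedDmrs}} (may be
#'   empty).
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{MethylationProfile} with groups normal, primary,
#'   metastasis.
#' @export
simulateMethylationProfile <- function(genome, planted = GRanges(), config) {
    validObject(config)
    sl <- chromLengths(genome)
    if (length(planted)) {
        bad <- !(as.character(seqnames(planted)) %in% names(sl)) |
            start(planted) < 1L |
            end(planted) > sl[as.character(seqnames(planted))]
        if (any(bad))
            stop("planted DMR interval(s) outside genome bounds")
    }
    sites <- cpgPositions(genome)
    set.seed(sampleSeed(config@seed, "profile"))
    inIsland <- overlapsAny(sites, genome@islands)
    base <- numeric(length(sites))
    base[inIsland] <- runif(sum(inIsland), config@islandLevelRange[1],
                            config@islandLevelRange[2])
    base[!inIsland] <- runif(sum(!inIsland), config@openseaLevelRange[1],
                             config@openseaLevelRange[2])
    groups <- c("normal", "primary", "metastasis")
    lv <- matrix(base, nrow = length(sites), ncol = 3,
                 dimnames = list(NULL, groups))
    if (config@tumorDriftSd > 0 && length(sites)) {
        block <- paste0(seqnames(sites), ":", (start(sites) - 1L) %/% 1500L)
        ub <- unique(block)
        drift <- setNames(rnorm(length(ub), 0, config@tumorDriftSd), ub)
        for (g in c("primary", "metastasis"))
            lv[, g] <- clamp01(lv[, g] + drift[block])
    }
    if (length(planted)) {
        hits <- findOverlaps(sites, planted)
        for (g in c("primary", "metastasis")) {
            inG <- grepl(g, mcols(planted)$affected[subjectHits(hits)],
                         fixed = TRUE)
            idx <- queryHits(hits)[inG]
            lv[idx, g] <- clamp01(
                lv[idx, g] + mcols(planted)$delta[subjectHits(hits)][inG])
        }
    }
    new("MethylationProfile", sites = sites, levels = lv)
}

## per-sample methylation levels: group levels plus between-sample jitter
.sampleLevels <- function(profile, config, group) {
    lv <- methLevels(profile)[, group]
    if (config@levelJitterSd > 0)
        lv <- clamp01(lv + rnorm(length(lv), 0, config@levelJitterSd))
    lv
}

#' Simulate MBD-capture fragments for one sample
#'
#' Candidate fragments get a uniform random start and a Normal(mean, sd)
#' length truncated at 50 bp; the number of candidates is negative-binomial
#' around the configured library size.  Each CpG on a candidate molecule is
#' methylated with probability equal to its (sample-jittered) level, and the
#' molecule is captured with probability 1 - (1 - q)^k where k is its number
#' of methylated CpGs and q the per-CpG capture affinity.  Fully
#' unmethylated molecules are therefore never captured, which is what makes
#' capture coverage track methylated-CpG content.
#'
#' @param profile a \linkS4class{MethylationProfile}.
#' @param genome the \linkS4class{GenomeModel} the profile was built on.
#' @param config a \linkS4class{SimulationConfig}.
#' @param group one of \code{"normal"}, \code{"primary"},
#'   \code{"metastasis"}.
#' @param sampleIndex 1-based index of the sample within its group.
#' @return Coordinate-sorted \code{GRanges} of retained fragments.
#' @export
simulateMbdFragments <- function(profile, genome, config, group,
                                 sampleIndex = 1L) {
    validObject(config)
    group <- match.arg(group, colnames(methLevels(profile)))
    q <- config@captureAffinity
    sl <- chromLengths(genome)
    sinfo <- Seqinfo(names(sl), seqlengths = unname(sl))
    set.seed(sampleSeed(config@seed, "mbd", group, sampleIndex))
    nCand <- rnbinom(1L, mu = config@librarySize, size = 1 / config@nbDispersion)
    if (nCand == 0L)
        return(GRanges(seqinfo = sinfo))
    chrom <- sample(names(sl), nCand, replace = TRUE, prob = sl / sum(sl))
    len <- pmax(50L, as.integer(round(rnorm(nCand, config@fragLengthMean,
                                            config@fragLengthSd))))
    startPos <- as.integer(floor(runif(nCand) * (sl[chrom] - 1L))) + 1L
    endPos <- pmin(startPos + len - 1L, sl[chrom])
    frags <- GRanges(unname(chrom), IRanges(unname(startPos), unname(endPos)),
                     seqinfo = sinfo)
    lv <- .sampleLevels(profile, config, group)
    hits <- findOverlaps(frags, cpgSites(profile))
    meth <- rbinom(length(hits), 1L, lv[subjectHits(hits)])
    k <- integer(nCand)
    if (length(hits)) {
        tab <- tapply(meth, queryHits(hits), sum)
        k[as.integer(names(tab))] <- as.integer(tab)
    }
    keep <- runif(nCand) < 1 - (1 - q)^k
    sort(frags[keep])
}

#' Simulate targeted bisulfite counts for one sample
#'
#' Per CpG, total coverage is negative-binomial around the configured mean
#' and the methylated count beta-binomial around the (sample-jittered)
#' methylation level; zero beta-binomial dispersion gives plain binomial
#' sampling.
#'
#' @param profile a \linkS4class{MethylationProfile}.
#' @param config a \linkS4class{SimulationConfig}.
#' @param group,sampleIndex sample identity, as in
#'   \code{\link{simulateMbdFragments}}.
#' @param targets optional \code{GRanges} restricting the assayed CpGs
#'   (emulating probe-selected loci); default all CpGs.
#' @return Width-1 \code{GRanges} of assayed CpGs with mcols
#'   \code{methylated} and \code{total}.
#' @export
simulateBisulfiteCounts <- function(profile, config, group,
                                    sampleIndex = 1L, targets = NULL) {
    validObject(config)
    group <- match.arg(group, colnames(methLevels(profile)))
    sites <- cpgSites(profile)
    lvAll <- methLevels(profile)[, group]
    keep <- if (is.null(targets)) rep(TRUE, length(sites))
            else overlapsAny(sites, targets)
    sites <- sites[keep]
    set.seed(sampleSeed(config@seed, "bis", group, sampleIndex))
    n <- length(sites)
    total <- as.integer(rnbinom(n, mu = config@bisCoverage,
                                size = 1 / config@nbDispersion))
    lv <- lvAll[keep]
    if (config@levelJitterSd > 0)
        lv <- clamp01(lv + rnorm(n, 0, config@levelJitterSd))
    rho <- config@bbDispersion
    if (rho > 0) {
        r <- (1 - rho) / rho
        p <- numeric(n)
        mid <- lv > 0 & lv < 1
        p[mid] <- rbeta(sum(mid), lv[mid] * r, (1 - lv[mid]) * r)
        p[lv == 0] <- 0
        p[lv == 1] <- 1
    } else {
        p <- lv
    }
    meth <- as.integer(rbinom(n, total, p))
    out <- sites
    mcols(out)$methylated <- meth
    mcols(out)$total <- total
    out
}

#' Automatically place planted DMRs on a simulated genome
#'
#' Hyper DMRs are placed on randomly chosen promoter CpG islands extended
#' by \code{hyperFlank} bp on each side (tumor promoter hypermethylation
#' typically spreads from the island into its shores); hypo DMRs are
#' short intervals dropped uniformly into the open sea, i.e. at least
#' \code{shoreWidth + shelfWidth} bp away from any island, mutually
#' non-overlapping and required to contain between \code{minCpgs} and
#' \code{maxCpgs} CpGs (a DMR without CpGs would be unobservable on either
#' platform; the cap biases hypo DMRs toward the CpG-sparse territory
#' where tumor hypomethylation concentrates).
#'
#' @param genome a \linkS4class{GenomeModel}.
#' @param nHyper,nHypo number of DMRs of each kind.
#' @param hyperDelta,hypoDelta level shifts (defaults reflect large-
#'   magnitude island gains and low-magnitude open-sea losses).
#' @param hyperFlank extension of each hyper DMR beyond its island (bp).
#' @param hyperAffected,hypoAffected affected tumor groups.
#' @param hypoWidthRange hypo DMR length range in bp.
#' @param shoreWidth,shelfWidth exclusion flanks defining the open sea.
#' @param minCpgs,maxCpgs CpG-content bounds for a hypo DMR.
#' @param seed integer seed for the placement draws.
#' @return \code{GRanges} as from \code{\link{plantedDmrs}}.
#' @export
autoPlantDmrs <- function(genome, nHyper, nHypo = 0L,
                          hyperDelta = 0.5, hypoDelta = -0.2,
                          hyperFlank = 2000L,
                          hyperAffected = c("primary", "metastasis"),
                          hypoAffected = "metastasis",
                          hypoWidthRange = c(200L, 400L),
                          shoreWidth = 2000L, shelfWidth = 2000L,
                          minCpgs = 2L, maxCpgs = 6L, seed = 1L) {
    set.seed(sampleSeed(seed, "plant"))
    out <- GRanges()
    isl <- islands(genome)
    if (nHyper > 0L) {
        if (nHyper > length(isl))
            stop("not enough islands to place ", nHyper, " hyper DMRs")
        pick <- sort(sample(length(isl), nHyper))
        out <- c(out, plantedDmrs(trim(isl[pick] + hyperFlank), "hyper",
                                  hyperDelta, hyperAffected))
    }
    if (nHypo > 0L) {
        sl <- chromLengths(genome)
        sites <- cpgPositions(genome)
        excl <- reduce(trim(isl + (shoreWidth + shelfWidth)))
        placed <- GRanges()
        tries <- 0L
        while (length(placed) < nHypo && tries < 200L * nHypo) {
            tries <- tries + 1L
            chrom <- sample(names(sl), 1L, prob = sl / sum(sl))
            w <- sample(hypoWidthRange[1]:hypoWidthRange[2], 1L)
            s <- sample.int(sl[[chrom]] - w, 1L)
            cand <- GRanges(chrom, IRanges(s, width = w))
            nC <- countOverlaps(cand, sites)
            if (!overlapsAny(cand, excl) && !overlapsAny(cand, placed) &&
                nC >= minCpgs && nC <= maxCpgs)
                placed <- c(placed, cand)
        }
        if (length(placed) < nHypo)
            stop("could not place ", nHypo, " hypo DMRs in the open sea")
        out <- c(out, plantedDmrs(sort(placed), "hypo", hypoDelta,
                                  hypoAffected))
    }
    sort(out)
}

#' Simulate a complete three-group capture experiment
#'
#' Convenience wrapper running \code{\link{simulateGenome}},
#' \code{\link{simulateMethylationProfile}} and the per-sample fragment (and
#' optionally bisulfite) generators for every sample in the design.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param planted \code{GRanges} from \code{\link{plantedDmrs}}.
#' @param bisulfite logical; also generate bisulfite count tables?
#' @param bisulfiteTargets optional \code{GRanges} of probe-targeted loci
#'   passed to \code{\link{simulateBisulfiteCounts}}.
#' @param genome optionally, a pre-built \linkS4class{GenomeModel} to reuse.
#' @return A list with elements \code{genome}, \code{profile},
#'   \code{fragments} (named \code{GRangesList}), \code{sampleSheet}
#'   (data.frame with sample, group), \code{bisulfite} (named list of
#'   \code{GRanges}, or NULL) and \code{truth} (the planted DMRs).
#' @examples
#' cfg <- simConfig(chromLengths = c(chr1 = 60000L), nGenes = 4L,
#'                  librarySize = 2000, seed = 3L)
#' sim <- simulateExperiment(cfg)
#' names(sim$fragments)
#' @export
simulateExperiment <- function(config, planted = GRanges(),
                               bisulfite = FALSE, bisulfiteTargets = NULL,
                               genome = NULL) {
    validObject(config)
    if (is.null(genome)) genome <- simulateGenome(config)
    profile <- simulateMethylationProfile(genome, planted, config)
    spg <- config@samplesPerGroup
    sheet <- data.frame(
        sample = unlist(lapply(names(spg), function(g)
            if (spg[g] > 0) paste0(g, "_", seq_len(spg[g])) else character())),
        group = rep(names(spg), spg),
        stringsAsFactors = FALSE)
    frags <- GRangesList(lapply(seq_len(nrow(sheet)), function(i) {
        idx <- sum(sheet$group[seq_len(i)] == sheet$group[i])
        simulateMbdFragments(profile, genome, config, sheet$group[i], idx)
    }))
    names(frags) <- sheet$sample
    bis <- NULL
    if (bisulfite) {
        bis <- lapply(seq_len(nrow(sheet)), function(i) {
            idx <- sum(sheet$group[seq_len(i)] == sheet$group[i])
            simulateBisulfiteCounts(profile, config, sheet$group[i], idx,
                                    targets = bisulfiteTargets)
        })
        names(bis) <- sheet$sample
    }
    list(genome = genome, profile = profile, fragments = frags,
         sampleSheet = sheet, bisulfite = bis, truth = planted)
}
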
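## Built-in evaluation scenarios: fixed synthetic study designs that probe
## the properties the analysis is supposed to have (type-I control, DMR
## recovery, contrast structure, cross-platform asymmetry).  Genome sizes
## scale with the planted footprint so that the signal fraction stays near
## what capture studies see (~10-15%) and background normalization remains
## well-posed.

## derive a scenario sub-seed from a user seed (kept below 2^31)
.scenSeed <- function(seed, label) sampleSeed(seed, "scenario", label)

#' Null-calibration scenario
#'
#' Simulates a 3 vs 3 comparison with no planted effects on the default
#' genome, runs the full window pipeline for the primary-vs-normal
#' contrast, and measures the raw p-value calibration and the fraction of
#' regions flagged at the given FDR.
#'
#' @param seed integer seed.
#' @param fdrCutoff region-level FDR threshold.
#' @return A list with \code{nFilteredWindows}, \code{rawPFraction}
#'   (fraction of filtered windows with raw p < 0.05), \code{nRegions}
#'   and \code{flaggedFraction}.
#' @export
benchmarkNull <- function(seed = 1L, fdrCutoff = 0.05) {
    cfg <- simConfig(samplesPerGroup = c(normal = 3L, primary = 3L,
                                         metastasis = 0L),
                     seed = .scenSeed(seed, "null"))
    sim <- simulateExperiment(cfg)
    wc <- estimateNormFactors(countWindows(sim$fragments,
                                           sim$sampleSheet$group,
                                           seqlens = chromLengths(sim$genome)))
    res <- fitNbGlm(filterWindows(wc), c("primary", "normal"))
    regions <- callDmrs(wc, c("primary", "normal"), fdrCutoff = fdrCutoff)
    list(nFilteredWindows = length(res),
         rawPFraction = mean(mcols(res)$p < 0.05),
         nRegions = length(regions),
         flaggedFraction = mean(mcols(regions)$significant))
}

#' Planted-DMR recovery scenario
#'
#' Plants 50 island-anchored hyper DMRs (delta +0.5, both tumor groups) on
#' a 1.6-Mb genome, calls DMRs for primary vs normal at FDR 0.05 and
#' measures recovery (>= 1-bp overlap with the truth) and the direction
#' accuracy of the recovered regions (per planted DMR, the direction of
#' the best overlapping significant region).
#'
#' @param seed integer seed.
#' @return A list with \code{recall}, \code{directionAccuracy},
#'   \code{nPlanted}, \code{nSignificant}.
#' @export
benchmarkRecovery <- function(seed = 1L) {
    s <- .scenSeed(seed, "recovery")
    cfg <- simConfig(chromLengths = c(chr1 = 1600000L), nGenes = 60L,
                     librarySize = 1e6,
                     samplesPerGroup = c(normal = 3L, primary = 3L,
                                         metastasis = 0L),
                     seed = s)
    genome <- simulateGenome(cfg)
    planted <- autoPlantDmrs(genome, nHyper = 50L, nHypo = 0L,
                             hyperDelta = 0.5, seed = s)
    sim <- simulateExperiment(cfg, planted, genome = genome)
    wc <- estimateNormFactors(countWindows(sim$fragments,
                                           sim$sampleSheet$group,
                                           seqlens = chromLengths(genome)))
    regions <- callDmrs(wc, c("primary", "normal"))
    sig <- regions[mcols(regions)$significant]
    recovered <- overlapsAny(planted, sig)
    hits <- findOverlaps(planted, sig)
    best <- vapply(split(subjectHits(hits), queryHits(hits)),
                   function(i) i[which.min(mcols(sig)$fdr[i])], integer(1))
    list(recall = mean(recovered),
         directionAccuracy = mean(mcols(sig)$direction[best] == "hyper"),
         nPlanted = length(planted),
         nSignificant = length(sig))
}

#' Two-contrast structure scenario
#'
#' Emulates the study's contrast structure on a 1.2-Mb genome with the
#' study's design (3 normal, 6 primary, 12 metastases): 30 sSISs-wide
#' hyper DMRs (+0.5) shared by both tumor groups and 60 short open-sea
#' hypo DMRs (-0.2) confined to the metastases.  Both tumor-vs-normal
#' contrasts are called and compared; a second simulation with identical
#' planted effects in both tumor groups provides the
#' metastasis-vs-primary null.
#'
#' @param seed integer seed.
#' @return A list with \code{hyperMutualOverlap} (the smaller of the two
#'   directed >= 1-bp overlap fractions between the contrasts' hyper
#'   DMRs), \code{hypoMetOnlyFraction} (fraction of all detected hypo
#'   DMRs found only in the metastasis contrast; 1 when nothing is
#'   detected), \code{nHypoMet}, \code{nHypoPrimary}, and
#'   \code{metVsPrimaryFlaggedFraction} from the identical-effects
#'   variant.
#' @export
benchmarkContrasts <- function(seed = 1L) {
    s <- .scenSeed(seed, "contrasts")
    cfg <- simConfig(chromLengths = c(chr1 = 1200000L), nGenes = 45L,
                     librarySize = 1.2e6,
                     samplesPerGroup = c(normal = 3L, primary = 6L,
                                         metastasis = 12L),
                     seed = s)
    genome <- simulateGenome(cfg)
    planted <- autoPlantDmrs(genome, nHyper = 30L, nHypo = 60L,
                             hyperDelta = 0.5, hypoDelta = -0.2,
                             hypoAffected = "metastasis", maxCpgs = 4L,
                             seed = s)
    sim <- simulateExperiment(cfg, planted, genome = genome)
    wc <- estimateNormFactors(countWindows(sim$fragments,
                                           sim$sampleSheet$group,
                                           seqlens = chromLengths(genome)))
    dmP <- callDmrs(wc, c("primary", "normal"))
    dmM <- callDmrs(wc, c("metastasis", "normal"))
    sigP <- dmP[mcols(dmP)$significant]
    sigM <- dmM[mcols(dmM)$significant]
    hP <- sigP[mcols(sigP)$direction == "hyper"]
    hM <- sigM[mcols(sigM)$direction == "hyper"]
    lP <- sigP[mcols(sigP)$direction == "hypo"]
    lM <- sigM[mcols(sigM)$direction == "hypo"]
    mutual <- min(if (length(hP)) mean(overlapsAny(hP, hM)) else 0,
                  if (length(hM)) mean(overlapsAny(hM, hP)) else 0)
    metOnly <- sum(!overlapsAny(lM, lP))
    denom <- metOnly + length(lP)
    metOnlyFrac <- if (denom == 0) 1 else metOnly / denom

    ## identical-effects variant: metastasis vs primary is an exact null
    planted6 <- autoPlantDmrs(genome, nHyper = 30L, nHypo = 60L,
                              hyperDelta = 0.5, hypoDelta = -0.2,
                              hypoAffected = c("primary", "metastasis"),
                              maxCpgs = 4L, seed = s)
    sim6 <- simulateExperiment(cfg, planted6, genome = genome)
    wc6 <- estimateNormFactors(countWindows(sim6$fragments,
                                            sim6$sampleSheet$group,
                                            seqlens = chromLengths(genome)))
    dm6 <- callDmrs(wc6, c("metastasis", "primary"))
    list(hyperMutualOverlap = mutual,
         hypoMetOnlyFraction = metOnlyFrac,
         nHypoMet = length(lM),
         nHypoPrimary = length(lP),
         nHyperPrimary = length(hP),
         nHyperMet = length(hM),
         metVsPrimaryFlaggedFraction = mean(mcols(dm6)$significant),
         truth = planted, regions = list(primary = dmP, metastasis = dmM))
}

#' Cross-platform asymmetry scenario
#'
#' Pushes one latent methylome (30 sSISs-wide hyper DMRs, 60 short
#' low-magnitude open-sea hypo DMRs, primary-affected) through both
#' generators: MBD-capture fragments for a 3 vs 3 cohort and targeted
#' bisulfite counts for a separate 5 vs 5 cohort.  Runs the capture
#' pipeline and the per-CpG beta regression, propagates region statistics
#' to CpGs, classifies joint calls and computes the density-stratified
#' Pearson correlation between platforms.
#'
#' @param seed integer seed.
#' @return A list with \code{teHypoCallRate} (sign rule),
#'   \code{teHypoSignifRate} (sign and p < 0.05),
#'   \code{mbdeHypoFlagRate} (planted hypo intervals overlapped by a
#'   significant hypo region), \code{correlation} (the stratified
#'   summary), \code{minStratumR}, \code{overallR} and
#'   \code{jointCounts}.
#' @export
benchmarkPlatforms <- function(seed = 1L) {
    s <- .scenSeed(seed, "platforms")
    cfg <- simConfig(chromLengths = c(chr1 = 600000L), nGenes = 40L,
                     samplesPerGroup = c(normal = 3L, primary = 3L,
                                         metastasis = 0L),
                     seed = s)
    genome <- simulateGenome(cfg)
    planted <- autoPlantDmrs(genome, nHyper = 30L, nHypo = 60L,
                             hyperDelta = 0.5, hypoDelta = -0.2,
                             hypoAffected = "primary", maxCpgs = 4L,
                             seed = s)
    profile <- simulateMethylationProfile(genome, planted, cfg)
    sim <- simulateExperiment(cfg, planted, genome = genome)

    ## TE cohort: same latent profile, independent 5 vs 5 samples
    bis <- list()
    groups <- character()
    for (g in c("normal", "primary")) for (i in 1:5) {
        bis[[paste0("te_", g, "_", i)]] <-
            simulateBisulfiteCounts(profile, cfg, g, i + 100L)
        groups <- c(groups, g)
    }
    te <- betaRegressionPerCpG(bis, groups, c("primary", "normal"))

    wc <- estimateNormFactors(countWindows(sim$fragments,
                                           sim$sampleSheet$group,
                                           seqlens = chromLengths(genome)))
    regions <- callDmrs(wc, c("primary", "normal"))
    sig <- regions[mcols(regions)$significant]
    hypo <- planted[mcols(planted)$direction == "hypo"]
    sigL <- sig[mcols(sig)$direction == "hypo"]

    prop <- propagateRegionStats(regions, granges(te))
    both <- mcols(prop)$mbde_covered
    dens <- classifyCpGDensity(genome)
    dcls <- mcols(dens)$density_class[match(
        paste(seqnames(te), start(te)),
        paste(seqnames(dens), start(dens)))]
    calls <- classifyCpGCalls(mcols(te)$diff[both], mcols(te)$p[both],
                              mcols(prop)$mbde_logFC[both],
                              mcols(prop)$mbde_p[both])
    cc <- correlateMethods(mcols(prop)$mbde_logFC[both],
                           mcols(te)$diff[both], dcls[both],
                           calls$joint_class)
    inHypo <- overlapsAny(te, hypo)
    strata <- cc[cc$stratum != "overall" & !cc$undefined, ]
    list(teHypoCallRate = mean(mcols(te)$diff[inHypo] < 0),
         teHypoSignifRate = mean(mcols(te)$diff[inHypo] < 0 &
                                 mcols(te)$p[inHypo] < 0.05),
         mbdeHypoFlagRate = mean(overlapsAny(hypo, sigL)),
         correlation = cc,
         minStratumR = min(strata$r),
         overallR = cc$r[cc$stratum == "overall"],
         jointCounts = table(calls$joint_class),
         nBothCovered = sum(both))
}
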
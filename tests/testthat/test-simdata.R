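test_that("genome simulation is seed-deterministic and validates input", {
    cfg <- simConfig(chromLengths = c(chr1 = 60000L), nGenes = 4L,
                     seed = 9L)
    gm1 <- simulateGenome(cfg)
    gm2 <- simulateGenome(cfg)
    expect_identical(as.character(genomeSequences(gm1)),
                     as.character(genomeSequences(gm2)))
    expect_identical(islands(gm1), islands(gm2))

    ## empty case: zero genes
    gm0 <- simulateGenome(simConfig(chromLengths = c(chr1 = 60000L),
                                    nGenes = 0L, seed = 9L))
    expect_length(islands(gm0), 0)
    expect_length(genes(gm0), 0)

    ## too-small chromosome and over-packed genes are rejected
    expect_error(simulateGenome(simConfig(chromLengths = c(chr1 = 20000L),
                                          nGenes = 1L)),
                 "50 kb")
    expect_error(simulateGenome(simConfig(chromLengths = c(chr1 = 60000L),
                                          nGenes = 30L)),
                 "too small")
})

test_that("generated islands are CpG-dense by recomputation", {
    gm <- tinyExperiment()$genome
    seqs <- genomeSequences(gm)
    islSeq <- DNAStringSet(Views(seqs[[1]], ranges(islands(gm))))
    oe <- oeCpGRatio(islSeq)
    gc <- letterFrequency(islSeq, "GC", as.prob = TRUE)[, 1]
    expect_true(all(oe >= 0.6))
    expect_true(all(gc >= 0.5))
    ## gene substructure is ordered along the strand and contiguous
    g <- genes(gm)
    m <- mcols(g)
    plus <- as.character(strand(g)) == "+"
    expect_true(all(end(m$utr5[plus]) + 1L == start(m$body[plus])))
    expect_true(all(end(m$body[plus]) + 1L == start(m$utr3[plus])))
    expect_true(all(end(m$utr3[!plus]) + 1L == start(m$body[!plus])))
    expect_true(all(end(m$body[!plus]) + 1L == start(m$utr5[!plus])))
})

test_that("methylation profiles follow baselines and planted shifts", {
    cfg <- simConfig(chromLengths = c(chr1 = 60000L), nGenes = 4L,
                     seed = 3L)
    gm <- simulateGenome(cfg)

    ## no planted effects: all groups identical (drift is off by default)
    p0 <- simulateMethylationProfile(gm, GRanges(), cfg)
    expect_identical(methLevels(p0)[, "normal"], methLevels(p0)[, "primary"])
    expect_identical(methLevels(p0)[, "normal"],
                     methLevels(p0)[, "metastasis"])
    inIsl <- overlapsAny(cpgSites(p0), islands(gm))
    expect_true(all(methLevels(p0)[inIsl, "normal"] <= 0.10))
    expect_true(all(methLevels(p0)[!inIsl, "normal"] >= 0.75))

    ## hyper DMR on an island raises both tumor groups by ~delta
    isl <- islands(gm)[1]
    planted <- plantedDmrs(isl, "hyper", 0.6, c("primary", "metastasis"))
    p1 <- simulateMethylationProfile(gm, planted, cfg)
    hit <- overlapsAny(cpgSites(p1), isl)
    for (g in c("primary", "metastasis")) {
        gap <- mean(methLevels(p1)[hit, g]) -
            mean(methLevels(p1)[hit, "normal"])
        expect_equal(gap, 0.6, tolerance = 0.02)
    }

    ## metastasis-only hypo leaves primary untouched
    sea <- GRanges("chr1", IRanges(start(isl) - 6000L, width = 300L))
    p2 <- simulateMethylationProfile(
        gm, plantedDmrs(sea, "hypo", -0.2, "metastasis"), cfg)
    expect_identical(methLevels(p2)[, "primary"], methLevels(p2)[, "normal"])
    hit2 <- overlapsAny(cpgSites(p2), sea)
    expect_true(all(methLevels(p2)[hit2, "metastasis"] <
                    methLevels(p2)[hit2, "normal"]))

    ## out-of-bounds planting is rejected
    expect_error(simulateMethylationProfile(
        gm, plantedDmrs(GRanges("chr1", IRanges(59000, 70000)),
                        "hyper", 0.5), cfg),
        "outside")
})

test_that("plantedDmrs enforces direction/delta/affected consistency", {
    gr <- GRanges("chr1", IRanges(1000, 2000))
    expect_error(plantedDmrs(gr, "hyper", -0.5), "delta")
    expect_error(plantedDmrs(gr, "hypo", 0.5), "delta")
    expect_error(plantedDmrs(gr, "hyper", 0.5, "normal"), "affected")
    out <- plantedDmrs(gr, "hypo", -0.2, "metastasis")
    expect_identical(mcols(out)$affected, "metastasis")
})

test_that("MBD capture retains only molecules with methylated CpGs", {
    cfg <- simConfig(chromLengths = c(chr1 = 60000L), nGenes = 2L,
                     librarySize = 5000, levelJitterSd = 0, seed = 4L)
    gm <- simulateGenome(cfg)
    sites <- cpgPositions(gm)

    ## all-zero methylation, q < 1: retention probability is exactly 0
    p0 <- makeProfile(start(sites), 0, chromLen = 60000L)
    fr0 <- simulateMbdFragments(p0, gm, cfg, "normal", 1L)
    expect_length(fr0, 0)

    ## q = 1, fully methylated: every retained fragment covers a CpG and
    ## every fragment covering a CpG is retained, so coverage is dense
    cfg1 <- simConfig(chromLengths = c(chr1 = 60000L), nGenes = 2L,
                      librarySize = 5000, captureAffinity = 1,
                      levelJitterSd = 0, seed = 4L)
    p1 <- makeProfile(start(sites), 1, chromLen = 60000L)
    fr1 <- simulateMbdFragments(p1, gm, cfg1, "normal", 1L)
    expect_true(all(countOverlaps(fr1, sites) >= 1))
    expect_gt(length(fr1), 0)

    ## invalid affinity is rejected at construction
    expect_error(simConfig(captureAffinity = 0), "captureAffinity")
    expect_error(simConfig(captureAffinity = 1.5), "captureAffinity")

    ## determinism and sorted output
    fr1b <- simulateMbdFragments(p1, gm, cfg1, "normal", 1L)
    expect_identical(fr1, fr1b)
    expect_false(is.unsorted(start(fr1)))
})

test_that("coverage of a methylated island exceeds an unmethylated one", {
    cfg <- simConfig(chromLengths = c(chr1 = 60000L), nGenes = 2L,
                     librarySize = 50000, levelJitterSd = 0, seed = 8L)
    gm <- simulateGenome(cfg)
    isl <- islands(gm)
    expect_length(isl, 2)
    sites <- cpgPositions(gm)
    lv <- numeric(length(sites))
    lv[overlapsAny(sites, isl[1])] <- 1    # methylated island
    prof <- makeProfile(start(sites), cbind(normal = lv, primary = lv,
                                            metastasis = lv),
                        chromLen = 60000L)
    fr <- simulateMbdFragments(prof, gm, cfg, "normal", 1L)
    nMeth <- sum(overlapsAny(fr, isl[1]))
    nUnmeth <- sum(overlapsAny(fr, isl[2]))
    expect_lt(binom.test(c(nMeth, nUnmeth))$p.value, 0.01)
    expect_gt(nMeth, nUnmeth)
})

test_that("capture coverage is monotone in methylation level", {
    cfg <- simConfig(chromLengths = c(chr1 = 60000L), nGenes = 2L,
                     librarySize = 4000, levelJitterSd = 0, seed = 2L)
    gm <- simulateGenome(cfg)
    sites <- cpgPositions(gm)
    region <- GRanges("chr1", IRanges(10000, 20000))
    cov <- vapply(c(0.2, 0.5, 0.8), function(level) {
        prof <- makeProfile(start(sites), level, chromLen = 60000L)
        mean(vapply(1:20, function(i)
            sum(overlapsAny(simulateMbdFragments(prof, gm, cfg, "normal", i),
                            region)), numeric(1)))
    }, numeric(1))
    expect_true(all(diff(cov) >= 0))
})

test_that("bisulfite counts honor levels, dispersion and coverage", {
    pos <- seq(100L, by = 50L, length.out = 10000L)
    cfg <- simConfig(bbDispersion = 0, levelJitterSd = 0, bisCoverage = 30,
                     seed = 6L)

    b0 <- simulateBisulfiteCounts(makeProfile(pos, 0), cfg, "normal", 1L)
    expect_true(all(mcols(b0)$methylated == 0))

    b1 <- simulateBisulfiteCounts(makeProfile(pos, 1), cfg, "normal", 1L)
    expect_identical(mcols(b1)$methylated, mcols(b1)$total)

    bh <- simulateBisulfiteCounts(makeProfile(pos, 0.5), cfg, "normal", 1L)
    pooled <- sum(mcols(bh)$methylated) / sum(mcols(bh)$total)
    expect_gte(pooled, 0.49)
    expect_lte(pooled, 0.51)
    expect_true(all(mcols(bh)$methylated <= mcols(bh)$total))

    ## beta-binomial dispersion widens the per-site distribution
    cfgD <- simConfig(bbDispersion = 0.3, levelJitterSd = 0,
                      bisCoverage = 30, seed = 6L)
    bd <- simulateBisulfiteCounts(makeProfile(pos, 0.5), cfgD, "normal", 1L)
    fr <- mcols(bd)$methylated / pmax(mcols(bd)$total, 1)
    fr0 <- mcols(bh)$methylated / pmax(mcols(bh)$total, 1)
    expect_gt(var(fr, na.rm = TRUE), var(fr0, na.rm = TRUE))
})

test_that("per-sample substreams are stable when the design grows", {
    cfg2 <- simConfig(chromLengths = c(chr1 = 60000L), nGenes = 3L,
                      librarySize = 3000,
                      samplesPerGroup = c(normal = 1L, primary = 1L,
                                          metastasis = 1L), seed = 5L)
    cfg3 <- simConfig(chromLengths = c(chr1 = 60000L), nGenes = 3L,
                      librarySize = 3000,
                      samplesPerGroup = c(normal = 2L, primary = 2L,
                                          metastasis = 2L), seed = 5L)
    s2 <- simulateExperiment(cfg2)
    s3 <- simulateExperiment(cfg3)
    expect_identical(s2$fragments[["normal_1"]], s3$fragments[["normal_1"]])
    expect_identical(s2$fragments[["primary_1"]], s3$fragments[["primary_1"]])
})

test_that("planted truth is exported exactly once per DMR", {
    fx <- tinyExperiment()
    path <- withr::local_tempfile(fileext = ".tsv")
    writeTruthTsv(fx$planted, path)
    back <- readTruthTsv(path)
    expect_identical(length(back), length(fx$planted))
    expect_identical(start(back), start(fx$planted))
    expect_identical(end(back), end(fx$planted))
    expect_identical(mcols(back)$direction, mcols(fx$planted)$direction)
    expect_identical(anyDuplicated(paste(seqnames(back), start(back))), 0L)
})
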
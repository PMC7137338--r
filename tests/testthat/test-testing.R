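test_that("NB GLM testing matches symmetry, oracle and conventions", {
    ## symmetric null: identical groups give logFC 0, p ~ 1
    wc <- makeWC(matrix(10L, nrow = 3, ncol = 6),
                 groups = rep(c("a", "b"), each = 3),
                 lib = rep(1000, 6))
    res <- fitNbGlm(wc, c("a", "b"), dispersion = 0.05)
    expect_equal(mcols(res)$logFC, rep(0, 3), tolerance = 1e-8)
    expect_true(all(mcols(res)$p > 0.99))

    ## extreme separation, cross-checked against a brute-force NB
    ## likelihood maximization on the same 2x3 table
    counts <- rbind(c(0L, 0L, 0L, 100L, 100L, 100L))
    wcX <- makeWC(counts, groups = rep(c("a", "b"), each = 3),
                  lib = rep(1000, 6))
    resX <- fitNbGlm(wcX, c("b", "a"), dispersion = 0.05)
    expect_gt(mcols(resX)$logFC, 3)
    expect_lt(mcols(resX)$p, 1e-4)
    oracle <- bfNbLrt(counts[1, 4:6], counts[1, 1:3],
                      rep(1000, 3), rep(1000, 3), disp = 0.05)
    expect_lt(oracle$p, 1e-4)
    expect_gt(oracle$logFC, 3)
    expect_equal(mcols(resX)$p, oracle$p, tolerance = 0.05)

    ## with estimated dispersion the call still works end to end
    set.seed(21)
    wcE <- makeWC(matrix(rpois(600, 30), ncol = 6),
                  groups = rep(c("a", "b"), each = 3))
    resE <- fitNbGlm(wcE, c("a", "b"))
    expect_true(all(mcols(resE)$p >= 0 & mcols(resE)$p <= 1))

    ## all-zero window convention
    cz <- rbind(c(0L, 0L, 0L, 0L, 0L, 0L), c(5L, 6L, 7L, 8L, 9L, 10L))
    wcZ <- makeWC(cz, groups = rep(c("a", "b"), each = 3),
                  lib = rep(1000, 6))
    resZ <- fitNbGlm(wcZ, c("a", "b"), dispersion = 0.05)
    expect_identical(mcols(resZ)$logFC[1], 0)
    expect_identical(mcols(resZ)$p[1], 1)

    ## design errors
    wc1 <- makeWC(matrix(1:6, 2), groups = c("a", "a", "a"))
    expect_error(fitNbGlm(wc1, c("a", "b")), "two groups|not in design")
})

test_that("logFC is offset-invariant on 100 random count tables", {
    ## the exact invariance regimes of the NB score equations: arbitrary
    ## offsets in the Poisson limit, and NB dispersion with equal library
    ## sizes within the fit (with unequal libraries the NB weights mu + k
    ## change with scale, so no implementation can be exactly invariant)
    set.seed(31)
    g <- c("a", "a", "b", "b")
    for (i in 1:50) {
        n <- sample(3:8, 1)
        counts <- matrix(rnbinom(4 * n, mu = runif(1, 5, 80), size = 10),
                         nrow = n)
        libs <- runif(4, 5e3, 2e4)
        r1 <- fitNbGlm(makeWC(counts, g, lib = libs), c("a", "b"),
                       dispersion = 0)
        r2 <- fitNbGlm(makeWC(2L * counts, g, lib = 2 * libs), c("a", "b"),
                       dispersion = 0)
        expect_lt(max(abs(mcols(r1)$logFC - mcols(r2)$logFC)), 1e-6)
    }
    for (i in 1:50) {
        n <- sample(3:8, 1)
        counts <- matrix(rnbinom(4 * n, mu = runif(1, 5, 80), size = 10),
                         nrow = n)
        lib0 <- runif(1, 5e3, 2e4)
        r1 <- fitNbGlm(makeWC(counts, g, lib = rep(lib0, 4)), c("a", "b"),
                       dispersion = 0.1)
        r2 <- fitNbGlm(makeWC(2L * counts, g, lib = rep(2 * lib0, 4)),
                       c("a", "b"), dispersion = 0.1)
        expect_lt(max(abs(mcols(r1)$logFC - mcols(r2)$logFC)), 1e-6)
    }
})

test_that("window merging follows the 50-bp gap rule", {
    mk <- function(s0, e0) {
        gr <- GRanges("chr1", IRanges(s0 + 1L, e0),
                      seqinfo = Seqinfo("chr1", 100000L))
        mcols(gr)$logFC <- 1
        mcols(gr)$p <- 0.5
        gr
    }
    ## gap exactly 50: merged
    r1 <- mergeTestedWindows(mk(c(1000, 1250), c(1200, 1450)), maxGap = 50L)
    expect_length(r1, 1)
    expect_identical(start(r1), 1001L)
    expect_identical(end(r1), 1450L)
    ## gap 51: two regions
    r2 <- mergeTestedWindows(mk(c(1000, 1251), c(1200, 1451)), maxGap = 50L)
    expect_length(r2, 2)
    ## single window: region equals it
    r3 <- mergeTestedWindows(mk(1000, 1200))
    expect_identical(granges(r3), granges(mk(1000, 1200)))
    ## unsorted input is rejected
    expect_error(mergeTestedWindows(mk(c(500, 100), c(700, 300))), "sorted")
})

test_that("merging agrees with an O(n^2) union-find oracle on fuzzed sets", {
    set.seed(41)
    for (rep in 1:60) {
        n <- sample(1:40, 1)
        chrom <- sort(sample(c("chr1", "chr2"), n, replace = TRUE))
        start0 <- unlist(lapply(split(seq_len(n), chrom), function(i)
            sort(sample.int(3000, length(i)))))
        width <- sample(10:200, n, replace = TRUE)
        maxGap <- sample(0:80, 1)
        gr <- GRanges(chrom, IRanges(start0 + 1L, start0 + width),
                      seqinfo = Seqinfo(c("chr1", "chr2"), c(1e5, 1e5)))
        gr <- sort(gr)
        mcols(gr)$logFC <- 0
        mcols(gr)$p <- 1
        regions <- mergeTestedWindows(gr, maxGap = maxGap)
        got <- integer(length(gr))
        for (k in seq_along(regions))
            got[mcols(regions)$member[[k]]] <- k
        want <- bfMergeOracle(as.character(seqnames(gr)), start(gr) - 1L,
                              end(gr), maxGap)
        ## same partition up to labeling: co-membership must agree pairwise
        expect_identical(outer(got, got, "=="), outer(want, want, "=="))
        ## span equals union hull of members
        for (k in seq_along(regions)) {
            i <- mcols(regions)$member[[k]]
            expect_identical(start(regions)[k], min(start(gr)[i]))
            expect_identical(end(regions)[k], max(end(gr)[i]))
        }
    }
})

test_that("Simes combination matches its definition", {
    expect_equal(simesPvalue(c(0.04, 0.01, 0.03)), 0.03)
    expect_identical(simesPvalue(0.37), 0.37)
    expect_identical(simesPvalue(c(1, 1)), 1)
    expect_error(simesPvalue(numeric(0)), "empty")
    expect_error(simesPvalue(c(0.5, 1.2)), "0, 1")
    set.seed(51)
    for (i in 1:50) {
        p <- runif(sample(1:50, 1))
        expect_equal(simesPvalue(p), bfSimes(p), tolerance = 1e-14)
    }
})

test_that("BH adjustment matches the step-up definition", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_identical(bhAdjust(0.5), 0.5)
    expect_identical(bhAdjust(c(1, 1, 1)), c(1, 1, 1))
    set.seed(52)
    for (i in 1:50) {
        p <- runif(sample(1:50, 1))
        expect_equal(bhAdjust(p), bfBH(p), tolerance = 1e-14)
    }
})

test_that("direction calls use the majority with the stated tie-break", {
    expect_identical(classifyDirection(c(2, 1, -0.5), c(0.1, 0.1, 0.1)),
                     "hyper")
    expect_identical(classifyDirection(c(-1, -2), c(0.5, 0.5)), "hypo")
    ## tie: direction of the smallest-p window
    expect_identical(classifyDirection(c(1, -1), c(0.001, 0.2)), "hyper")
    expect_identical(classifyDirection(c(1, -1), c(0.2, 0.001)), "hypo")
    ## full tie: hyper
    expect_identical(classifyDirection(0, 0.5), "hyper")
})

test_that("callDmrs composes the pipeline deterministically", {
    fx <- tinyExperiment()
    dm <- callDmrs(fx$wc, c("primary", "normal"))
    expect_true(all(c("n_windows", "logFC", "simes_p", "fdr", "direction",
                      "significant") %in% colnames(mcols(dm))))
    expect_true(all(mcols(dm)$fdr >= mcols(dm)$simes_p - 1e-12))

    ## fdr cutoff 0 flags nothing
    dm0 <- callDmrs(fx$wc, c("primary", "normal"), fdrCutoff = 0)
    expect_identical(sum(mcols(dm0)$significant), 0L)

    ## output invariant to sample order
    perm <- c(3L, 5L, 1L, 6L, 2L, 4L)
    wcP <- fx$wc[, perm]
    dmP <- callDmrs(wcP, c("primary", "normal"))
    expect_identical(granges(dm), granges(dmP))
    expect_equal(mcols(dm)$simes_p, mcols(dmP)$simes_p, tolerance = 1e-8)
    expect_identical(mcols(dm)$direction, mcols(dmP)$direction)
    expect_identical(mcols(dm)$significant, mcols(dmP)$significant)
})
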
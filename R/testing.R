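## Window-level NB-GLM testing, region merging, Simes combination, FDR and
## direction calling.

## resolve a contrast spec into the (numerator, denominator) group pair
.contrastPair <- function(contrast, levels) {
    if (is.numeric(contrast)) {
        if (!is.null(names(contrast))) contrast <- contrast[levels]
        if (length(contrast) != length(levels) ||
            sum(contrast == 1) != 1L || sum(contrast == -1) != 1L ||
            sum(contrast != 0) != 2L)
            stop("only pairwise (1, -1) contrasts are supported")
        contrast <- c(levels[contrast == 1], levels[contrast == -1])
    }
    if (!is.character(contrast) || length(contrast) != 2L)
        stop("contrast must be c('groupA','groupB') or a pairwise vector")
    if (!all(contrast %in% levels))
        stop("contrast group(s) not in design: ",
             paste(setdiff(contrast, levels), collapse = ", "))
    contrast
}

## exact one-group NB mean fit with log(lib) offsets and per-window
## dispersion, by vectorized Fisher scoring; returns the coefficient and
## the log-likelihood kernel (terms constant across mean models dropped)
.nbGroupFit <- function(counts, libs, disp, maxit = 100L) {
    counts <- as.matrix(counts)
    if (!nrow(counts)) return(list(b = numeric(0), ll = numeric(0)))
    k <- ifelse(disp > 0, 1 / disp, 1e8)
    b <- log((rowSums(counts) + 0.1) / sum(libs))
    for (it in seq_len(maxit)) {
        mu <- exp(b) %o% libs
        score <- rowSums(k * (counts - mu) / (mu + k))
        info <- rowSums(mu * k / (mu + k))
        step <- pmin(pmax(score / pmax(info, 1e-10), -5), 5)
        b <- pmin(b + step, 50)
        if (max(abs(step)) < 1e-12) break
    }
    b <- pmax(b, -50)
    mu <- exp(b) %o% libs
    ## likelihood kernel; the -(y + k) log k piece is model-independent and
    ## dropped, and log1p keeps the Poisson limit (large k) stable
    ll <- rowSums(counts * log(pmax(mu, 1e-300)) -
                  (counts + k) * log1p(mu / k))
    list(b = b, ll = ll)
}

## likelihood-ratio test of groupA vs groupB (other groups drop out of the
## statistic); logFC is the exact MLE difference, with a library-scaled
## prior-count fallback only where a group has no counts at all
.nbPairTest <- function(counts, libs, disp, isA, isB) {
    fA <- .nbGroupFit(counts[, isA, drop = FALSE], libs[isA], disp)
    fB <- .nbGroupFit(counts[, isB, drop = FALSE], libs[isB], disp)
    f0 <- .nbGroupFit(counts[, isA | isB, drop = FALSE], libs[isA | isB],
                      disp)
    stat <- pmax(2 * (fA$ll + fB$ll - f0$ll), 0)
    logFC <- (fA$b - fB$b) / log(2)
    bad <- rowSums(counts[, isA, drop = FALSE]) == 0 |
        rowSums(counts[, isB, drop = FALSE]) == 0
    if (any(bad)) {
        pc <- 0.125 * libs / mean(libs[isA | isB])
        aug <- t(t(counts[bad, , drop = FALSE]) + 2 * pc)
        gA <- .nbGroupFit(aug[, isA, drop = FALSE], libs[isA], disp[bad])
        gB <- .nbGroupFit(aug[, isB, drop = FALSE], libs[isB], disp[bad])
        logFC[bad] <- (gA$b - gB$b) / log(2)
    }
    list(logFC = logFC, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Test windows for differential binding with a negative-binomial GLM
#'
#' Fits, per window, an NB model with log link and log effective library
#' sizes as offsets.  Dispersions are Cox-Reid adjusted-profile-likelihood
#' estimates shrunk toward an abundance-dependent trend with
#' \code{priorDf} prior degrees of freedom (via edgeR's
#' \code{estimateDisp}); the group means are then maximized exactly by
#' Fisher scoring and the contrast is tested with a likelihood-ratio test.
#' In the one-way layout every supported contrast is a group pair, so the
#' null model constrains only the two contrasted groups to a common mean.
#' Windows whose counts are all zero in both contrasted groups get logFC 0
#' and p 1 by convention; a window with counts in only one of the groups
#' gets a finite logFC through a library-scaled prior count.
#'
#' @param x a filtered, normalized \linkS4class{WindowCounts}.
#' @param contrast either \code{c("groupA", "groupB")} for the log2 fold
#'   change of A over B, or a (1, -1) numeric contrast vector over the
#'   group levels.
#' @param priorDf prior degrees of freedom for dispersion shrinkage.
#' @param dispersion optional fixed NB dispersion (scalar or per-window),
#'   bypassing estimation; 0 gives the Poisson limit.  At fixed dispersion
#'   the fit is offset-invariant (doubling all counts and library sizes
#'   leaves logFC unchanged) exactly in the Poisson limit or with equal
#'   library sizes, which is as far as the NB score equations allow.
#' @return The window \code{GRanges} with mcols \code{logFC} (log2) and
#'   \code{p}.
#' @export
fitNbGlm <- function(x, contrast, priorDf = 10, dispersion = NULL) {
    stopifnot(is(x, "WindowCounts"))
    g <- droplevels(factor(colData(x)$group))
    if (nlevels(g) < 2L)
        stop("design needs at least two groups")
    design <- model.matrix(~ 0 + g)
    colnames(design) <- levels(g)
    if (qr(design)$rank < ncol(design))
        stop("singular design matrix")
    pair <- .contrastPair(contrast, levels(g))
    isA <- g == pair[1]
    isB <- g == pair[2]
    if (sum(isA | isB) < 2L)
        stop("contrast needs at least two samples in the contrasted groups")
    counts <- assay(x, "counts")
    effLib <- unname(effectiveLibSizes(x))
    if (is.null(dispersion)) {
        y <- edgeR::DGEList(counts = counts, lib.size = unname(libSizes(x)),
                            norm.factors = unname(normFactors(x)),
                            group = g)
        y <- edgeR::estimateDisp(y, design, prior.df = priorDf)
        dispersion <- y$tagwise.dispersion
    }
    dispersion <- rep_len(dispersion, nrow(counts))
    res <- .nbPairTest(counts, effLib, dispersion, isA, isB)
    out <- granges(rowRanges(x))
    mcols(out)$logFC <- res$logFC
    mcols(out)$p <- res$p
    allZero <- rowSums(counts[, isA | isB, drop = FALSE]) == 0
    mcols(out)$logFC[allZero] <- 0
    mcols(out)$p[allZero] <- 1
    out
}

#' Merge tested windows into candidate regions
#'
#' Two windows on the same chromosome belong to the same region when the
#' gap between them is at most \code{maxGap} bp (overlapping windows have
#' gap <= 0); regions are the transitive closure of that relation and span
#' the union hull of their members.
#'
#' @param results sorted window \code{GRanges} (output of
#'   \code{\link{fitNbGlm}}; only tested windows should be passed).
#' @param maxGap maximum merge gap in bp.
#' @return \code{GRanges} of regions with an \code{IntegerList} mcol
#'   \code{member} indexing into \code{results}.
#' @export
mergeTestedWindows <- function(results, maxGap = 50L) {
    if (!length(results)) {
        out <- GRanges(seqinfo = seqinfo(results))
        mcols(out)$member <- IntegerList()
        return(out)
    }
    chromInt <- as.integer(seqnames(results))
    o <- order(chromInt, start(results))
    if (any(o != seq_along(o)))
        stop("window results must be sorted by (chrom, start)")
    ## running max end within chromosome, then gap to the previous cluster
    runEnd <- end(results)
    newChrom <- c(TRUE, chromInt[-1] != chromInt[-length(chromInt)])
    runMax <- stats::ave(runEnd, cumsum(newChrom), FUN = cummax)
    gap <- start(results) - 1L - c(0L, runMax[-length(runMax)])
    newRegion <- newChrom | gap > maxGap
    id <- cumsum(newRegion)
    memb <- split(seq_along(results), id)
    regStart <- vapply(memb, function(i) min(start(results)[i]), integer(1))
    regEnd <- vapply(memb, function(i) max(end(results)[i]), integer(1))
    regChrom <- as.character(seqnames(results))[vapply(memb, `[`, integer(1), 1L)]
    out <- GRanges(regChrom, IRanges(regStart, regEnd))
    out <- .withSeqinfo(out, seqinfo(results))
    mcols(out)$member <- IntegerList(unname(memb))
    out
}

#' Simes combined p-value
#'
#' For sorted component p-values p(1) <= ... <= p(m), returns
#' min over i of m * p(i) / i, capped at 1.  Valid under positive
#' dependence, which holds for overlapping-window statistics.
#'
#' @param p nonempty numeric vector of p-values in [0, 1].
#' @return The combined p-value.
#' @examples
#' simesPvalue(c(0.04, 0.01, 0.03))  # 0.03
#' @export
simesPvalue <- function(p) {
    if (!length(p)) stop("empty p-value vector")
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    m <- length(p)
    min(1, min(m * sort(p) / seq_len(m)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment via \code{stats::p.adjust(method = "BH")}.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, capped at 1.
#' @export
bhAdjust <- function(p) {
    if (length(p) && (any(is.na(p)) || any(p < 0) || any(p > 1)))
        stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Call the methylation-change direction of a region
#'
#' Hyper if strictly more member windows have positive than negative log
#' fold change, hypo for the reverse; on a tie (zeros included) the
#' direction follows the sign of the member window with the smallest
#' p-value, and a remaining tie is called hyper (deterministic).
#'
#' @param logFC,p member-window log2 fold changes and p-values.
#' @return \code{"hyper"} or \code{"hypo"}.
#' @export
classifyDirection <- function(logFC, p) {
    stopifnot(length(logFC) >= 1L, length(logFC) == length(p))
    nUp <- sum(logFC > 0)
    nDown <- sum(logFC < 0)
    if (nUp > nDown) return("hyper")
    if (nDown > nUp) return("hypo")
    best <- logFC[which.min(p)]
    if (best < 0) "hypo" else "hyper"
}

#' Attach combined statistics to merged regions
#'
#' @param regions output of \code{\link{mergeTestedWindows}}.
#' @param results the window results the regions were merged from.
#' @return \code{regions} with mcols \code{n_windows}, \code{logFC}
#'   (mean member logFC), \code{simes_p} and \code{direction}.
#' @export
summarizeRegions <- function(regions, results) {
    memb <- mcols(regions)$member
    if (is.null(memb)) stop("regions lack a member mcol; run mergeTestedWindows")
    lfc <- mcols(results)$logFC
    pv <- mcols(results)$p
    mcols(regions)$n_windows <- lengths(memb)
    mcols(regions)$logFC <- vapply(memb, function(i) mean(lfc[i]), numeric(1))
    mcols(regions)$simes_p <- vapply(memb, function(i) simesPvalue(pv[i]),
                                     numeric(1))
    mcols(regions)$direction <- vapply(memb, function(i)
        classifyDirection(lfc[i], pv[i]), character(1))
    regions
}

#' Call differentially methylated regions
#'
#' Composes the full window pipeline for one contrast: (optional)
#' background-bin TMM normalization, abundance/chromosome filtering, NB-GLM
#' likelihood-ratio testing, gap-based merging, Simes combination, BH
#' adjustment across regions and direction calling.  Regions with adjusted
#' Simes p at or below \code{fdrCutoff} are flagged significant.
#'
#' @param x a \linkS4class{WindowCounts} from \code{\link{countWindows}}
#'   (unfiltered; filtering happens here).
#' @param contrast as in \code{\link{fitNbGlm}}.
#' @param fdrCutoff region-level FDR threshold.
#' @param maxGap merge gap, see \code{\link{mergeTestedWindows}}.
#' @param minCountSum,minAvgLogCpm,excludedChroms see
#'   \code{\link{filterWindows}}.
#' @param normalize estimate TMM factors first (skipped when factors are
#'   already set)?
#' @param binWidth background bin width for normalization.
#' @param priorDf dispersion shrinkage prior df.
#' @return Region \code{GRanges} with mcols \code{n_windows}, \code{logFC},
#'   \code{simes_p}, \code{fdr}, \code{direction}, \code{significant}.
#' @export
callDmrs <- function(x, contrast, fdrCutoff = 0.05, maxGap = 50L,
                     minCountSum = 30, minAvgLogCpm = -1,
                     excludedChroms = c("X", "Y"),
                     normalize = TRUE, binWidth = 2000L, priorDf = 10) {
    stopifnot(is(x, "WindowCounts"))
    if (normalize && ncol(x) >= 2L && all(normFactors(x) == 1))
        x <- estimateNormFactors(x, binWidth = binWidth)
    xf <- filterWindows(x, minCountSum = minCountSum,
                        minAvgLogCpm = minAvgLogCpm,
                        excludedChroms = excludedChroms)
    res <- fitNbGlm(xf, contrast, priorDf = priorDf)
    regions <- summarizeRegions(mergeTestedWindows(res, maxGap = maxGap), res)
    mcols(regions)$fdr <- bhAdjust(mcols(regions)$simes_p)
    mcols(regions)$significant <- if (fdrCutoff <= 0)
        rep(FALSE, length(regions)) else mcols(regions)$fdr <= fdrCutoff
    mcols(regions)$member <- NULL
    regions
}
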
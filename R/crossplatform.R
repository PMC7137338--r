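## MBDE-vs-targeted-bisulfite concordance: per-CpG beta regression on
## bisulfite counts, propagation of region statistics to CpGs, joint
## classification, density-stratified correlation and >= 1-bp DMR overlap.

## negative beta log-likelihood with logit mean link and common precision
.betaNll <- function(par, y, x) {
    mu <- plogis(par[1] + par[2] * x)
    phi <- exp(par[3])
    -sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

## fit one CpG; returns c(diff, p, propA, propB, converged)
.fitBetaCpG <- function(y, x, maxit = 200L) {
    n <- length(y)
    y <- (y * (n - 1) + 0.5) / n  # squeeze into the open unit interval
    mA <- mean(y[x == 1]); mB <- mean(y[x == 0])
    start <- c(qlogis(min(max(mB, 1e-3), 1 - 1e-3)),
               qlogis(min(max(mA, 1e-3), 1 - 1e-3)) -
                   qlogis(min(max(mB, 1e-3), 1 - 1e-3)),
               log(10))
    fit <- tryCatch(
        optim(start, .betaNll, y = y, x = x, method = "BFGS",
              hessian = TRUE, control = list(maxit = maxit)),
        error = function(e) NULL)
    propA <- if (is.null(fit)) mA else plogis(fit$par[1] + fit$par[2])
    propB <- if (is.null(fit)) mB else plogis(fit$par[1])
    if (is.null(fit) || fit$convergence != 0)
        return(c(diff = propA - propB, p = 1, propA = propA, propB = propB,
                 converged = 0))
    se <- tryCatch({
        v <- solve(fit$hessian)[2, 2]
        if (!is.finite(v) || v <= 0) NA_real_ else sqrt(v)
    }, error = function(e) NA_real_)
    if (is.na(se))
        return(c(diff = propA - propB, p = 1, propA = propA, propB = propB,
                 converged = 0))
    z <- fit$par[2] / se
    c(diff = propA - propB, p = 2 * pnorm(-abs(z)), propA = propA,
      propB = propB, converged = 1)
}

#' Per-CpG beta regression on targeted bisulfite counts
#'
#' Models the observed methylation proportion of each CpG with a beta
#' likelihood (logit mean link, common precision per CpG), maximized
#' numerically, and tests the group effect with a Wald test.  Proportions
#' are squeezed into the open unit interval with the standard
#' \code{(y * (n - 1) + 0.5) / n} transform.  CpGs with fewer than two
#' covered samples in either group are skipped and reported; CpGs whose
#' fit fails to converge are flagged and get the conservative p = 1.
#'
#' @param counts named list of per-sample bisulfite \code{GRanges} (mcols
#'   \code{methylated}, \code{total}), as from
#'   \code{\link{simulateBisulfiteCounts}}; all samples must share the
#'   same site set.
#' @param groups group label per sample.
#' @param contrast \code{c("tumorGroup", "referenceGroup")}; the reported
#'   difference is tumor minus reference.
#' @return Width-1 CpG \code{GRanges} with mcols \code{prop_tumor},
#'   \code{prop_ref} (fitted group means), \code{diff}, \code{p} and
#'   \code{converged}; skipped sites are in
#'   \code{metadata(result)$skipped}.
#' @export
betaRegressionPerCpG <- function(counts, groups,
                                 contrast = c("primary", "normal")) {
    stopifnot(length(counts) == length(groups), length(contrast) == 2L)
    use <- groups %in% contrast
    counts <- counts[use]
    groups <- groups[use]
    if (!length(counts)) stop("no samples in the contrasted groups")
    sites <- granges(counts[[1]])
    if (any(vapply(counts, length, integer(1)) != length(sites)))
        stop("all samples must cover the same CpG set")
    meth <- matrix(vapply(counts, function(g) as.numeric(mcols(g)$methylated),
                          numeric(length(sites))), ncol = length(counts))
    total <- matrix(vapply(counts, function(g) as.numeric(mcols(g)$total),
                           numeric(length(sites))), ncol = length(counts))
    x <- as.integer(groups == contrast[1])
    covA <- rowSums(total[, x == 1, drop = FALSE] > 0)
    covB <- rowSums(total[, x == 0, drop = FALSE] > 0)
    testable <- covA >= 2 & covB >= 2
    skipped <- sites[!testable]
    sites <- sites[testable]
    meth <- meth[testable, , drop = FALSE]
    total <- total[testable, , drop = FALSE]
    res <- matrix(NA_real_, nrow = length(sites), ncol = 5)
    for (i in seq_len(nrow(res))) {
        cov <- total[i, ] > 0
        res[i, ] <- .fitBetaCpG(meth[i, cov] / total[i, cov], x[cov])
    }
    mcols(sites)$prop_tumor <- res[, 3]
    mcols(sites)$prop_ref <- res[, 4]
    mcols(sites)$diff <- res[, 1]
    mcols(sites)$p <- res[, 2]
    mcols(sites)$converged <- res[, 5] == 1
    metadata(sites)$skipped <- skipped
    sites
}

#' Propagate region-level statistics to the CpGs they contain
#'
#' Nearby CpGs are frequently co-methylated, so every CpG inside a
#' capture-derived region inherits the region's log fold change and
#' combined p-value; CpGs outside all regions are marked as not covered.
#'
#' @param regions non-overlapping region \code{GRanges} with mcols
#'   \code{logFC} and \code{simes_p} (or \code{p}).
#' @param cpgs width-1 \code{GRanges} of CpG positions.
#' @return \code{cpgs} with mcols \code{mbde_covered}, \code{mbde_logFC},
#'   \code{mbde_p}.
#' @export
propagateRegionStats <- function(regions, cpgs) {
    if (length(regions) > 1L) {
        hits <- findOverlaps(regions, regions)
        if (any(queryHits(hits) != subjectHits(hits)))
            stop("regions overlap each other; merge them first")
    }
    pcol <- if ("simes_p" %in% colnames(mcols(regions))) "simes_p" else "p"
    hits <- findOverlaps(cpgs, regions)
    out <- cpgs
    mcols(out)$mbde_covered <- FALSE
    mcols(out)$mbde_logFC <- NA_real_
    mcols(out)$mbde_p <- NA_real_
    mcols(out)$mbde_covered[queryHits(hits)] <- TRUE
    mcols(out)$mbde_logFC[queryHits(hits)] <-
        mcols(regions)$logFC[subjectHits(hits)]
    mcols(out)$mbde_p[queryHits(hits)] <-
        mcols(regions)[[pcol]][subjectHits(hits)]
    out
}

#' Jointly classify CpGs covered by both platforms
#'
#' Per-method calls: TE is hyper when the fitted proportion difference is
#' > 0, hypo when < 0 and none when exactly 0 (ties at 1e-12 resolution);
#' MBDE is hyper when logFC > 0 with p < alpha, hypo when logFC < 0 with
#' p < alpha, none otherwise.  Joint classes: \code{hyper_concordant}
#' (both hyper), \code{hypo_concordant} (both hypo), \code{iso} (TE
#' difference 0 and MBDE none with logFC 0) and \code{other}, the latter
#' subclassified (e.g. \code{MBDE_only_hyper}, \code{TE_only_hypo},
#' \code{discordant}).
#'
#' @param teDiff,teP TE fitted proportion differences and p-values.
#' @param mbdeLogFC,mbdeP propagated MBDE statistics.
#' @param alpha significance level for the MBDE call.
#' @return \code{data.frame} with columns \code{te_call},
#'   \code{mbde_call}, \code{joint_class}, \code{joint_subclass}.
#' @export
classifyCpGCalls <- function(teDiff, teP, mbdeLogFC, mbdeP, alpha = 0.05) {
    if (any(is.na(teDiff)) || any(is.na(mbdeLogFC)) || any(is.na(mbdeP)))
        stop("records must be covered by both methods (no NA statistics)")
    d <- round(teDiff, 12)
    te <- ifelse(d > 0, "hyper", ifelse(d < 0, "hypo", "none"))
    mbde <- ifelse(mbdeLogFC > 0 & mbdeP < alpha, "hyper",
                   ifelse(mbdeLogFC < 0 & mbdeP < alpha, "hypo", "none"))
    joint <- rep("other", length(d))
    joint[te == "hyper" & mbde == "hyper"] <- "hyper_concordant"
    joint[te == "hypo" & mbde == "hypo"] <- "hypo_concordant"
    joint[te == "none" & mbde == "none" & mbdeLogFC == 0] <- "iso"
    sub <- rep(NA_character_, length(d))
    isOther <- joint == "other"
    sub[isOther & mbde != "none" & te == "none"] <-
        paste0("MBDE_only_", mbde[isOther & mbde != "none" & te == "none"])
    sub[isOther & mbde == "none" & te != "none"] <-
        paste0("TE_only_", te[isOther & mbde == "none" & te != "none"])
    sub[isOther & mbde != "none" & te != "none" & mbde != te] <- "discordant"
    sub[isOther & is.na(sub)] <- "no_call"
    data.frame(te_call = te, mbde_call = mbde, joint_class = joint,
               joint_subclass = sub, stringsAsFactors = FALSE)
}

#' Density-stratified concordance summary
#'
#' Pearson correlation between MBDE log fold change and TE proportion
#' difference within each CpG-density stratum, plus joint-class counts.
#' Strata with fewer than 3 CpGs or zero variance in either variable get
#' \code{NA} correlation and are flagged undefined rather than reported as
#' 0.
#'
#' @param mbdeLogFC,teDiff per-CpG statistics (both-covered CpGs only).
#' @param densityClass per-CpG density class (low / intermediate / high).
#' @param jointClass per-CpG joint class from
#'   \code{\link{classifyCpGCalls}} (optional).
#' @return \code{data.frame} with one row per stratum plus an
#'   \code{overall} row: \code{n}, \code{r}, \code{undefined} and, when
#'   \code{jointClass} is given, one count column per joint class.
#' @export
correlateMethods <- function(mbdeLogFC, teDiff, densityClass,
                             jointClass = NULL) {
    stopifnot(length(mbdeLogFC) == length(teDiff),
              length(teDiff) == length(densityClass))
    strata <- c(intersect(c("low", "intermediate", "high"),
                          unique(densityClass)), "overall")
    rows <- lapply(strata, function(s) {
        idx <- if (s == "overall") rep(TRUE, length(teDiff))
               else densityClass == s
        xs <- mbdeLogFC[idx]; ys <- teDiff[idx]
        ok <- sum(idx) >= 3 && stats::sd(xs) > 0 && stats::sd(ys) > 0
        row <- data.frame(stratum = s, n = sum(idx),
                          r = if (ok) cor(xs, ys) else NA_real_,
                          undefined = !ok, stringsAsFactors = FALSE)
        if (!is.null(jointClass)) {
            for (cl in c("hyper_concordant", "hypo_concordant", "iso",
                         "other"))
                row[[cl]] <- sum(jointClass[idx] == cl)
        }
        row
    })
    do.call(rbind, rows)
}

#' Direction-aware >= 1-bp overlap between two DMR sets
#'
#' A region is "both" iff it shares at least 1 bp with at least one region
#' of the same direction in the other set (counted once however many
#' partners it has).
#'
#' @param setA,setB internally non-overlapping region \code{GRanges} with
#'   a \code{direction} mcol.
#' @return A list with \code{a_both}, \code{a_only}, \code{b_both},
#'   \code{b_only} (GRanges) and a \code{counts} data.frame per direction.
#' @export
overlapDmrs <- function(setA, setB) {
    stopifnot(!is.null(mcols(setA)$direction), !is.null(mcols(setB)$direction))
    matched <- function(x, y) {
        hit <- rep(FALSE, length(x))
        for (d in unique(mcols(x)$direction)) {
            xi <- mcols(x)$direction == d
            yi <- mcols(y)$direction == d
            if (any(yi))
                hit[xi] <- overlapsAny(x[xi], y[yi], minoverlap = 1L)
        }
        hit
    }
    aHit <- matched(setA, setB)
    bHit <- matched(setB, setA)
    dirs <- union(mcols(setA)$direction, mcols(setB)$direction)
    counts <- do.call(rbind, lapply(dirs, function(d) data.frame(
        direction = d,
        a_both = sum(aHit & mcols(setA)$direction == d),
        a_only = sum(!aHit & mcols(setA)$direction == d),
        b_both = sum(bHit & mcols(setB)$direction == d),
        b_only = sum(!bHit & mcols(setB)$direction == d),
        stringsAsFactors = FALSE)))
    list(a_both = setA[aHit], a_only = setA[!aHit],
         b_both = setB[bHit], b_only = setB[!bHit], counts = counts)
}
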
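## Independent brute-force oracles.  These re-derive every combined
## statistic from first principles, separately from the package's code
## paths, so that implementation and oracle can disagree.

## Simes: literal formula over the sorted vector
bfSimes <- function(p) {
    m <- length(p)
    sp <- sort(p)
    min(1, min(sp * m / seq_len(m)))
}

## Benjamini-Hochberg step-up from the definition (running minimum from the
## largest rank down)
bfBH <- function(p) {
    m <- length(p)
    o <- order(p)
    sorted <- p[o]
    adj <- numeric(m)
    run <- Inf
    for (i in m:1) {
        run <- min(run, sorted[i] * m / i)
        adj[i] <- min(1, run)
    }
    out <- numeric(m)
    out[o] <- adj
    out
}

## O(n^2) union-find closure of the "gap <= maxGap on the same chromosome"
## relation; intervals are 0-based half-open.  Returns a canonical member
## id per interval.
bfMergeOracle <- function(chrom, start0, end0, maxGap) {
    n <- length(start0)
    parent <- seq_len(n)
    findRoot <- function(i) {
        while (parent[i] != i) i <- parent[i]
        i
    }
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i < j && chrom[i] == chrom[j]) {
            gap <- max(start0[i], start0[j]) - min(end0[i], end0[j])
            if (gap <= maxGap) {
                ri <- findRoot(i); rj <- findRoot(j)
                if (ri != rj) parent[ri] <- rj
            }
        }
    }
    vapply(seq_len(n), findRoot, integer(1))
}

## brute-force NB GLM likelihood-ratio test for a two-group table with
## log(lib) offsets and fixed dispersion, maximized by 1-d optimization
bfNbLrt <- function(yA, yB, libA, libB, disp) {
    ll <- function(b, y, lib) sum(dnbinom(y, mu = exp(b) * lib,
                                          size = 1 / disp, log = TRUE))
    mx <- function(y, lib) optimize(ll, c(-30, 10), y = y, lib = lib,
                                    maximum = TRUE)
    fA <- mx(yA, libA); fB <- mx(yB, libB)
    f0 <- mx(c(yA, yB), c(libA, libB))
    stat <- 2 * (fA$objective + fB$objective - f0$objective)
    list(logFC = (fA$maximum - fB$maximum) / log(2),
         p = pchisq(max(stat, 0), df = 1, lower.tail = FALSE))
}

## independent beta-regression ML oracle on the (muA, muB, phi) scale,
## maximized with nlminb; the squeeze transform mirrors the stated model
bfBetaFit <- function(y, x) {
    n <- length(y)
    ys <- (y * (n - 1) + 0.5) / n
    nll <- function(par) {
        muA <- par[1]; muB <- par[2]; phi <- exp(par[3])
        if (muA <= 0 || muA >= 1 || muB <= 0 || muB >= 1) return(1e10)
        mu <- ifelse(x == 1, muA, muB)
        -sum(dbeta(ys, mu * phi, (1 - mu) * phi, log = TRUE))
    }
    fit <- nlminb(c(mean(ys[x == 1]), mean(ys[x == 0]), log(10)), nll,
                  lower = c(1e-6, 1e-6, -10), upper = c(1 - 1e-6, 1 - 1e-6, 20),
                  control = list(rel.tol = 1e-12))
    list(diff = fit$par[1] - fit$par[2], nll = fit$objective)
}
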
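---
title: "capDMR: models, design choices and what the synthetic benchmarks show"
author: "capDMR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{capDMR methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement and the statistical model

MBD-capture sequencing enriches sheared DNA for methylated fragments with a
methyl-CpG-binding-domain polypeptide before sequencing.  Coverage is
therefore a *relative* readout: it grows with the number of methylated CpGs
on each molecule and carries no absolute methylation fraction.  The natural
analysis is differential binding between sample groups, exactly as for
ChIP-seq-style enrichment data.

capDMR implements the windowed form of that analysis:

1. **Counting.** Fragments (single-end reads extended to the 200-bp
   fragment size from their 5' end, strand-aware) are counted into 200-bp
   windows spaced every 10 bp (190-bp overlap).  A fragment counts toward a
   window when they share at least 1 bp.  Windows tile each chromosome from
   coordinate 0; all interval arithmetic is 0-based half-open on disk (BED)
   and `GRanges` in memory.
2. **Filtering.** Windows are kept when their count sum across samples is
   at least 30 and their average log2 counts-per-million is at least -1,
   with logCPM computed per sample as
   `log2(((count + 0.5) / (effective library size + 1)) * 1e6)`; both
   boundaries are inclusive.  Sex chromosomes are excluded (tolerant of a
   `chr` prefix).
3. **Normalization.** Trimmed-mean-of-M-values factors are computed on
   2-kb bins restricted to the low-abundance background (at or below the
   0.6 abundance quantile) and rescaled to geometric mean 1.  Background
   normalization matters for enrichment data because capture competes for
   a fixed sequencing budget: when one group gains methylation, its
   enriched loci soak up reads and unchanged loci would otherwise look
   depleted.  We calibrated the estimator against the ground truth the
   generator provides (median logFC of unchanged windows should be 0):
   raw library-size offsets left a systematic -0.09 log2 shift, 10-kb TMM
   bins -0.03, 2-kb bins -0.01 at moderate signal loads — but with
   broader planted signal, bins *partially* overlapping differential
   regions form a continuum of intermediate M-values that no trim
   fraction can separate (-0.05 residual regardless of `logratioTrim`).
   Restricting factor estimation to low-abundance bins, where capture
   signal cannot live, brings the residual back to ~-0.01.  A
   `--norm totals`-style escape hatch (`normalize = FALSE` after leaving
   factors at 1) is available.
4. **Testing.** Each filtered window is tested with a negative-binomial
   model with log link and log effective library sizes as offsets.
   Window dispersions are Cox-Reid adjusted-profile-likelihood estimates
   shrunk toward an abundance-dependent trend with 10 prior degrees of
   freedom (edgeR's `estimateDisp`).  Given those dispersions the group
   means are maximized exactly by vectorized Fisher scoring (converged to
   1e-12) and the contrast is assessed with a likelihood-ratio test.  All
   study contrasts are pairwise, so the null model constrains only the two
   contrasted groups to a common mean; the third group drops out of the
   statistic.  We fit the means ourselves rather than through a general
   GLM solver because the generic Levenberg path leaves ~1e-2
   non-reproducibility in logFC under exact count/library rescaling, which
   breaks the offset-invariance property we assert in the test suite.
   Note a genuine limit of that property: the NB score weights `mu + k`
   depend on scale, so exact invariance holds only in the Poisson limit or
   with equal library sizes — the property tests cover those regimes.
5. **Regions.** Tested windows separated by at most 50 bp (same
   chromosome; overlapping windows have gap <= 0) are merged into regions
   by transitive closure.  The region p-value is the Simes combination
   `min_i ( m * p_(i) / i )` of its member windows, valid under the
   positive dependence that overlapping windows exhibit.  Regions are
   BH-adjusted and flagged at FDR 0.05.
6. **Direction.** A region is hypermethylated if strictly more member
   windows have positive than negative logFC, hypomethylated for the
   reverse; a tie follows the sign of the smallest-p member, and a
   remaining tie is called hyper (deterministic).

## Annotation layers

The genic context uses three layers built from gene models: *regulatory*
(the strand-aware 5-kb stretch upstream of the TSS unioned with the
5'UTR), *gene body* (end of 5'UTR to start of 3'UTR) and *3'UTR*.
Anything outside is extragenic.  The CpG context treats an island with its
flanking shores and shelves as one composite (sSISs) unit: shores are the
2-kb island flanks minus the islands, shelves the next 2-kb band, with
precedence island > shore > shelf so the layers are pairwise disjoint.
Shore/shelf widths of 2 kb follow the convention of the standard
annotation sources; they are arguments, not constants.  A region is
assigned to the layer with the largest overlap, ties broken
regulatory > gene_body > utr3 and island > shore > shelf; "intragenic" and
"sSISs" membership needs only 1 bp of overlap, matching the overlap
convention used everywhere else.  Because each region receives exactly one
class and one subclass, class counts partition any region set — the
property the stacked-bar summaries rely on.

CpG density is the classical observed/expected CpG statistic on the 200-bp
window centered on each CpG: observed CG dinucleotide count divided by
(#C x #G / length), 0 when no C or G is present, with N counting toward
length but not composition.  Classes: low < 0.3 <= intermediate < 0.6 <=
high.

## Cross-platform concordance

Targeted bisulfite sequencing (TE) yields absolute per-CpG
methylated/total counts.  For each CpG the methylation proportion is
modeled with a beta likelihood (logit mean link, common precision per
CpG), maximized numerically (BFGS on `(b0, b1, log phi)`); the group
effect is tested with a Wald test and the reported difference is the
fitted group-mean difference.  Observed proportions are squeezed into the
open unit interval with `(y * (n - 1) + 0.5) / n`.  CpGs with fewer than
two covered samples per group are skipped and reported; non-converged fits
are flagged and assigned the conservative p = 1.  Note the squeeze
compresses extreme differences slightly (a true 0.6 gap fits near 0.54
with n = 10); the difference is reported on the squeezed, fitted scale.

On the capture side, every CpG inside a region inherits the region's logFC
and Simes p (nearby CpGs are frequently co-methylated, which is what makes
the propagation meaningful); the *unadjusted* Simes p is propagated
because the per-CpG classification rule thresholds a p-value, not an FDR
(configurable).  CpGs covered by both platforms are classified per method
(TE by the sign of the fitted difference; capture by logFC sign with
p < 0.05) and jointly (hyper/hypo-concordant, iso, other with subclasses
such as `TE_only_hypo`).  `iso` requires an exact zero difference (at
1e-12) and zero logFC, so it is rare with continuous statistics — honored
as the classification is defined.  Pearson correlations between capture
logFC and TE difference are computed within each CpG-density stratum;
strata with fewer than 3 CpGs or zero variance are reported undefined, not
as 0.

Direction-aware DMR overlap between two platforms' region sets uses the
>= 1-bp rule, each region counting once however many partners it has.

## The synthetic-data generator

The generator's job is to produce data with the statistical structure the
analysis assumes, at desk scale, with planted truth:

* **Genome.** Background sequence is i.i.d. with G+C ~0.4, shaped into a
  CpG-density mosaic by thinning CG dinucleotides: "sea" blocks (mean
  1.2 kb, CG keep 0.45, O:E ~0.5) alternate with CpG-poor "deserts" (mean
  3 kb, keep 0.01).  Deserts are what makes capture coverage regionally
  structured — with a uniform background every window passes the abundance
  filter and the whole chromosome merges into a single region, which no
  real capture experiment shows.  Each gene promoter carries one CpG-dense
  island (Markov-generated; O:E >= 0.6 and G+C >= 0.5 by construction,
  re-verifiable with `oeCpGRatio`) flanked by 2-kb intermediate-density
  shore zones (keep 0.30), as real shores are.
* **Methylome.** Island CpGs start near 0.05-0.10, open-sea CpGs near
  0.75-0.85 (the canonical somatic pattern).  Hyper DMRs are planted over
  island +/- 2 kb — promoter hypermethylation in tumors spreads across the
  island-shore unit — with delta +0.5 in both tumor groups by default.
  Hypo DMRs are short (200-400 bp), low magnitude (delta -0.2), placed in
  open sea with 2-6 CpGs so they sit in the CpG-sparse territory where
  tumor hypomethylation concentrates, metastasis-only by default.  These
  magnitudes follow the observed asymmetry between large island gains and
  shallow open-sea losses.  A `tumorDriftSd` knob can add regionally
  coherent methylome drift shared by both tumor groups; it defaults to 0
  because drift constitutes genuine (unplanted) differential signal and
  would blur planted-truth bookkeeping.
* **Capture.** Candidate fragments get uniform starts and
  Normal(200, 20) lengths truncated at 50 bp; the candidate total is
  negative binomial around the library size (600,000 by default — a deep
  library that puts sea windows near mean count 100 per sample, which is
  what makes the low-magnitude hypo signal sit at the detection edge, as
  it does in practice).  Each CpG on a molecule is methylated with
  probability equal to its sample-jittered level (jitter sd 0.02; the
  study gives no between-sample variability figure, so this is exposed as
  a parameter) and the molecule is captured with probability
  `1 - (1 - q)^k`, the simplest per-molecule affinity model that makes
  coverage increase with methylated-CpG content (q = 0.1 per CpG).
  A fully unmethylated molecule is never captured.
* **Bisulfite.** Per CpG, totals are negative binomial around coverage 30
  and methylated counts beta-binomial (rho = 0.02) around the jittered
  level.
* **Reproducibility.** Every operation derives its own RNG substream from
  the config seed via a small integer hash of a stream label, so outputs
  are bit-identical per seed and adding samples never perturbs earlier
  samples.

What the generator does **not** emulate: sequencing error, mappability and
GC bias, copy-number aberrations, diploidy, real hg19 coordinates or real
CpG-island tracks, probe design for targeted enrichment, or fragment-level
read models (the pipeline consumes aligned intervals, so read-level error
belongs upstream).  Passing benchmarks on this generator therefore shows
that the *statistical machinery* behaves as intended under the assumed
data structure — calibrated nulls, recovery of planted signal, the
expected platform asymmetry — not that any particular biological dataset
would yield the same numbers.

## Built-in evaluation scenarios

Four exported functions rerun the whole analysis on fixed study designs
(sub-seeded from one user seed).  Sizes were chosen so each scenario runs
in minutes on one core while keeping >= 2,000 filtered windows and a
planted-signal fraction of ~10-15% of the genome — above ~30% the TMM trim
can no longer see past the planted signal and composition correction
degrades, which is a genuine regime boundary of background normalization,
not an implementation artifact.

* `benchmarkNull()` — default 500-kb genome, 3 vs 3, no planted effects.
  Raw p < 0.05 fraction and FDR-flagged region fraction.
* `benchmarkRecovery()` — 1.6-Mb genome, 60 genes, 50 planted island
  hyper DMRs (+0.5, both groups), 3 vs 3.  Recall at >= 1-bp overlap and
  per-truth direction accuracy.
* `benchmarkContrasts()` — 1.2-Mb genome, the study's design (3 normal /
  6 primary / 12 metastases), 30 shared hyper DMRs plus 60
  metastasis-only hypo DMRs; both tumor-vs-normal contrasts, their mutual
  hyper overlap and the metastasis-exclusivity of detected hypo DMRs; a
  second simulation with identical effects in both tumor groups provides
  the metastasis-vs-primary null.
* `benchmarkPlatforms()` — one latent methylome (30 hyper, 60
  primary-affected hypo) pushed through both generators: capture for a
  3 vs 3 cohort, bisulfite for an independent 5 vs 5 cohort (per-CpG beta
  regression with n = 3 per group would have too few residual degrees of
  freedom to be a sane design, and the two platforms' cohorts are
  distinct in the emulated study anyway).  Reports the TE hypo call rate
  on planted hypo CpGs, the capture-side hypo flag rate, and the
  density-stratified Pearson correlations.

`scripts/acceptance.R` runs all four and writes the headline numbers as
JSON.

## Numerical choices and degenerate inputs

* Window tiling starts at coordinate 0 on every chromosome (no phase is
  stated anywhere authoritative; 0 is deterministic).
* logCPM stabilizers are +0.5 on counts and +1 on effective library
  sizes; boundary windows at exactly the thresholds are kept.
* Dispersion shrinkage prior df is 10; windows with too few residual df
  fall back toward the trend inside `estimateDisp`.
* A window with zero counts in both contrasted groups is logFC 0, p 1 by
  convention; zero counts in exactly one group get a finite logFC through
  a library-scaled prior count (0.125 per average observation), while the
  p-value always comes from the unaugmented likelihood-ratio statistic.
* Simes and BH are capped at 1; `simesPvalue` rejects empty input.
* Beta-regression fits that fail to converge (or produce a singular
  Hessian) are flagged and given p = 1.
* `classifyDirection` ties are broken by the smallest-p member, then
  toward hyper — deterministic by construction.
* Region merging requires sorted input and errors otherwise; the gap
  between 0-based half-open intervals is `next.start - current.end`.

## Known limitations

* Only pairwise contrasts are supported by design; the emulated analysis
  uses nothing else.  A quasi-likelihood option is not provided.
* Capture coverage is relative; the package deliberately makes no attempt
  to calibrate absolute methylation from it — cross-platform comparison is
  handled by the concordance module instead.
* The beta regression replaces spatially smoothed cluster-wise testing
  with direct per-CpG fits; this is a stated simplification that tests
  each site independently.
* With planted (or real) differential signal covering a large fraction of
  the genome, background TMM normalization degrades (see above); users
  analyzing heavily remodeled genomes should inspect normalization
  diagnostics.
* The open-sea hypomethylation signal is detected with limited power at
  3 vs 3 — this mirrors the platform's real behavior and is asserted as
  an asymmetry property rather than "fixed".
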
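mkGene <- function(chrom, strand, tss, chromLen = 100000L) {
    ## standard layout used by the generator: 200-bp 5'UTR, 2-kb body,
    ## 300-bp 3'UTR, strand-aware
    if (strand == "+") {
        u5 <- IRanges(tss, width = 200L)
        body <- IRanges(tss + 200L, width = 2000L)
        u3 <- IRanges(tss + 2200L, width = 300L)
    } else {
        u5 <- IRanges(tss - 199L, width = 200L)
        body <- IRanges(tss - 2199L, width = 2000L)
        u3 <- IRanges(tss - 2499L, width = 300L)
    }
    gr <- GRanges(chrom, IRanges(min(start(u5), start(u3)),
                                 max(end(u5), end(u3))), strand = strand,
                  seqinfo = Seqinfo(chrom, chromLen))
    mcols(gr)$tss <- as.integer(tss)
    mcols(gr)$utr5 <- u5
    mcols(gr)$body <- body
    mcols(gr)$utr3 <- u3
    gr
}

test_that("regulatory layer is 5 kb upstream plus the 5'UTR, strand-aware", {
    ## + strand gene, TSS at 0-based 10,000, 5'UTR [10000, 10200)
    g <- mkGene("chr1", "+", 10001L)
    ann <- buildIntragenicLayers(g, upstream = 5000L)
    reg <- genicLayers(ann)$regulatory
    ## union of [5000, 10000) and [10000, 10200) in 0-based terms
    expect_identical(start(reg) - 1L, 5000L)
    expect_identical(end(reg), 10200L)
    body <- genicLayers(ann)$gene_body
    expect_identical(c(start(body) - 1L, end(body)), c(10200L, 12200L))
    u3 <- genicLayers(ann)$utr3
    expect_identical(c(start(u3) - 1L, end(u3)), c(12200L, 12500L))

    ## - strand gene near the chromosome end: upstream clipped to bounds
    gM <- mkGene("chr1", "-", 3000L, chromLen = 4000L)
    annM <- buildIntragenicLayers(gM, upstream = 5000L)
    regM <- genicLayers(annM)$regulatory
    expect_lte(max(end(regM)), 4000L)
    expect_true(any(start(regM) <= 3000L & end(regM) >= 3000L))

    ## overlapping upstream regions are merged within the layer
    g2 <- c(mkGene("chr1", "+", 10001L), mkGene("chr1", "+", 12001L))
    ann2 <- buildIntragenicLayers(g2, upstream = 5000L)
    reg2 <- genicLayers(ann2)$regulatory
    expect_identical(length(reduce(reg2)), length(reg2))
    expect_identical(start(reg2) - 1L, 5000L)
})

test_that("sSISs layers are disjoint with island > shore > shelf precedence", {
    si <- Seqinfo("chr1", 100000L)
    ## isolated island, 0-based [10000, 11000)
    isl <- GRanges("chr1", IRanges(10001, 11000), seqinfo = si)
    ann <- buildSsissLayers(isl, shoreWidth = 2000L, shelfWidth = 2000L)
    shores <- cpgLayers(ann)$shore
    shelves <- cpgLayers(ann)$shelf
    expect_identical(start(shores) - 1L, c(8000L, 11000L))
    expect_identical(end(shores), c(10000L, 13000L))
    expect_identical(start(shelves) - 1L, c(6000L, 13000L))
    expect_identical(end(shelves), c(8000L, 15000L))

    ## two islands 1 kb apart: the gap is entirely shore
    isl2 <- GRanges("chr1", IRanges(c(10001, 12001), c(11000, 13000)),
                    seqinfo = si)
    ann2 <- buildSsissLayers(isl2)
    gap <- GRanges("chr1", IRanges(11001, 12000))
    expect_identical(sum(width(intersect(gap, cpgLayers(ann2)$shore))), 1000L)
    expect_identical(sum(width(intersect(gap, cpgLayers(ann2)$shelf))), 0L)

    ## empty island list: everything extra-sSISs
    ann0 <- buildSsissLayers(isl[0])
    expect_true(all(lengths(cpgLayers(ann0)) == 0))
    call0 <- classifyRegions(GRanges("chr1", IRanges(1, 100)),
                             combineAnnotation(buildIntragenicLayers(
                                 mkGene("chr1", "+", 10001L)[0]), ann0))
    expect_identical(call0$cpg_class, "extra_sSISs")
    expect_identical(call0$cpg_subclass, "none")

    ## idempotence: rebuilding from the constructed island layer
    ann3 <- buildSsissLayers(cpgLayers(ann2)$island)
    expect_identical(cpgLayers(ann3)$shore, cpgLayers(ann2)$shore)
    expect_identical(cpgLayers(ann3)$shelf, cpgLayers(ann2)$shelf)
})

test_that("region classification uses largest overlap with fixed ties", {
    g <- mkGene("chr1", "+", 10001L)
    isl <- GRanges("chr1", IRanges(9501, 10500),
                   seqinfo = Seqinfo("chr1", 100000L))
    ann <- combineAnnotation(buildIntragenicLayers(g),
                             buildSsissLayers(isl))

    ## region inside regulatory only
    r1 <- classifyRegions(GRanges("chr1", IRanges(5501, 5700)), ann)
    expect_identical(r1$genic_class, "intragenic")
    expect_identical(r1$genic_subclass, "regulatory")

    ## 150 bp of gene body vs 50 bp of 3'UTR: body wins by overlap length
    r2 <- classifyRegions(GRanges("chr1", IRanges(12051, 12250)), ann)
    expect_identical(r2$genic_subclass, "gene_body")

    ## region overlapping nothing
    r3 <- classifyRegions(GRanges("chr1", IRanges(50001, 50100)), ann)
    expect_identical(unlist(r3, use.names = FALSE),
                     c("extragenic", "none", "extra_sSISs", "none"))

    ## invariant to the storage order of annotation intervals
    islA <- GRanges("chr1", IRanges(c(9501, 30001), c(10500, 31000)),
                    seqinfo = Seqinfo("chr1", 100000L))
    regions <- GRanges("chr1", IRanges(c(9601, 12051, 29901, 50001),
                                       c(9800, 12250, 30100, 50100)))
    expect_identical(
        classifyRegions(regions, combineAnnotation(
            buildIntragenicLayers(g), buildSsissLayers(islA))),
        classifyRegions(regions, combineAnnotation(
            buildIntragenicLayers(g), buildSsissLayers(rev(islA)))))
})

test_that("class and subclass counts partition any region set", {
    fx <- tinyExperiment()
    ann <- combineAnnotation(buildIntragenicLayers(genes(fx$genome)),
                             buildSsissLayers(islands(fx$genome)))
    set.seed(61)
    regions <- GRanges("chr1",
                       IRanges(sample.int(115000, 200), width = 500),
                       seqinfo = Seqinfo("chr1", 120000L))
    cls <- classifyRegions(regions, ann)
    expect_identical(sum(cls$genic_class == "intragenic") +
                     sum(cls$genic_class == "extragenic"), 200L)
    expect_identical(sum(cls$genic_subclass != "none"),
                     sum(cls$genic_class == "intragenic"))
    expect_identical(sum(cls$cpg_subclass != "none"),
                     sum(cls$cpg_class == "sSISs"))
    expect_true(all(cls$genic_subclass %in%
                    c("regulatory", "gene_body", "utr3", "none")))
    expect_true(all(cls$cpg_subclass %in%
                    c("island", "shore", "shelf", "none")))
})

test_that("O:E CpG ratio matches hand-derived values", {
    expect_identical(oeCpGRatio(strrep("CG", 100)), 2)
    expect_identical(oeCpGRatio(strrep("ACGT", 50)), 4)
    expect_identical(oeCpGRatio(strrep("A", 200)), 0)
    expect_error(oeCpGRatio(""), "empty")
    ## N counts toward length but not composition
    withN <- paste0(strrep("CG", 50), strrep("N", 100))
    expect_identical(oeCpGRatio(withN), 50 / (50 * 50 / 200))
})

test_that("CpG density classes follow the stated thresholds", {
    expect_identical(capDMR:::.densityClass(c(0.29, 0.30, 0.59, 0.60)),
                     c("low", "intermediate", "intermediate", "high"))

    ## a genome with one CG-rich tract: its CpGs class high
    tract <- paste0(strrep("AT", 500), strrep("CG", 100), strrep("AT", 500))
    seqs <- DNAStringSet(c(chr1 = tract))
    gm <- new("GenomeModel", sequences = seqs,
              islands = GRanges(), genes = GRanges())
    dens <- classifyCpGDensity(gm, window = 200L)
    mid <- start(dens) > 1050 & start(dens) <= 1150
    expect_true(all(mcols(dens)$density_class[mid] == "high"))
    ## the one CpG whose window lies fully inside the tract scores exactly 2
    expect_equal(mcols(dens)$oe_ratio[start(dens) == 1101], 2)

    ## clipping at the chromosome edge still yields a defined class
    edgeSeq <- DNAStringSet(c(chr1 = paste0("ACG", strrep("AT", 200))))
    gmE <- new("GenomeModel", sequences = edgeSeq,
               islands = GRanges(), genes = GRanges())
    densE <- classifyCpGDensity(gmE, window = 200L)
    expect_identical(length(densE), 1L)
    expect_false(is.na(mcols(densE)$oe_ratio))
})
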
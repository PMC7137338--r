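## End-to-end orchestration: simulate -> count -> test -> annotate ->
## compare, with YAML configuration, provenance manifest and per-stage
## telemetry.

#' Default pipeline configuration
#'
#' Returns the full configuration tree with the analysis defaults: 200-bp
#' windows every 10 bp, fragment extension to 200 bp, minimum count sum
#' 30, average logCPM floor -1, sex chromosomes excluded, 50-bp merge gap,
#' region FDR 0.05, 5-kb upstream regulatory extent, 2-kb shores and
#' shelves, O:E density thresholds 0.3 / 0.6 and classification alpha
#' 0.05.  Every key can be overridden from a YAML file read with
#' \code{\link{readPipelineConfig}}.
#'
#' @return A named nested list.
#' @export
defaultPipelineConfig <- function() {
    list(
        seed = 1L,
        simulate = list(
            enabled = TRUE,
            chrom_lengths = c(chr1 = 500000L),
            n_genes = 30L,
            island_length = 1000L,
            samples_per_group = c(normal = 3L, primary = 3L, metastasis = 3L),
            library_size = 600000,
            frag_length_mean = 200,
            frag_length_sd = 20,
            capture_affinity = 0.1,
            nb_dispersion = 0.05,
            bis_coverage = 30,
            bb_dispersion = 0.02,
            level_jitter_sd = 0.02,
            tumor_drift_sd = 0,
            island_level_range = c(0.05, 0.10),
            opensea_level_range = c(0.75, 0.85),
            n_hyper = 20L,
            hyper_delta = 0.5,
            hyper_affected = c("primary", "metastasis"),
            n_hypo = 20L,
            hypo_delta = -0.2,
            hypo_affected = "metastasis",
            hypo_width_range = c(200L, 400L),
            bisulfite = FALSE),
        inputs = list(
            genome_fasta = NULL,
            islands_bed = NULL,
            genes_tsv = NULL,
            sample_sheet = NULL),
        count = list(width = 200L, step = 10L, fragment_extension = 200L),
        filter = list(min_count_sum = 30, min_avg_logcpm = -1,
                      excluded_chroms = c("X", "Y")),
        normalize = list(method = "tmm", bin_width = 2000L),
        test = list(contrasts = list(c("primary", "normal"),
                                     c("metastasis", "normal"),
                                     c("metastasis", "primary")),
                    fdr = 0.05, max_gap = 50L, prior_df = 10),
        annotate = list(upstream = 5000L, shore_width = 2000L,
                        shelf_width = 2000L, density_window = 200L,
                        density_low = 0.3, density_high = 0.6),
        compare = list(enabled = FALSE, alpha = 0.05,
                       use_adjusted_p = FALSE,
                       contrast = c("primary", "normal")))
}

## recursive unknown-key validation against the default tree
.checkConfigKeys <- function(cfg, ref, prefix = "") {
    if (!is.list(cfg)) return(invisible())
    unknown <- setdiff(names(cfg), names(ref))
    if (length(unknown))
        stop("unknown configuration key(s): ",
             paste0(prefix, unknown, collapse = ", "))
    for (k in names(cfg))
        if (is.list(ref[[k]]) && !is.null(names(ref[[k]])))
            .checkConfigKeys(cfg[[k]], ref[[k]], paste0(prefix, k, "/"))
    invisible()
}

## overlay user values onto the defaults, preserving structure
.mergeConfig <- function(user, ref) {
    for (k in names(user)) {
        if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) && is.list(user[[k]]))
            ref[[k]] <- .mergeConfig(user[[k]], ref[[k]])
        else
            ref[[k]] <- user[[k]]
    }
    ref
}

#' Read and validate a pipeline configuration
#'
#' Reads a YAML file, rejects unknown keys (naming them) and overlays the
#' values on \code{\link{defaultPipelineConfig}}.
#'
#' @param path YAML file; \code{NULL} returns the defaults.
#' @return The merged configuration list.
#' @export
readPipelineConfig <- function(path = NULL) {
    ref <- defaultPipelineConfig()
    if (is.null(path)) return(ref)
    user <- yaml::read_yaml(path)
    .checkConfigKeys(user, ref)
    cfg <- .mergeConfig(user, ref)
    ## YAML maps come back as lists; coerce the vectors the stages expect
    for (k in c("chrom_lengths", "samples_per_group"))
        cfg$simulate[[k]] <- unlist(cfg$simulate[[k]])
    cfg$test$contrasts <- lapply(cfg$test$contrasts, unlist)
    cfg
}

.simConfigFromPipeline <- function(cfg) {
    s <- cfg$simulate
    simConfig(chromLengths = s$chrom_lengths, nGenes = s$n_genes,
              islandLength = s$island_length,
              samplesPerGroup = s$samples_per_group,
              librarySize = s$library_size,
              fragLengthMean = s$frag_length_mean,
              fragLengthSd = s$frag_length_sd,
              captureAffinity = s$capture_affinity,
              nbDispersion = s$nb_dispersion,
              bisCoverage = s$bis_coverage,
              bbDispersion = s$bb_dispersion,
              levelJitterSd = s$level_jitter_sd,
              tumorDriftSd = s$tumor_drift_sd,
              islandLevelRange = s$island_level_range,
              openseaLevelRange = s$opensea_level_range,
              seed = cfg$seed)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (simulate or load inputs, count,
#' test every configured contrast, annotate, optionally compare platforms),
#' writing each stage's outputs into \code{outputDir} and recording a run
#' manifest (parameter snapshot, per-file md5 hashes, package version,
#' timestamps).  Re-running with the same configuration reproduces
#' identical output hashes.
#'
#' @param config a configuration list from
#'   \code{\link{readPipelineConfig}} / \code{\link{defaultPipelineConfig}},
#'   or a path to a YAML file.
#' @param outputDir output directory (created if needed).
#' @param verbose print per-stage record counts?
#' @return Invisibly, a list with the in-memory stage results
#'   (\code{sim}, \code{windows}, \code{dmrs}, \code{annotation},
#'   \code{annotated}, \code{concordance}) and the \code{manifest}.
#' @export
runPipeline <- function(config = defaultPipelineConfig(),
                        outputDir = tempfile("capdmr_"), verbose = TRUE) {
    if (is.character(config)) config <- readPipelineConfig(config)
    .checkConfigKeys(config, defaultPipelineConfig())
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    say <- function(...) if (verbose) message(...)
    manifest <- list(version = as.character(packageVersion("capDMR")),
                     started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                     parameters = config, stages = list())
    addStage <- function(name, info, paths) {
        manifest$stages[[name]] <<- c(
            info, list(files = as.list(setNames(unname(md5sum(paths)),
                                                basename(paths)))))
    }

    ## -- stage: simulate or load --------------------------------------
    if (isTRUE(config$simulate$enabled)) {
        sc <- .simConfigFromPipeline(config)
        genome <- simulateGenome(sc)
        planted <- autoPlantDmrs(
            genome,
            nHyper = config$simulate$n_hyper,
            nHypo = config$simulate$n_hypo,
            hyperDelta = config$simulate$hyper_delta,
            hypoDelta = config$simulate$hypo_delta,
            hyperAffected = config$simulate$hyper_affected,
            hypoAffected = config$simulate$hypo_affected,
            hypoWidthRange = config$simulate$hypo_width_range,
            shoreWidth = config$annotate$shore_width,
            shelfWidth = config$annotate$shelf_width,
            seed = config$seed)
        sim <- simulateExperiment(sc, planted,
                                  bisulfite = isTRUE(config$simulate$bisulfite),
                                  genome = genome)
        fa <- file.path(outputDir, "genome.fa")
        writeGenomeFasta(genome, fa)
        islBed <- file.path(outputDir, "islands.bed")
        writeBed(islands(genome), islBed)
        genesTsv <- file.path(outputDir, "genes.tsv")
        writeGeneTable(genes(genome), genesTsv)
        truthTsv <- file.path(outputDir, "truth.tsv")
        writeTruthTsv(planted, truthTsv)
        fragPaths <- vapply(names(sim$fragments), function(nm) {
            p <- file.path(outputDir, paste0("fragments_", nm, ".bed"))
            writeBed(sim$fragments[[nm]], p)
            p
        }, character(1))
        addStage("simulate",
                 list(n_genes = length(genes(genome)),
                      n_planted = length(planted),
                      n_samples = nrow(sim$sampleSheet)),
                 c(fa, islBed, genesTsv, truthTsv, fragPaths))
        say("simulate: ", length(planted), " planted DMR(s), ",
            nrow(sim$sampleSheet), " samples")
    } else {
        inp <- config$inputs
        if (is.null(inp$sample_sheet) || is.null(inp$genome_fasta))
            stop("simulate stage disabled and no input files configured")
        seqs <- readDNAStringSet(inp$genome_fasta)
        names(seqs) <- sub("\\s.*", "", names(seqs))
        sheet <- readSampleSheet(inp$sample_sheet)
        sl <- setNames(width(seqs), names(seqs))
        frags <- GRangesList(lapply(sheet$path, readBed, seqlens = sl))
        names(frags) <- sheet$sample
        genome <- new("GenomeModel", sequences = seqs,
                      islands = if (!is.null(inp$islands_bed))
                          readBed(inp$islands_bed, sl)
                      else GRanges(),
                      genes = if (!is.null(inp$genes_tsv))
                          readGeneTable(inp$genes_tsv, sl)
                      else GRanges())
        sim <- list(genome = genome, fragments = frags, sampleSheet = sheet,
                    profile = NULL, bisulfite = NULL, truth = GRanges())
        addStage("load", list(n_samples = nrow(sheet)),
                 c(inp$genome_fasta, inp$sample_sheet))
    }

    ## -- stage: count --------------------------------------------------
    wc <- countWindows(sim$fragments, sim$sampleSheet$group,
                       seqlens = chromLengths(sim$genome),
                       width = config$count$width, step = config$count$step,
                       fragmentExtension = config$count$fragment_extension)
    if (ncol(wc) >= 2L && identical(config$normalize$method, "tmm"))
        wc <- estimateNormFactors(wc, binWidth = config$normalize$bin_width)
    say("count: ", nrow(wc), " windows x ", ncol(wc), " samples")

    ## -- stage: test (per contrast) -------------------------------------
    annot <- combineAnnotation(
        buildIntragenicLayers(genes(sim$genome),
                              upstream = config$annotate$upstream),
        buildSsissLayers(islands(sim$genome),
                         shoreWidth = config$annotate$shore_width,
                         shelfWidth = config$annotate$shelf_width))
    dmrs <- list()
    annotated <- list()
    for (ct in config$test$contrasts) {
        label <- paste0(ct[1], "_vs_", ct[2])
        regions <- callDmrs(wc, ct,
                            fdrCutoff = config$test$fdr,
                            maxGap = config$test$max_gap,
                            minCountSum = config$filter$min_count_sum,
                            minAvgLogCpm = config$filter$min_avg_logcpm,
                            excludedChroms = config$filter$excluded_chroms,
                            normalize = FALSE,
                            priorDf = config$test$prior_df)
        dmrs[[label]] <- regions
        bedPath <- file.path(outputDir, paste0("dmrs_", label, ".bed"))
        writeDmrBed(regions, bedPath)
        cls <- classifyRegions(regions, annot)
        annotated[[label]] <- cbind(
            data.frame(chrom = as.character(seqnames(regions)),
                       start = start(regions) - 1L, end = end(regions),
                       direction = mcols(regions)$direction,
                       significant = mcols(regions)$significant),
            cls)
        annPath <- file.path(outputDir, paste0("dmrs_", label,
                                               "_annotated.tsv"))
        write.table(annotated[[label]], annPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        addStage(paste0("test_", label),
                 list(n_regions = length(regions),
                      n_significant = sum(mcols(regions)$significant)),
                 c(bedPath, annPath))
        say("test ", label, ": ", length(regions), " regions, ",
            sum(mcols(regions)$significant), " significant")
    }

    ## -- stage: compare (optional) --------------------------------------
    concordance <- NULL
    if (isTRUE(config$compare$enabled)) {
        if (is.null(sim$bisulfite))
            stop("compare stage needs bisulfite data (simulate$bisulfite)")
        ct <- config$compare$contrast
        label <- paste0(ct[1], "_vs_", ct[2])
        if (is.null(dmrs[[label]]))
            stop("compare stage needs the ", label, " contrast to be tested")
        te <- betaRegressionPerCpG(sim$bisulfite, sim$sampleSheet$group, ct)
        sig <- dmrs[[label]]
        if (isTRUE(config$compare$use_adjusted_p))
            mcols(sig)$simes_p <- mcols(sig)$fdr
        prop <- propagateRegionStats(sig, granges(te))
        dens <- classifyCpGDensity(sim$genome,
                                   window = config$annotate$density_window,
                                   lowCut = config$annotate$density_low,
                                   highCut = config$annotate$density_high)
        dcls <- mcols(dens)$density_class[match(start(te), start(dens))]
        both <- mcols(prop)$mbde_covered
        calls <- classifyCpGCalls(mcols(te)$diff[both], mcols(te)$p[both],
                                  mcols(prop)$mbde_logFC[both],
                                  mcols(prop)$mbde_p[both],
                                  alpha = config$compare$alpha)
        concordance <- correlateMethods(mcols(prop)$mbde_logFC[both],
                                        mcols(te)$diff[both], dcls[both],
                                        calls$joint_class)
        concPath <- file.path(outputDir, "concordance_summary.tsv")
        write.table(concordance, concPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        addStage("compare", list(n_cpgs_both = sum(both)), concPath)
        say("compare: ", sum(both), " CpGs covered by both platforms")
    }

    manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    manPath <- file.path(outputDir, "manifest.json")
    jsonlite::write_json(manifest, manPath, auto_unbox = TRUE, pretty = TRUE,
                         null = "null")
    invisible(list(sim = sim, windows = wc, dmrs = dmrs,
                   annotation = annot, annotated = annotated,
                   concordance = concordance, manifest = manifest,
                   outputDir = outputDir))
}
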
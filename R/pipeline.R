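#' Default pipeline configuration
#'
#' A nested list mirroring the YAML config: a `simulate` section (any
#' [SimParams()] argument) or an `inputs` section with paths
#' (`counts_l1`, `counts_genes`, `samples`, `l1_bed`, `genes_gtf`, and
#' optionally `fragments_bedpe`, `signal_bedgraph`, `ir_table`), plus
#' stage thresholds.
#'
#' @return the default config list.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    simulate = list(),
    inputs = NULL,
    min_mean_l1 = 200, min_mean_genes = 200, min_length = 5000,
    subfamilies = c("L1HS", "L1PA*"),
    z_threshold = 3,
    min_mapq = 30,
    n_resamples = 1000L,
    n_random_pairings = 50L,
    flank = 5000L, body_bins = 60L, flank_bin_size = 50L,
    correlation_method = "pearson"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected early; missing keys take defaults from
#' [defaultPipelineConfig()].
#'
#' @param path YAML file path.
#' @return merged config list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- defaultPipelineConfig()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  cfg
}

#' Run the full analysis end to end
#'
#' Executes the stages in dependency order: simulate (or load) ->
#' normalize -> expressed-feature filters -> per-sample z scores -> net
#' upregulation -> genomic context -> overlap pairs -> anticorrelated
#' genes -> resampling enrichment -> fragment sharing -> signal
#' profiles -> L1/host correlations, writing each stage's table under
#' `outDir` together with a manifest (seed, parameters, package
#' version) and a markdown report. Every output is reproducible from
#' the config and seed.
#'
#' @param config config list ([defaultPipelineConfig()]) or a YAML path.
#' @param outDir output directory.
#' @return invisibly, a list with the main in-memory results.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir) {
  if (is.character(config)) config <- readPipelineConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$inputs)) {
    need <- c("counts_l1", "counts_genes", "samples", "l1_bed", "genes_gtf")
    missing <- setdiff(need, names(config$inputs))
    if (length(missing))
      stop("config inputs missing: ", paste(missing, collapse = ", "))
    for (p in unlist(config$inputs))
      if (!file.exists(p)) stop("input file not found: ", p)
    l1 <- readBed(config$inputs$l1_bed)
    genes <- readGtfGenes(config$inputs$genes_gtf)
    cntL1 <- readCountsTsv(config$inputs$counts_l1)
    cntG <- readCountsTsv(config$inputs$counts_genes)
    samples <- readSampleSheet(config$inputs$samples)
    fragments <- if (!is.null(config$inputs$fragments_bedpe))
      readBedpe(config$inputs$fragments_bedpe) else NULL
    track <- if (!is.null(config$inputs$signal_bedgraph))
      readBedgraph(config$inputs$signal_bedgraph) else NULL
    truth <- NULL
  } else {
    sp <- do.call(SimParams, c(list(seed = config$seed), config$simulate))
    ann <- simulateAnnotation(sp)
    genes <- ann$genes; l1 <- ann$l1
    sim <- simulateCounts(sp, genes, l1)
    cntL1 <- SummarizedExperiment::assay(sim$l1SE, "counts")
    cntG <- SummarizedExperiment::assay(sim$genesSE, "counts")
    samples <- sim$samples
    truth <- sim$truth
    upTrue <- l1[truth$feature_id[truth$feature_type == "l1"]]
    track <- simulateSignalTrack(upTrue, sp@chrom, sp@genomeLength,
                                 enrichLevel = 5, backgroundLevel = 1,
                                 noise = 0.5, seed = config$seed)
    fragments <- NULL
    writeSimulation(sim, genes, l1, file.path(outDir, "simulated"),
                    track = track)
  }

  # normalization + filters
  sfL1 <- sizeFactorsMoR(cntL1)
  sfG <- sizeFactorsMoR(cntG)
  normL1 <- normalizeCounts(cntL1, sfL1)
  normG <- normalizeCounts(cntG, sfG)
  subfam <- setNames(subfamilyOf(rownames(cntL1)), rownames(cntL1))
  lenL1 <- setNames(GenomicRanges::width(l1), names(l1))
  exprL1 <- selectExpressed(cntL1, minMean = config$min_mean_l1,
                            lengths = lenL1, minLength = config$min_length,
                            subfamilies = subfam,
                            whitelist = config$subfamilies)
  exprG <- selectExpressed(cntG, minMean = config$min_mean_genes)
  mdSummary <- milliDivSummary(l1, exprL1)

  # per-sample z scores and net scores
  ztL1 <- perSampleZ(normL1, samples, exprL1, zThreshold = config$z_threshold)
  ztG <- perSampleZ(normG, samples, exprG, zThreshold = config$z_threshold)
  net <- netUpregulated(ztL1)
  deCounts <- deGeneCounts(ztG)

  # genomic context, overlap pairs, anticorrelated genes
  ctx <- classifyContext(l1, genes)
  caseIds <- samples$sample_id[samples$group == "case"]
  pairs <- do.call(rbind, lapply(caseIds, function(s)
    deOverlapPairs(ztL1, ztG, l1, genes, s, config$z_threshold)))
  acBySample <- lapply(caseIds, function(s)
    anticorrelatedGenes(ztL1, ztG, l1, genes, s, config$z_threshold, ctx))
  names(acBySample) <- caseIds
  acGenes <- unique(unlist(acBySample))

  # enrichment of anticorrelated genes within labelled sets
  gid <- S4Vectors::mcols(genes)$gene_id
  annSets <- list(SFARI = gid[S4Vectors::mcols(genes)$labels == "SFARI"])
  universe <- intersect(featureIds(exprG), gid)
  enr <- NULL
  if (length(acGenes) && all(acGenes %in% universe))
    enr <- lapply(names(annSets), function(nm)
      resamplingEnrichment(acGenes, annSets[[nm]], universe,
                           n = config$n_resamples, seed = config$seed,
                           setName = nm))

  # fragment sharing (only when fragments are available)
  sharing <- NULL
  upIds <- rownames(SummarizedExperiment::assay(ztL1, "z"))[
    rowSums(SummarizedExperiment::assay(ztL1, "status") == "up") > 0]
  if (!is.null(fragments) && length(upIds))
    sharing <- sharingDistributions(genes, l1[upIds], fragments,
                                    nRandom = config$n_random_pairings,
                                    minMapq = config$min_mapq,
                                    seed = config$seed)

  # signal profiles over upregulated vs expressed loci
  profiles <- NULL
  if (!is.null(track)) {
    sets <- list(upregulated = l1[intersect(upIds, names(l1))],
                 expressed = l1[intersect(featureIds(exprL1), names(l1))])
    sets <- sets[lengths(sets) > 0]
    profiles <- lapply(sets, function(rg)
      meanProfile(profileMatrix(track, rg, flank = config$flank,
                                bodyBins = config$body_bins,
                                flankBinSize = config$flank_bin_size)))
  }

  # L1 / host-gene correlations
  corr <- l1HostCorrelation(normL1, normG, ctx,
                            method = config$correlation_method,
                            expressedL1 = exprL1)

  # serialize stage outputs
  writeCountsTsv(normL1, file.path(outDir, "norm_l1.tsv"))
  writeCountsTsv(normG, file.path(outDir, "norm_genes.tsv"))
  writeZScoreTable(ztL1, file.path(outDir, "zscores_l1.tsv"))
  writeZScoreTable(ztG, file.path(outDir, "zscores_genes.tsv"))
  data.table::fwrite(net, file.path(outDir, "net_upregulation.tsv"), sep = "\t")
  data.table::fwrite(ctx, file.path(outDir, "context_calls.tsv"), sep = "\t")
  data.table::fwrite(mdSummary, file.path(outDir, "millidiv_summary.tsv"),
                     sep = "\t")
  if (!is.null(pairs) && nrow(pairs))
    data.table::fwrite(pairs, file.path(outDir, "overlap_pairs.tsv"),
                       sep = "\t")
  data.table::fwrite(data.frame(gene_id = acGenes),
                     file.path(outDir, "anticorrelated_genes.tsv"), sep = "\t")
  if (!is.null(enr))
    data.table::fwrite(enrichmentTable(enr),
                       file.path(outDir, "enrichment.tsv"), sep = "\t")
  data.table::fwrite(corr$pairs, file.path(outDir, "correlations.tsv"),
                     sep = "\t")

  manifest <- list(package = "retroDE",
                   version = as.character(utils::packageVersion("retroDE")),
                   seed = config$seed, parameters = config[setdiff(
                     names(config), c("simulate", "inputs"))])
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))

  topNet <- net[order(-net$net), ][seq_len(min(5L, nrow(net))), ]
  report <- c(
    "# Locus-level L1 expression report", "",
    sprintf("- features: %d L1 loci (%d expressed), %d genes (%d expressed)",
            nrow(cntL1), length(featureIds(exprL1)), nrow(cntG),
            length(featureIds(exprG))),
    sprintf("- samples: %d controls, %d cases",
            sum(samples$group == "control"), sum(samples$group == "case")),
    sprintf("- expected |z|>%g false calls per sample (t reference): %.1f",
            config$z_threshold,
            2 * pt(-config$z_threshold, df = sum(samples$group == "control") - 1) *
              length(featureIds(exprL1))),
    "", "## Top net-upregulation samples", "",
    sprintf("- %s: net %d (%d up, %d down)", topNet$sample_id, topNet$net,
            topNet$n_up, topNet$n_down),
    "", sprintf("- upregulated-L1/DE-gene overlap pairs: %d",
                if (is.null(pairs)) 0L else nrow(pairs)),
    sprintf("- anticorrelated host genes: %d", length(acGenes)),
    sprintf("- fraction of L1/host pairs with r < 0: %s",
            ifelse(is.na(corr$fractionNegative), "NA",
                   sprintf("%.2f", corr$fractionNegative))))
  if (!is.null(truth)) {
    trueUp <- unique(truth$samples[truth$feature_type == "l1"])
    report <- c(report, "",
                sprintf("- simulated affected samples: %s",
                        paste(trueUp, collapse = ",")))
  }
  writeLines(report, file.path(outDir, "report.md"))

  invisible(list(l1 = l1, genes = genes, samples = samples,
                 expressedL1 = exprL1, expressedGenes = exprG,
                 ztL1 = ztL1, ztGenes = ztG, net = net, deCounts = deCounts,
                 context = ctx, pairs = pairs, anticorrelated = acBySample,
                 enrichment = enr, sharing = sharing, profiles = profiles,
                 correlation = corr, truth = truth, milliDiv = mdSummary))
}
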
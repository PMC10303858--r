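#' Simulate gene models and L1 loci on a synthetic genome
#'
#' Places `nGenes` non-overlapping multi-exon gene models along a single
#' linear chromosome, then places `nL1` L1 loci stratified into intronic,
#' exonic and intergenic contexts according to `l1ContextProps`. Exactly
#' `round(flFraction * nL1)` loci are full length (length > 5000 bp).
#' Subfamily labels follow the RepeatMasker naming (L1HS, L1PA2, ...,
#' plus older subfamilies); per-locus divergence from the subfamily
#' consensus (MilliDiv, mismatches per thousand) is drawn so that young
#' subfamilies have lower MilliDiv, and within a subfamily loci with a
#' higher latent expression propensity are less diverged. The propensity
#' is carried in `mcols()$propensity` and later scales baseline means in
#' [simulateCounts()], so expressed loci end up younger on average.
#'
#' @param params a [SimParams-class] object.
#' @return a list with elements `genes` (a `GRanges` of gene bodies with
#'   metadata columns `gene_id`, `gene_name`, `biotype`, `labels` and an
#'   `exons` `GRangesList` column) and `l1` (a `GRanges` of L1 loci named
#'   by locus id, with `subfamily`, `milliDiv`, `context` and
#'   `propensity` columns).
#' @examples
#' ann <- simulateAnnotation(SimParams(seed = 7, nGenes = 15, nL1 = 10,
#'                                     genomeLength = 2e6))
#' table(ann$l1$context)
#' @export
simulateAnnotation <- function(params) {
  stopifnot(is(params, "SimParams"))
  withSeed(params@seed, {
    chrom <- params@chrom
    nGenes <- params@nGenes
    nL1 <- params@nL1

    # gene skeletons: k exons of 150-400 bp separated by 8-20 kb introns,
    # so introns always have room for a full-length (~6 kb) L1
    nExons <- sample(2:5, nGenes, replace = TRUE)
    geneStarts <- geneEnds <- integer(nGenes)
    exStartAll <- exEndAll <- vector("list", nGenes)
    cursor <- 1L
    for (g in seq_len(nGenes)) {
      gap <- sample(5000:20000, 1L)
      cursor <- cursor + gap
      k <- nExons[g]
      exLen <- sample(150:400, k, replace = TRUE)
      inLen <- if (k > 1L) sample(8000:20000, k - 1L, replace = TRUE) else integer()
      starts <- cursor + cumsum(c(0L, exLen[-k] + inLen))
      exStartAll[[g]] <- starts
      exEndAll[[g]] <- starts + exLen - 1L
      geneStarts[g] <- cursor
      geneEnds[g] <- starts[k] + exLen[k] - 1L
      cursor <- geneEnds[g] + 1L
    }
    if (cursor + 5000 > params@genomeLength)
      stop(sprintf(paste0("genome length %g bp is too small to place %d genes ",
                          "without overlap (need >= %d bp); increase genomeLength"),
                   params@genomeLength, nGenes, cursor + 5000))

    genes <- grFrom(chrom, geneStarts, geneEnds)
    ids <- sprintf("g%04d", seq_len(nGenes))
    names(genes) <- ids
    S4Vectors::mcols(genes)$gene_id <- ids
    S4Vectors::mcols(genes)$gene_name <- sprintf("GENE%04d", seq_len(nGenes))
    S4Vectors::mcols(genes)$biotype <- "protein_coding"
    labels <- rep("", nGenes)
    labels[sample.int(nGenes, max(1L, nGenes %/% 8L))] <- "SFARI"
    S4Vectors::mcols(genes)$labels <- labels
    exonsFlat <- grFrom(chrom, unlist(exStartAll), unlist(exEndAll))
    exons <- IRanges::relist(exonsFlat,
      IRanges::PartitioningByWidth(nExons, names = ids))
    S4Vectors::mcols(genes)$exons <- exons

    l1 <- placeL1Loci(params, genes)
    list(genes = genes, l1 = l1)
  })
}

# Stratified placement of L1 loci into intronic / exonic / intergenic
# positions; called inside simulateAnnotation's seeded scope.
placeL1Loci <- function(params, genes) {
  chrom <- params@chrom
  nL1 <- params@nL1
  nFl <- round(params@flFraction * nL1)
  isFl <- sample(rep(c(TRUE, FALSE), c(nFl, nL1 - nFl)))
  len <- integer(nL1)
  len[isFl] <- sample(5500:6500, nFl, replace = TRUE)
  len[!isFl] <- sample(1000:4500, nL1 - nFl, replace = TRUE)

  ctxCounts <- round(params@l1ContextProps * nL1)
  while (sum(ctxCounts) > nL1) ctxCounts[which.max(ctxCounts)] <- ctxCounts[which.max(ctxCounts)] - 1L
  while (sum(ctxCounts) < nL1) ctxCounts[which.max(ctxCounts)] <- ctxCounts[which.max(ctxCounts)] + 1L
  context <- sample(rep(names(ctxCounts), ctxCounts))

  exonsAll <- unlist(S4Vectors::mcols(genes)$exons, use.names = FALSE)
  introns <- GenomicRanges::sort(GenomicRanges::setdiff(
    GenomicRanges::reduce(genes, ignore.strand = TRUE),
    GenomicRanges::reduce(exonsAll, ignore.strand = TRUE),
    ignore.strand = TRUE))
  gaps <- GenomicRanges::setdiff(
    grFrom(chrom, 1, params@genomeLength),
    GenomicRanges::reduce(genes, ignore.strand = TRUE), ignore.strand = TRUE)

  # placement bookkeeping on plain integer vectors (GRanges built once at
  # the end): occS/occE track already-placed loci
  intS <- GenomicRanges::start(introns); intE <- GenomicRanges::end(introns)
  gapS <- GenomicRanges::start(gaps); gapE <- GenomicRanges::end(gaps)
  exS <- GenomicRanges::start(exonsAll); exE <- GenomicRanges::end(exonsAll)
  occS <- occE <- integer()
  clashes <- function(s, e) any(occS <= e & occE >= s)
  starts <- integer(nL1)
  for (i in seq_len(nL1)) {
    placed <- FALSE
    if (context[i] == "exonic") {
      # start inside an exon, run into the following intron
      for (e in sample.int(length(exS), length(exS))) {
        s <- exE[e] - 49L
        if (s + len[i] - 1L <= params@genomeLength && !clashes(s, s + len[i] - 1L)) {
          starts[i] <- s; placed <- TRUE; break
        }
      }
      if (!placed) stop("genome too small: no exon-adjacent room left for an exonic L1")
    } else {
      poolS <- if (context[i] == "intronic") intS else gapS
      poolE <- if (context[i] == "intronic") intE else gapE
      ok <- which(poolE - poolS + 1L >= len[i] + 2L)
      for (attempt in seq_len(200L)) {
        if (!length(ok)) break
        j <- ok[sample.int(length(ok), 1L)]
        lo <- poolS[j] + 1L
        hi <- poolE[j] - len[i]
        s <- if (hi > lo) sample(lo:hi, 1L) else lo
        if (!clashes(s, s + len[i] - 1L)) {
          starts[i] <- s; placed <- TRUE; break
        }
      }
      if (!placed)
        stop(sprintf("genome too small: could not place a %s L1 of %d bp without overlap",
                     context[i], len[i]))
    }
    occS <- c(occS, starts[i]); occE <- c(occE, starts[i] + len[i] - 1L)
  }

  young <- c("L1HS", paste0("L1PA", 2:8))
  old <- c("L1PA13", "L1MA4", "L1ME1")
  subfam <- character(nL1)
  subfam[isFl] <- sample(young, nFl, replace = TRUE)
  subfam[!isFl] <- sample(c(young, old, old), nL1 - nFl, replace = TRUE)
  age <- rep(30, nL1)
  age[subfam == "L1HS"] <- 1
  isPA <- grepl("^L1PA[0-9]+$", subfam)
  age[isPA] <- as.numeric(sub("L1PA", "", subfam[isPA]))
  propensity <- runif(nL1)
  milliDiv <- round(pmax(0, age * 8 * (1.3 - 0.6 * propensity) + rnorm(nL1, 0, 2)), 1)

  l1 <- grFrom(chrom, starts, starts + len - 1L,
               strand = sample(c("+", "-"), nL1, replace = TRUE))
  names(l1) <- sprintf("%s:L1:LINE:%03d", subfam, seq_len(nL1))
  S4Vectors::mcols(l1)$subfamily <- subfam
  S4Vectors::mcols(l1)$milliDiv <- milliDiv
  S4Vectors::mcols(l1)$context <- context
  S4Vectors::mcols(l1)$propensity <- propensity
  l1
}

#' Simulate negative-binomial count matrices with injected effects
#'
#' Draws raw counts for genes and L1 loci as
#' NB(mean = baseMean * sizeFactor * fold, variance = mu + alpha * mu^2).
#' In the affected case samples, a fixed subset of intronic full-length
#' L1 loci has its mean multiplied by `l1Fold`, `geneDeCount` genes are
#' perturbed (half up by `geneFold`, half down by `1/geneFold`), and for
#' each of `anticorrPairs` L1/host-gene couplings the host gene's mean is
#' divided by `anticorrFactor` wherever its L1 is upregulated. The loci
#' chosen for upregulation are guaranteed to sit above the expressed-
#' feature threshold (baseline mean >= 400) so the injected signal lives
#' in the analysis universe, mirroring how upregulation is only ever
#' observable among expressed loci.
#'
#' @param params a [SimParams-class] object.
#' @param genes,l1 annotation from [simulateAnnotation()].
#' @return a list with elements:
#'   \describe{
#'     \item{genesSE,l1SE}{`SummarizedExperiment`s with a `counts` assay,
#'       `rowRanges` from the annotation and the sample sheet as
#'       `colData`.}
#'     \item{samples}{data.frame with `sample_id`, `group`, `dataset`.}
#'     \item{truth}{data.frame of injected effects: `feature_id`,
#'       `feature_type`, `effect`, `factor`, `samples` (comma-separated
#'       sample ids), plus `partner` for anticorrelation couplings.}
#'   }
#' @export
simulateCounts <- function(params, genes, l1) {
  stopifnot(is(params, "SimParams"))
  if (any(params@sizeFactorRange <= 0))
    stop("size_factor_range must exclude 0: size factors are positive scales")
  withSeed(params@seed + 1L, {
    nS <- params@nControls + params@nCases
    sampleId <- c(sprintf("ctrl_%02d", seq_len(params@nControls)),
                  sprintf("case_%02d", seq_len(params@nCases)))
    group <- rep(c("control", "case"), c(params@nControls, params@nCases))
    samples <- data.frame(sample_id = sampleId, group = group,
                          dataset = "simulated", stringsAsFactors = FALSE)
    affected <- sampleId[params@nControls + params@affectedCases]
    sf <- runif(nS, params@sizeFactorRange[1], params@sizeFactorRange[2])

    # baseline means; L1 means scaled by latent propensity so that
    # low-propensity loci fall below the expressed threshold
    muG <- runif(params@nGenes, params@baseMeanRange[1], params@baseMeanRange[2])
    muL <- runif(params@nL1, params@baseMeanRange[1], params@baseMeanRange[2]) *
      (0.25 + 1.5 * S4Vectors::mcols(l1)$propensity)

    fl <- GenomicRanges::width(l1) > 5000
    intronicFl <- which(S4Vectors::mcols(l1)$context == "intronic" & fl)
    nUp <- ceiling(params@l1UpFraction * length(intronicFl))
    upIdx <- if (nUp > 0) sort(sample(intronicFl, nUp)) else integer()
    muL[upIdx] <- pmax(muL[upIdx], 400)

    foldL <- matrix(1, params@nL1, nS,
                    dimnames = list(names(l1), sampleId))
    foldL[upIdx, affected] <- params@l1Fold

    # host genes of anticorrelated pairs; remaining DE genes drawn apart
    ctx <- classifyContext(l1, genes)
    hosts <- ctx$host_gene[match(names(l1)[upIdx], ctx$l1_id)]
    pairIdx <- which(!is.na(hosts))
    pairIdx <- head(pairIdx, params@anticorrPairs)
    acL1 <- names(l1)[upIdx][pairIdx]
    acGene <- hosts[pairIdx]

    foldG <- matrix(1, params@nGenes, nS,
                    dimnames = list(names(genes), sampleId))
    foldG[acGene, affected] <- 1 / params@anticorrFactor
    dePool <- setdiff(names(genes), acGene)
    nDe <- min(params@geneDeCount, length(dePool))
    deGenes <- sort(sample(dePool, nDe))
    deUp <- deGenes[seq_len(nDe %/% 2)]
    deDown <- setdiff(deGenes, deUp)
    foldG[deUp, affected] <- params@geneFold
    foldG[deDown, affected] <- 1 / params@geneFold

    drawNB <- function(mu, disp) {
      n <- length(mu)
      if (disp == 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / disp)
    }
    muMatG <- outer(muG, sf) * foldG
    muMatL <- outer(muL, sf) * foldL
    cntG <- matrix(drawNB(muMatG, params@nbDispersion), nrow = params@nGenes,
                   dimnames = dimnames(foldG))
    cntL <- matrix(drawNB(muMatL, params@nbDispersion), nrow = params@nL1,
                   dimnames = dimnames(foldL))

    colData <- S4Vectors::DataFrame(samples, row.names = sampleId)
    genesSE <- SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = cntG), rowRanges = genes, colData = colData)
    l1SE <- SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = cntL), rowRanges = l1, colData = colData)

    truth <- rbind(
      if (length(upIdx))
        data.frame(feature_id = names(l1)[upIdx], feature_type = "l1",
                   effect = "up", factor = params@l1Fold,
                   samples = paste(affected, collapse = ","),
                   partner = NA_character_, stringsAsFactors = FALSE),
      if (length(deUp))
        data.frame(feature_id = deUp, feature_type = "gene", effect = "up",
                   factor = params@geneFold,
                   samples = paste(affected, collapse = ","),
                   partner = NA_character_, stringsAsFactors = FALSE),
      if (length(deDown))
        data.frame(feature_id = deDown, feature_type = "gene", effect = "down",
                   factor = 1 / params@geneFold,
                   samples = paste(affected, collapse = ","),
                   partner = NA_character_, stringsAsFactors = FALSE),
      if (length(acGene))
        data.frame(feature_id = acGene, feature_type = "gene",
                   effect = "anticorr_host", factor = 1 / params@anticorrFactor,
                   samples = paste(affected, collapse = ","),
                   partner = acL1, stringsAsFactors = FALSE))
    if (is.null(truth))
      truth <- data.frame(feature_id = character(), feature_type = character(),
                          effect = character(), factor = numeric(),
                          samples = character(), partner = character(),
                          stringsAsFactors = FALSE)
    list(genesSE = genesSE, l1SE = l1SE, samples = samples, truth = truth)
  })
}

#' Simulate a paired-end fragment table for a pair of loci
#'
#' Generates `nPairs` read pairs anchored on locus `A`. A fraction
#' `coSplicedFraction` of pairs is "co-spliced": one mate placed fully
#' inside `A` and the other fully inside `B`, emulating a transcript that
#' splices the two loci together. The remaining pairs have both mates
#' inside `A` (an independent transcriptional unit). Mapping qualities
#' are drawn uniformly from `mapqRange`, except that a fraction
#' `lowMapqFraction` of pairs gets mapq 20 (below the usual filter) and a
#' fraction `1 - properPairFraction` is flagged improper, to exercise the
#' upstream filters.
#'
#' @param A,B single-interval `GRanges` loci.
#' @param nPairs number of read pairs (>= 1).
#' @param coSplicedFraction fraction of pairs with one mate in each locus.
#' @param mapqRange integer range for mapping qualities.
#' @param lowMapqFraction fraction of pairs given mapq 20.
#' @param properPairFraction fraction of pairs flagged as proper.
#' @param readLength mate length in bp.
#' @param seed RNG seed.
#' @return a fragment table: data.frame with one row per pair
#'   (`read_id`, `chrom1`, `start1`, `end1`, `chrom2`, `start2`, `end2`,
#'   `strand1`, `strand2`, `mapq`, `proper_pair`), coordinates 1-based
#'   inclusive.
#' @export
simulateFragments <- function(A, B, nPairs, coSplicedFraction = 0,
                              mapqRange = c(30L, 60L), lowMapqFraction = 0,
                              properPairFraction = 1, readLength = 100L,
                              seed = 1L) {
  if (nPairs < 1) stop("nPairs must be >= 1")
  stopifnot(length(A) == 1L, length(B) == 1L)
  if (GenomicRanges::width(A) < readLength || GenomicRanges::width(B) < readLength)
    stop("loci must be at least one read length wide")
  withSeed(seed, {
    placeIn <- function(gr, n) {
      s <- GenomicRanges::start(gr) +
        floor(runif(n) * (GenomicRanges::width(gr) - readLength + 1))
      cbind(start = s, end = s + readLength - 1L)
    }
    split <- runif(nPairs) < coSplicedFraction
    m1 <- placeIn(A, nPairs)
    m2 <- placeIn(A, nPairs)
    if (any(split)) {
      mB <- placeIn(B, sum(split))
      m2[split, ] <- mB
    }
    mapq <- sample(seq(mapqRange[1], mapqRange[2]), nPairs, replace = TRUE)
    mapq[runif(nPairs) < lowMapqFraction] <- 20L
    proper <- runif(nPairs) < properPairFraction
    data.frame(read_id = sprintf("frag_%06d", seq_len(nPairs)),
               chrom1 = as.character(GenomicRanges::seqnames(A)),
               start1 = as.integer(m1[, "start"]), end1 = as.integer(m1[, "end"]),
               chrom2 = as.character(GenomicRanges::seqnames(B)),
               start2 = as.integer(m2[, "start"]), end2 = as.integer(m2[, "end"]),
               strand1 = "+", strand2 = "-",
               mapq = as.integer(mapq), proper_pair = proper,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a genome-wide signal track with enriched regions
#'
#' Produces a contiguous bedGraph-style track covering the whole
#' simulated chromosome: runs inside `regions` average `enrichLevel`,
#' runs elsewhere average `backgroundLevel`; with `noise > 0` the track
#' is tiled into `binWidth` bins carrying iid Gaussian noise (truncated
#' at 0). With `noise = 0` the values are exact, so profile means over
#' the regions equal `enrichLevel` exactly.
#'
#' @param regions `GRanges` of enriched regions (must lie inside the
#'   genome).
#' @param chrom chromosome name.
#' @param genomeLength chromosome length in bp.
#' @param enrichLevel,backgroundLevel non-negative signal levels.
#' @param noise Gaussian sd added per bin.
#' @param binWidth tile width used when `noise > 0`.
#' @param seed RNG seed.
#' @return a sorted `GRanges` with a `score` column covering
#'   `[1, genomeLength]` without overlap.
#' @export
simulateSignalTrack <- function(regions, chrom, genomeLength,
                                enrichLevel = 5, backgroundLevel = 1,
                                noise = 0, binWidth = 50L, seed = 1L) {
  assertScalarNumber(enrichLevel, "enrichLevel", 0)
  assertScalarNumber(backgroundLevel, "backgroundLevel", 0)
  if (length(regions) &&
      (min(GenomicRanges::start(regions)) < 1 ||
       max(GenomicRanges::end(regions)) > genomeLength))
    stop("regions outside genome bounds")
  genome <- grFrom(chrom, 1, genomeLength)
  enriched <- GenomicRanges::reduce(regions, ignore.strand = TRUE)
  background <- GenomicRanges::setdiff(genome, enriched, ignore.strand = TRUE)
  runs <- c(enriched, background)
  level <- rep(c(enrichLevel, backgroundLevel),
               c(length(enriched), length(background)))
  o <- GenomicRanges::order(runs)
  runs <- runs[o]; level <- level[o]
  if (noise == 0) {
    S4Vectors::mcols(runs)$score <- level
    return(runs)
  }
  withSeed(seed, {
    tl <- GenomicRanges::tile(runs, width = pmin(binWidth, GenomicRanges::width(runs)))
    tiles <- unlist(tl)
    lev <- rep(level, lengths(tl))
    S4Vectors::mcols(tiles)$score <- pmax(0, lev + rnorm(length(tiles), 0, noise))
    GenomicRanges::sort(tiles)
  })
}

#' Write a simulated dataset bundle to disk
#'
#' Serializes everything the pipeline consumes: `genes.gtf`, `l1.bed`
#' (BED6 + subfamily, milliDiv, length), `counts_genes.tsv`,
#' `counts_l1.tsv`, `samples.tsv` and `truth.tsv`, plus optional
#' `fragments.bedpe` and `signal.bedgraph`.
#'
#' @param sim output of [simulateCounts()].
#' @param genes,l1 annotation from [simulateAnnotation()].
#' @param dir output directory (created if missing).
#' @param fragments optional fragment table from [simulateFragments()].
#' @param track optional signal track from [simulateSignalTrack()].
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, genes, l1, dir, fragments = NULL,
                            track = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeGtfGenes(genes, file.path(dir, "genes.gtf"))
  writeBed(l1, file.path(dir, "l1.bed"))
  writeCountsTsv(SummarizedExperiment::assay(sim$genesSE, "counts"),
                 file.path(dir, "counts_genes.tsv"))
  writeCountsTsv(SummarizedExperiment::assay(sim$l1SE, "counts"),
                 file.path(dir, "counts_l1.tsv"))
  writeSampleSheet(sim$samples, file.path(dir, "samples.tsv"))
  data.table::fwrite(sim$truth, file.path(dir, "truth.tsv"), sep = "\t")
  if (!is.null(fragments))
    writeBedpe(fragments, file.path(dir, "fragments.bedpe"))
  if (!is.null(track))
    writeBedgraph(track, file.path(dir, "signal.bedgraph"))
  invisible(dir)
}
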
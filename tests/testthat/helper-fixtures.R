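suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

# shorthand GRanges on one chromosome
gr <- function(start, end, chrom = "chr1", strand = "*", names = NULL) {
  g <- GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
  if (!is.null(names)) names(g) <- names
  g
}

# tiny two-gene annotation used by context/correlation tests:
#   gA [1000, 20000]: exons [1000,1200] and [19000,20000]
#   gB [30000, 52000]: exons [30000,30300], [40000,40200], [51000,52000]
tinyGenes <- function() {
  genes <- gr(c(1000, 30000), c(20000, 52000), names = c("gA", "gB"))
  mcols(genes)$gene_id <- c("gA", "gB")
  mcols(genes)$gene_name <- c("GENEA", "GENEB")
  mcols(genes)$biotype <- "protein_coding"
  mcols(genes)$labels <- c("SFARI", "")
  ex <- GRangesList(
    gA = gr(c(1000, 19000), c(1200, 20000)),
    gB = gr(c(30000, 40000, 51000), c(30300, 40200, 52000)))
  mcols(genes)$exons <- ex
  genes
}

# z-score table stub: wrap a z matrix (features x samples) as the
# SummarizedExperiment layout perSampleZ() produces
mkZT <- function(z, zThreshold = 3) {
  status <- matrix("ns", nrow(z), ncol(z), dimnames = dimnames(z))
  status[is.na(z)] <- "undefined"
  status[!is.na(z) & z > zThreshold] <- "up"
  status[!is.na(z) & z < -zThreshold] <- "down"
  SummarizedExperiment(assays = list(z = z, log2fc = z * 0, status = status))
}

# random non-degenerate interval set on [1, L]
randIntervals <- function(n, L, maxw = 500) {
  s <- sample.int(L - maxw, n, replace = TRUE)
  w <- sample.int(maxw, n, replace = TRUE)
  gr(s, pmin(s + w - 1L, L), names = sprintf("iv%03d", seq_len(n)))
}

# per-base membership oracle: logical coverage vector over [1, L]
bfCover <- function(g, L) {
  v <- logical(L)
  for (i in seq_along(g)) v[seq(start(g)[i], end(g)[i])] <- TRUE
  v
}

# per-base subtraction oracle returning a sorted merged GRanges
bfSubtract <- function(a, b, L, chrom = "chr1") {
  v <- bfCover(a, L) & !bfCover(b, L)
  r <- rle(v)
  e <- cumsum(r$lengths)
  s <- e - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(GRanges())
  gr(s[keep], e[keep], chrom = chrom)
}

# brute-force closest oracle with the package's tie rules
bfClosest <- function(query, features) {
  gapd <- function(i) {
    if (start(features)[i] <= end(query) && end(features)[i] >= start(query))
      return(0L)
    if (end(features)[i] < start(query)) start(query) - end(features)[i] - 1L
    else start(features)[i] - end(query) - 1L
  }
  d <- vapply(seq_along(features), gapd, 0L)
  cand <- which(d == min(d))
  cand <- cand[order(start(features)[cand], names(features)[cand])]
  list(id = names(features)[cand[1]], dist = min(d))
}

# brute-force shared-fragment statistic materializing id sets explicitly
bfSharedPct <- function(A, B, fragments, minMapq = 30) {
  f <- fragments[fragments$proper_pair & fragments$mapq >= minMapq, ]
  insideA <- function(s, e, chrom)
    chrom == as.character(seqnames(A)) & s >= start(A) & e <= end(A)
  touchB <- function(s, e, chrom)
    chrom == as.character(seqnames(B)) & s <= end(B) & e >= start(B)
  ids <- unique(f$read_id[insideA(f$start1, f$end1, f$chrom1) |
                            insideA(f$start2, f$end2, f$chrom2)])
  if (!length(ids)) return(list(total = 0L, shared = 0L, pct = NA_real_))
  g <- f[f$read_id %in% ids, ]
  shared <- unique(g$read_id[touchB(g$start1, g$end1, g$chrom1) |
                               touchB(g$start2, g$end2, g$chrom2)])
  list(total = 2L * length(ids), shared = length(shared),
       pct = 100 * length(shared) / (2 * length(ids)))
}

# small fast simulation parameter set for multi-seed property tests
smallSim <- function(seed, ...) {
  SimParams(seed = seed, nGenes = 30L, nL1 = 40L, genomeLength = 4e6, ...)
}

# calibration-sized simulation: a cohort-like L1 locus set (the source
# cohorts carried 100-175 expressed loci), so median-of-ratios size
# factors are estimated with realistic precision
calibSim <- function(seed, ...) {
  SimParams(seed = seed, nGenes = 40L, nL1 = 150L, genomeLength = 1.2e7, ...)
}

# run annotation -> counts -> normalization -> expressed filter -> L1 z
# table in one go, mirroring the pipeline's stage order (z scores are
# computed on the expressed full-length L1HS/L1PA universe)
simToZ <- function(params, filter = TRUE) {
  ann <- simulateAnnotation(params)
  sim <- simulateCounts(params, ann$genes, ann$l1)
  cnt <- assay(sim$l1SE, "counts")
  norm <- normalizeCounts(cnt, sizeFactorsMoR(cnt))
  expressed <- if (filter)
    selectExpressed(cnt, minMean = 200,
                    lengths = setNames(width(ann$l1), names(ann$l1)),
                    minLength = 5000,
                    subfamilies = setNames(ann$l1$subfamily, names(ann$l1)),
                    whitelist = c("L1HS", "L1PA*"))
  list(ann = ann, sim = sim, counts = cnt, norm = norm,
       expressed = expressed,
       zt = perSampleZ(norm, sim$samples, features = expressed))
}

# single-pair fragment record
oneFrag <- function(id, s1, e1, s2, e2, mapq = 60L, proper = TRUE) {
  data.frame(read_id = id, chrom1 = "chr1", start1 = s1, end1 = e1,
             chrom2 = "chr1", start2 = s2, end2 = e2,
             strand1 = "+", strand2 = "-", mapq = mapq, proper_pair = proper,
             stringsAsFactors = FALSE)
}
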
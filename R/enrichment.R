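#' Resampling enrichment of a gene set against an annotation set
#'
#' Compares the observed overlap between a target gene set and an
#' annotation set with the overlaps of `n` equally sized random sets
#' drawn uniformly without replacement from the expressed-gene universe.
#' The enrichment z is (observed - null mean) / null sd; an enrichment
#' is conventionally called at z > 3 (z > 5 for the stricter variant).
#' The exact hypergeometric upper tail is reported alongside as an
#' independent cross-check of the resampled null.
#'
#' @param target character vector of target genes (must be a subset of
#'   `universe`).
#' @param annotation character vector of annotation genes.
#' @param universe character vector: the expressed-gene universe used for
#'   the z scores.
#' @param n number of resamples (default 1000).
#' @param seed RNG seed.
#' @param setName label stored in the result.
#' @return an [EnrichmentResult-class].
#' @export
resamplingEnrichment <- function(target, annotation, universe, n = 1000L,
                                 seed = 1L, setName = "annotation") {
  target <- unique(target); universe <- unique(universe)
  if (length(target) > length(universe))
    stop("target larger than universe")
  if (!all(target %in% universe))
    stop("target must be a subset of the universe")
  m <- length(target)
  inAnn <- universe %in% annotation
  observed <- sum(target %in% annotation)
  nullCounts <- withSeed(seed, vapply(seq_len(n), function(i)
    sum(inAnn[sample.int(length(universe), m)]), 0L))
  nullMean <- mean(nullCounts)
  nullSd <- sd(nullCounts)
  degenerate <- !is.finite(nullSd) || nullSd == 0
  K <- sum(inAnn)
  new("EnrichmentResult", set = setName, observed = as.numeric(observed),
      nullMean = nullMean, nullSd = if (degenerate) 0 else nullSd,
      z = if (degenerate) NA_real_ else (observed - nullMean) / nullSd,
      n = as.integer(n), seed = as.integer(seed),
      pHyper = phyper(observed - 1, K, length(universe) - K, m,
                      lower.tail = FALSE),
      note = if (degenerate) "degenerate null (sd = 0)" else "")
}

#' Resampling enrichment of L1 loci within gene sets
#'
#' Interval-based variant: the observed statistic is the number of L1
#' loci overlapping any gene of the annotation set; the null swaps in
#' `n` equally sized random gene sets drawn from the universe and counts
#' overlaps the same way.
#'
#' @param l1 `GRanges` of L1 loci.
#' @param geneSets named list of character vectors of gene ids.
#' @param genes `GRanges` of gene bodies with a `gene_id` column.
#' @param universe gene ids to draw random sets from (defaults to all
#'   genes in `genes`).
#' @param n number of resamples.
#' @param seed RNG seed.
#' @return list of [EnrichmentResult-class], one per gene set.
#' @export
genomicL1Enrichment <- function(l1, geneSets, genes,
                                universe = S4Vectors::mcols(genes)$gene_id,
                                n = 1000L, seed = 1L) {
  gid <- S4Vectors::mcols(genes)$gene_id
  universe <- unique(universe)
  stopifnot(all(universe %in% gid))
  # per-gene list of overlapping L1 indices, computed once
  hits <- GenomicRanges::findOverlaps(genes, l1, ignore.strand = TRUE)
  byGene <- S4Vectors::splitAsList(S4Vectors::subjectHits(hits),
    factor(gid[S4Vectors::queryHits(hits)], levels = universe))
  countFor <- function(geneIds) {
    idx <- unlist(byGene[geneIds], use.names = FALSE)
    length(unique(idx))
  }
  res <- lapply(names(geneSets), function(nm) {
    setGenes <- intersect(unique(geneSets[[nm]]), universe)
    m <- length(setGenes)
    if (m > length(universe)) stop("gene set larger than universe")
    observed <- countFor(setGenes)
    nullCounts <- withSeed(seed, vapply(seq_len(n), function(i)
      countFor(universe[sample.int(length(universe), m)]), 0L))
    nullSd <- sd(nullCounts)
    degenerate <- !is.finite(nullSd) || nullSd == 0
    new("EnrichmentResult", set = nm, observed = as.numeric(observed),
        nullMean = mean(nullCounts),
        nullSd = if (degenerate) 0 else nullSd,
        z = if (degenerate) NA_real_
            else (observed - mean(nullCounts)) / nullSd,
        n = as.integer(n), seed = as.integer(seed), pHyper = NA_real_,
        note = if (degenerate) "degenerate null (sd = 0)" else "")
  })
  names(res) <- names(geneSets)
  res
}
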
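# Introns of a gene-model GRanges: per-gene body minus its exons,
# returned flat with a gene_id metadata column.
geneIntrons <- function(genes) {
  body <- GenomicRanges::granges(unname(genes))
  GenomicRanges::strand(body) <- "*"
  ex <- unname(S4Vectors::mcols(genes)$exons)
  exFlat <- unlist(ex, use.names = FALSE)
  GenomicRanges::strand(exFlat) <- "*"
  ex <- IRanges::relist(exFlat, ex)
  perGene <- GenomicRanges::psetdiff(body, ex)
  out <- unlist(perGene, use.names = FALSE)
  S4Vectors::mcols(out)$gene_id <-
    rep(S4Vectors::mcols(genes)$gene_id, lengths(perGene))
  out
}

#' All introns of a gene annotation
#'
#' @param genes gene-model `GRanges` (with an `exons` column).
#' @return `GRanges` of introns with a `gene_id` metadata column.
#' @export
intronsOf <- function(genes) geneIntrons(genes)

#' Classify L1 loci by genomic context
#'
#' Each locus gets exactly one context: `exonic` when it overlaps an
#' exon by at least 1 bp (exon contact takes precedence), else
#' `intronic` when it overlaps an intron, else `intergenic`. Genic loci
#' are assigned a host gene: the gene with the largest body overlap,
#' ties broken by smaller gene start. Overlaps are strand-blind.
#'
#' @param l1 `GRanges` of L1 loci (named).
#' @param genes gene-model `GRanges`.
#' @param exonPrecedence when `FALSE`, intron contact wins over exon
#'   contact instead.
#' @return data.frame with `l1_id`, `context`, `host_gene` (`NA` for
#'   intergenic loci).
#' @export
classifyContext <- function(l1, genes, exonPrecedence = TRUE) {
  exonsAll <- unlist(S4Vectors::mcols(genes)$exons, use.names = FALSE)
  introns <- geneIntrons(genes)
  exHit <- IRanges::overlapsAny(l1, exonsAll, ignore.strand = TRUE)
  inHit <- IRanges::overlapsAny(l1, introns, ignore.strand = TRUE)
  context <- ifelse(if (exonPrecedence) exHit else exHit & !inHit, "exonic",
             ifelse(inHit, "intronic", "intergenic"))

  host <- rep(NA_character_, length(l1))
  genic <- which(context != "intergenic")
  if (length(genic)) {
    hits <- GenomicRanges::findOverlaps(l1[genic], genes, ignore.strand = TRUE)
    if (length(hits)) {
      ov <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::granges(l1[genic])[S4Vectors::queryHits(hits)],
        GenomicRanges::granges(genes)[S4Vectors::subjectHits(hits)]))
      df <- data.frame(q = S4Vectors::queryHits(hits),
                       g = S4Vectors::subjectHits(hits), ov = ov,
                       gstart = GenomicRanges::start(genes)[S4Vectors::subjectHits(hits)])
      df <- df[order(df$q, -df$ov, df$gstart), ]
      df <- df[!duplicated(df$q), ]
      host[genic[df$q]] <- S4Vectors::mcols(genes)$gene_id[df$g]
    }
  }
  data.frame(l1_id = names(l1), context = context, host_gene = host,
             stringsAsFactors = FALSE)
}

#' Upregulated-L1 / DE-gene overlap pairs for one sample
#'
#' Reconstructs the per-sample overlap classification: every pair where
#' an upregulated L1 (z > threshold) overlaps (>= 1 bp, any overlap) the
#' body of a differentially expressed gene (|z| > threshold), with the
#' gene's direction taken from the sign of its z.
#'
#' @param ztL1,ztGenes z-score tables from [perSampleZ()] for L1 loci and
#'   genes.
#' @param l1 `GRanges` of L1 loci.
#' @param genes gene-model `GRanges`.
#' @param sample sample id present in both tables.
#' @param zThreshold DE threshold (strict inequalities).
#' @return data.frame with `l1_chrom`, `l1_start`, `l1_end` (0-based
#'   half-open, the interval currency of the serialized tables),
#'   `l1_id`, `gene_name`, `gene_direction`
#'   (`Upregulated`/`Downregulated`), `sample_id`, `l1_z`, `gene_z`.
#' @export
deOverlapPairs <- function(ztL1, ztGenes, l1, genes, sample, zThreshold = 3) {
  zl <- SummarizedExperiment::assay(ztL1, "z")[, sample]
  zg <- SummarizedExperiment::assay(ztGenes, "z")[, sample]
  upL1 <- names(zl)[!is.na(zl) & zl > zThreshold]
  deG <- names(zg)[!is.na(zg) & abs(zg) > zThreshold]
  upL1 <- intersect(upL1, names(l1))
  deG <- intersect(deG, S4Vectors::mcols(genes)$gene_id)
  empty <- data.frame(l1_chrom = character(), l1_start = integer(),
                      l1_end = integer(), l1_id = character(),
                      gene_name = character(), gene_direction = character(),
                      sample_id = character(), l1_z = numeric(),
                      gene_z = numeric(), stringsAsFactors = FALSE)
  if (!length(upL1) || !length(deG)) return(empty)
  lsel <- l1[upL1]
  gsel <- genes[match(deG, S4Vectors::mcols(genes)$gene_id)]
  hits <- GenomicRanges::findOverlaps(lsel, gsel, ignore.strand = TRUE)
  if (!length(hits)) return(empty)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  gid <- S4Vectors::mcols(gsel)$gene_id[si]
  data.frame(
    l1_chrom = as.character(GenomicRanges::seqnames(lsel))[qi],
    l1_start = GenomicRanges::start(lsel)[qi] - 1L,
    l1_end = GenomicRanges::end(lsel)[qi],
    l1_id = names(lsel)[qi],
    gene_name = S4Vectors::mcols(gsel)$gene_name[si],
    gene_direction = ifelse(zg[gid] > 0, "Upregulated", "Downregulated"),
    sample_id = sample,
    l1_z = unname(zl[names(lsel)[qi]]),
    gene_z = unname(zg[gid]),
    stringsAsFactors = FALSE)
}

#' Genes anticorrelated with an intronic upregulated L1
#'
#' The host-gene side of the L1/host relationship: all genes with a
#' negative z (no cutoff on magnitude) hosting an intronic L1 whose z
#' exceeds the threshold in the given sample.
#'
#' @inheritParams deOverlapPairs
#' @param contextCalls optional precomputed [classifyContext()] result.
#' @return character vector of gene ids.
#' @export
anticorrelatedGenes <- function(ztL1, ztGenes, l1, genes, sample,
                                zThreshold = 3, contextCalls = NULL) {
  if (is.null(contextCalls)) contextCalls <- classifyContext(l1, genes)
  zl <- SummarizedExperiment::assay(ztL1, "z")[, sample]
  zg <- SummarizedExperiment::assay(ztGenes, "z")[, sample]
  upIntronic <- contextCalls$l1_id[contextCalls$context == "intronic" &
    !is.na(zl[contextCalls$l1_id]) & zl[contextCalls$l1_id] > zThreshold]
  hosts <- unique(contextCalls$host_gene[contextCalls$l1_id %in% upIntronic])
  hosts <- hosts[!is.na(hosts)]
  hosts[!is.na(zg[hosts]) & zg[hosts] < 0]
}

#' Overlap of expressed L1 loci with named reference interval sets
#'
#' Counts how many expressed loci overlap (>= 1 bp) each reference set
#' (e.g. L1Base2-style intactness classes); one locus may match several
#' sets.
#'
#' @param l1 `GRanges` of expressed L1 loci.
#' @param referenceSets named list of `GRanges`.
#' @return data.frame with `set`, `matched`, `total`, `fraction`.
#' @export
referenceSetOverlap <- function(l1, referenceSets) {
  do.call(rbind, lapply(names(referenceSets), function(nm) {
    hit <- IRanges::overlapsAny(l1, referenceSets[[nm]], ignore.strand = TRUE)
    data.frame(set = nm, matched = sum(hit), total = length(l1),
               fraction = if (length(l1)) sum(hit) / length(l1) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Percentage of L1 subsets overlapping expressed genes
#'
#' For each named subset (e.g. upregulated, expressed, all annotated),
#' the percentage of its loci overlapping (>= 1 bp) any expressed gene
#' body.
#'
#' @param l1Subsets named list of `GRanges`.
#' @param expressedGenes `GRanges` of expressed gene bodies.
#' @return data.frame with `subset`, `n`, `n_in_genes`, `pct`.
#' @export
fractionInExpressedGenes <- function(l1Subsets, expressedGenes) {
  do.call(rbind, lapply(names(l1Subsets), function(nm) {
    gr <- l1Subsets[[nm]]
    hit <- IRanges::overlapsAny(gr, expressedGenes, ignore.strand = TRUE)
    data.frame(subset = nm, n = length(gr), n_in_genes = sum(hit),
               pct = if (length(gr)) 100 * sum(hit) / length(gr) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
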
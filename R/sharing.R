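#' Shared read-pair fragments between two loci
#'
#' The exonization statistic: from the fragment table (properly paired
#' mates with mapping quality at least `minMapq`), (1) collect the read
#' ids with at least one mate mapping fully within locus `A`; (2) the
#' "total fragments" are all mates belonging to those ids (two per id);
#' (3) the "shared" ids are those among them with at least one mate
#' overlapping locus `B` by any amount. The percentage is
#' `100 * shared ids / total fragments`, so a pair of loci spliced into
#' the same transcript by every read pair tops out at 50 (one shared id
#' per two fragments), while an independent transcriptional unit scores
#' near 0. Step 1 demands full containment within `A`; step 3 uses
#' any-overlap with `B` — the asymmetry is part of the statistic's
#' definition.
#'
#' @param A,B single-interval `GRanges` loci.
#' @param fragments fragment table (see [readBedpe()]).
#' @param minMapq minimum mapping quality (default 30).
#' @param dedup drop duplicated (read id, coordinates) records first.
#' @return one-row data.frame: `locus_a`, `locus_b`,
#'   `n_total_fragments`, `n_shared_ids`, `pct` (`NA` with a note when no
#'   qualifying read maps inside `A`).
#' @export
sharedFragmentPct <- function(A, B, fragments, minMapq = 30L, dedup = FALSE) {
  stopifnot(length(A) == 1L, length(B) == 1L)
  keep <- fragments$proper_pair & fragments$mapq >= minMapq
  fragments <- fragments[keep, , drop = FALSE]
  if (dedup)
    fragments <- fragments[!duplicated(fragments[, c("read_id", "chrom1",
      "start1", "end1", "chrom2", "start2", "end2")]), , drop = FALSE]
  labA <- if (is.null(names(A))) "A" else names(A)
  labB <- if (is.null(names(B))) "B" else names(B)
  if (!nrow(fragments))
    return(data.frame(locus_a = labA, locus_b = labB, n_total_fragments = 0L,
                      n_shared_ids = 0L, pct = NA_real_,
                      stringsAsFactors = FALSE))
  mates <- fragmentMates(fragments)
  within <- function(gr, locus)
    IRanges::overlapsAny(gr, locus, type = "within", ignore.strand = TRUE)
  touches <- function(gr, locus)
    IRanges::overlapsAny(gr, locus, ignore.strand = TRUE)
  inA <- within(mates$mate1, A) | within(mates$mate2, A)
  ids <- unique(fragments$read_id[inA])
  nTotal <- 2L * length(ids)
  if (nTotal == 0L)
    return(data.frame(locus_a = labA, locus_b = labB, n_total_fragments = 0L,
                      n_shared_ids = 0L, pct = NA_real_,
                      stringsAsFactors = FALSE))
  sel <- fragments$read_id %in% ids
  hitB <- touches(mates$mate1[sel], B) | touches(mates$mate2[sel], B)
  nShared <- length(unique(fragments$read_id[sel][hitB]))
  data.frame(locus_a = labA, locus_b = labB, n_total_fragments = nTotal,
             n_shared_ids = nShared, pct = 100 * nShared / nTotal,
             stringsAsFactors = FALSE)
}

#' Fragment-sharing distributions for the three control pairings
#'
#' Computes the shared-fragment percentage for (a) random expressed
#' exons paired with their closest exon, (b) upregulated full-length L1
#' loci paired with their closest exon, and (c) random 6 kb segments
#' drawn from introns of expressed genes paired with their closest exon.
#' Exonized L1s push distribution (b) toward (a); L1s expressed as
#' independent transcriptional units leave (b) indistinguishable from
#' (c). Distributions are compared with a two-sided rank-sum test.
#'
#' @param genes expressed gene models (`GRanges` with `exons`).
#' @param upL1 `GRanges` of upregulated L1 loci.
#' @param fragments fragment table covering all loci.
#' @param nRandom number of random exons / intronic segments (0 gives
#'   empty control distributions).
#' @param segmentLength length of the random intronic segments.
#' @param minMapq mapping-quality filter passed through.
#' @param seed RNG seed.
#' @return list with `distributions` (named list of per-pairing
#'   data.frames), `summary` (per-pairing n and median pct) and `tests`
#'   (rank-sum p values: L1 vs intronic control, L1 vs exon pairing).
#' @export
sharingDistributions <- function(genes, upL1, fragments, nRandom = 1000L,
                                 segmentLength = 6000L, minMapq = 30L,
                                 seed = 1L) {
  exonsAll <- unlist(S4Vectors::mcols(genes)$exons, use.names = FALSE)
  names(exonsAll) <- sprintf("exon_%05d", seq_along(exonsAll))
  introns <- geneIntrons(genes)

  pctFor <- function(queries) {
    if (!length(queries))
      return(data.frame(locus_a = character(), locus_b = character(),
                        n_total_fragments = integer(),
                        n_shared_ids = integer(), pct = numeric(),
                        stringsAsFactors = FALSE))
    do.call(rbind, lapply(seq_along(queries), function(i) {
      q <- queries[i]
      others <- exonsAll[!IRanges::overlapsAny(exonsAll, q,
                                               ignore.strand = TRUE)]
      if (!length(others)) others <- exonsAll
      cl <- closestFeature(q, others)
      if (is.na(cl$id))
        return(NULL)
      sharedFragmentPct(q, exonsAll[cl$id], fragments, minMapq = minMapq)
    }))
  }

  withSeed(seed, {
    randExons <- if (nRandom > 0)
      exonsAll[sample.int(length(exonsAll), min(nRandom, length(exonsAll)))]
      else exonsAll[0]
    randIntronic <- if (nRandom > 0)
      randomIntronicSegments(introns, nRandom, segmentLength,
                             seed = sample.int(1e6, 1))
      else grFrom(character(), integer(), integer())
    dists <- list(exon_exon = pctFor(randExons),
                  l1_exon = pctFor(upL1),
                  intron_exon = pctFor(randIntronic))
    summary <- do.call(rbind, lapply(names(dists), function(nm)
      data.frame(pairing = nm, n = nrow(dists[[nm]]),
                 median_pct = median(dists[[nm]]$pct, na.rm = TRUE),
                 stringsAsFactors = FALSE)))
    rs <- function(a, b) {
      a <- a$pct[!is.na(a$pct)]; b <- b$pct[!is.na(b$pct)]
      if (!length(a) || !length(b)) return(NA_real_)
      if (length(unique(c(a, b))) == 1L) return(1)  # fully tied: no evidence
      suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
    }
    list(distributions = dists, summary = summary,
         tests = c(l1_vs_intron = rs(dists$l1_exon, dists$intron_exon),
                   l1_vs_exon = rs(dists$l1_exon, dists$exon_exon)))
  })
}
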
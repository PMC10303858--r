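#' Flag intervals overlapping another set
#'
#' bedtools-intersect semantics: an overlap is at least 1 shared base;
#' strand is ignored throughout (the analyses are strand-blind).
#'
#' @param a query `GRanges`.
#' @param b subject `GRanges` (named, when ids are wanted back).
#' @return a list with `hit` (logical per query) and `ids` (a
#'   `CharacterList` of overlapping subject names per query).
#' @export
intersectAny <- function(a, b) {
  hits <- GenomicRanges::findOverlaps(a, b, minoverlap = 1L,
                                      ignore.strand = TRUE)
  ids <- if (is.null(names(b))) as.character(S4Vectors::subjectHits(hits))
         else names(b)[S4Vectors::subjectHits(hits)]
  byQuery <- unname(S4Vectors::splitAsList(ids,
    factor(S4Vectors::queryHits(hits), levels = seq_along(a))))
  list(hit = lengths(byQuery) > 0L, ids = byQuery)
}

#' Subtract one interval set from another
#'
#' Exact per-chromosome set difference (bedtools subtract on merged
#' inputs): the parts of `a` not covered by `b`, sorted and merged.
#' Strand is ignored.
#'
#' @param a,b `GRanges`.
#' @return a sorted, merged `GRanges`.
#' @export
subtractIntervals <- function(a, b) {
  res <- GenomicRanges::setdiff(GenomicRanges::reduce(a, ignore.strand = TRUE),
                                GenomicRanges::reduce(b, ignore.strand = TRUE),
                                ignore.strand = TRUE)
  GenomicRanges::sort(res)
}

#' Closest feature to a query interval
#'
#' Minimal-gap neighbor on the query's chromosome; an overlapping feature
#' has distance 0. Ties are broken by smaller feature start, then
#' lexicographically smaller id, so results are deterministic. The
#' returned distance is signed: negative when the closest feature lies
#' left of the query, positive when right, 0 on overlap.
#'
#' @param query a single-interval `GRanges`.
#' @param features a named `GRanges`.
#' @return list with `id` and `distance`; both `NA` (with a
#'   `"no neighbor"` note) when no feature shares the query's chromosome.
#' @export
closestFeature <- function(query, features) {
  stopifnot(length(query) == 1L)
  same <- features[as.character(GenomicRanges::seqnames(features)) ==
                     as.character(GenomicRanges::seqnames(query))]
  if (!length(same))
    return(list(id = NA_character_, distance = NA_real_, note = "no neighbor"))
  d <- GenomicRanges::distance(rep(query, length(same)), same,
                               ignore.strand = TRUE)
  best <- which(d == min(d))
  if (length(best) > 1L) {
    st <- GenomicRanges::start(same)[best]
    best <- best[st == min(st)]
    if (length(best) > 1L) {
      ids <- names(same)[best]
      best <- best[order(ids)][1L]
    }
  }
  best <- best[1L]
  sgn <- if (d[best] == 0) 0
         else if (GenomicRanges::end(same)[best] < GenomicRanges::start(query)) -1
         else 1
  list(id = names(same)[best], distance = sgn * d[best], note = "")
}

# Build per-mate GRanges from a fragment table.
fragmentMates <- function(fragments) {
  gr1 <- grFrom(fragments$chrom1, fragments$start1, fragments$end1)
  gr2 <- grFrom(fragments$chrom2, fragments$start2, fragments$end2)
  names(gr1) <- names(gr2) <- fragments$read_id
  list(mate1 = gr1, mate2 = gr2)
}

#' Count mates fully contained in a region set
#'
#' bedtools `-F 1` semantics: a mate counts only when 100% of its length
#' lies inside the (merged) region set. Reads supplied as a `GRangesList`
#' are treated as spliced alignments: with `splitBlocks = TRUE` each
#' block must be fully contained for the read to count (the `-split`
#' behavior); with `splitBlocks = FALSE` the unsplit span
#' (min start to max end) is tested instead.
#'
#' @param fragments a fragment table (each mate is one unspliced read) or
#'   a `GRangesList` of per-read alignment blocks.
#' @param regions `GRanges` region set.
#' @param splitBlocks test individual blocks rather than the read span.
#' @return integer count of contained mates/reads.
#' @export
countContainedFragments <- function(fragments, regions, splitBlocks = FALSE) {
  merged <- GenomicRanges::reduce(regions, ignore.strand = TRUE)
  containedIn <- function(gr)
    IRanges::overlapsAny(gr, merged, type = "within", ignore.strand = TRUE)
  if (is(fragments, "GRangesList")) {
    if (splitBlocks) {
      ok <- all(S4Vectors::splitAsList(
        containedIn(unlist(fragments, use.names = FALSE)),
        rep(seq_along(fragments), lengths(fragments))))
    } else {
      ok <- containedIn(unlist(base::range(fragments,
                                                    ignore.strand = TRUE)))
    }
    return(sum(ok))
  }
  mates <- fragmentMates(fragments)
  sum(containedIn(mates$mate1)) + sum(containedIn(mates$mate2))
}

#' Draw random fixed-length segments inside introns
#'
#' Samples `n` segments of `length` bp, each fully contained in one
#' intron, uniformly over all eligible placements (introns weighted by
#' their number of valid start positions), seeded for reproducibility.
#'
#' @param introns `GRanges` of introns.
#' @param n number of segments.
#' @param length segment length in bp.
#' @param seed RNG seed.
#' @return a `GRanges` of `n` segments named `ris_<i>`.
#' @export
randomIntronicSegments <- function(introns, n, length, seed = 1L) {
  eligible <- introns[GenomicRanges::width(introns) >= length]
  if (!length(eligible))
    stop("no intron of at least ", length, " bp to sample from")
  withSeed(seed, {
    nPlacements <- GenomicRanges::width(eligible) - length + 1
    pick <- sample.int(base::length(eligible), n, replace = TRUE,
                       prob = nPlacements)
    offset <- floor(runif(n) * nPlacements[pick])
    gr <- grFrom(as.character(GenomicRanges::seqnames(eligible))[pick],
                 GenomicRanges::start(eligible)[pick] + offset,
                 GenomicRanges::start(eligible)[pick] + offset + length - 1)
    names(gr) <- sprintf("ris_%04d", seq_len(n))
    gr
  })
}
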
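#' Median-of-ratios size factors
#'
#' The library-scale estimator behind DESeq-style normalization: the
#' per-feature reference is the geometric mean across samples (computed
#' in log space; features containing any zero are excluded from the
#' reference), and each sample's size factor is the median over included
#' features of count / reference.
#'
#' @param counts raw count matrix (features x samples), >= 2 samples.
#' @return named numeric vector of positive size factors, one per sample.
#' @examples
#' m <- matrix(c(10, 20, 40, 80), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
#' sizeFactorsMoR(m)  # (1/sqrt(2), sqrt(2))
#' @export
sizeFactorsMoR <- function(counts) {
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  allPos <- rowSums(counts <= 0) == 0L
  if (!any(allPos))
    stop("no feature has all-positive counts; pre-filter low-count features ",
         "before estimating size factors")
  logRef <- rowMeans(log(counts[allPos, , drop = FALSE]))
  sf <- apply(counts[allPos, , drop = FALSE], 2L,
              function(col) median(exp(log(col) - logRef)))
  setNames(as.numeric(sf), colnames(counts))
}

#' Divide counts by per-sample size factors
#'
#' @param counts raw count matrix (features x samples).
#' @param sf named size factors covering every sample.
#' @return a real-valued normalized matrix of the same shape.
#' @export
normalizeCounts <- function(counts, sf) {
  missing <- setdiff(colnames(counts), names(sf))
  if (length(missing))
    stop("no size factor for sample(s): ", paste(missing, collapse = ", "))
  sweep(counts, 2L, sf[colnames(counts)], "/")
}

#' Select expressed features
#'
#' A feature is kept when its mean raw count across all samples is at
#' least `minMean` (inclusive), its length strictly exceeds `minLength`
#' when that filter is requested, and its subfamily matches the
#' whitelist when one is given. The defaults encode the full-length L1
#' selection used throughout: L1HS/L1PA subfamilies, length > 5000 bp,
#' mean >= 200 reads; for genes drop the length/subfamily filters and
#' keep `minMean` (200, or 15 for the more permissive variant).
#'
#' @param counts raw count matrix.
#' @param minMean minimum mean raw count (inclusive).
#' @param lengths named feature lengths in bp; required when `minLength`
#'   is set.
#' @param minLength strict lower bound on feature length, or `NA` to skip.
#' @param subfamilies named feature subfamilies; required when
#'   `whitelist` is set.
#' @param whitelist subfamily patterns, globs allowed (e.g.
#'   `c("L1HS", "L1PA*")`), or `NULL` to skip.
#' @return an [ExpressedSet-class].
#' @export
selectExpressed <- function(counts, minMean = 200, lengths = NULL,
                            minLength = NA_real_, subfamilies = NULL,
                            whitelist = NULL) {
  keep <- rowMeans(counts) >= minMean
  if (!is.na(minLength)) {
    if (is.null(lengths))
      stop("length filter requested but features carry no length annotation")
    keep <- keep & lengths[rownames(counts)] > minLength
  }
  if (!is.null(whitelist)) {
    if (is.null(subfamilies))
      stop("subfamily filter requested but features carry no subfamily annotation")
    rx <- paste(vapply(whitelist, utils::glob2rx, ""), collapse = "|")
    keep <- keep & grepl(rx, subfamilies[rownames(counts)])
  }
  new("ExpressedSet", ids = rownames(counts)[which(keep)],
      minMean = as.numeric(minMean), minLength = as.numeric(minLength),
      subfamilies = as.character(if (is.null(whitelist)) character() else whitelist))
}

#' Per-subfamily mean MilliDiv, for all and for expressed loci
#'
#' MilliDiv (base mismatches per thousand against the subfamily
#' consensus) proxies the evolutionary age of a repeat copy; comparing
#' the expressed stratum against all annotated copies shows whether
#' transcription concentrates in the younger (less diverged) loci.
#'
#' @param l1 `GRanges` of L1 loci with `subfamily` and `milliDiv`
#'   metadata columns.
#' @param expressed an [ExpressedSet-class] or character vector of
#'   expressed locus ids.
#' @return data.frame with one row per subfamily: `subfamily`,
#'   `mean_all`, `n_all`, `mean_expressed`, `n_expressed`
#'   (`NaN`/0 when a subfamily has no expressed locus).
#' @export
milliDivSummary <- function(l1, expressed) {
  ids <- if (is(expressed, "ExpressedSet")) featureIds(expressed)
         else as.character(expressed)
  mc <- S4Vectors::mcols(l1)
  if (is.null(mc$milliDiv)) stop("loci carry no milliDiv annotation")
  isExpr <- names(l1) %in% ids
  sub <- sort(unique(mc$subfamily))
  do.call(rbind, lapply(sub, function(s) {
    inS <- mc$subfamily == s
    data.frame(subfamily = s,
               mean_all = mean(mc$milliDiv[inS]),
               n_all = sum(inS),
               mean_expressed = mean(mc$milliDiv[inS & isExpr]),
               n_expressed = sum(inS & isExpr),
               stringsAsFactors = FALSE)
  }))
}

#' Filter retained introns
#'
#' Keeps introns called retained under the per-sample rule:
#' `IRratio >= 0.1`, `IntronDepth >= 3` (both inclusive), a clean
#' `Warnings` field (`"-"`), and no overlap with a known feature.
#'
#' @param records retained-intron data.frame (see [readIrTable()]).
#' @param minRatio,minDepth inclusive thresholds.
#' @return the retained subset of `records`.
#' @export
filterRetainedIntrons <- function(records, minRatio = 0.1, minDepth = 3) {
  keep <- records$IRratio >= minRatio &
    records$IntronDepth >= minDepth &
    records$Warnings == "-" &
    !records$overlaps_known_feature
  records[keep, , drop = FALSE]
}
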
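#' L1 / host-gene expression correlation across samples
#'
#' For every genic L1 locus (its host gene taken from the context
#' calls), the correlation between the locus's normalized expression and
#' its host gene's across all samples of the dataset, plus the summary
#' fraction of pairs with negative correlation. Zero-variance vectors
#' make a pair incomputable; such pairs are kept in the output with
#' `r = NA` and `flag = "zero variance"` and excluded from the summary.
#'
#' @param normL1,normGenes normalized count matrices sharing sample
#'   columns.
#' @param contextCalls result of [classifyContext()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param expressedL1 optional [ExpressedSet-class] or id vector
#'   restricting the L1 loci.
#' @return list with `pairs` (data.frame: `l1_id`, `gene_id`, `r`, `n`,
#'   `method`, `flag`) and `fractionNegative`.
#' @export
l1HostCorrelation <- function(normL1, normGenes, contextCalls,
                              method = c("pearson", "spearman"),
                              expressedL1 = NULL) {
  method <- match.arg(method)
  shared <- intersect(colnames(normL1), colnames(normGenes))
  if (length(shared) < 3L) stop("need at least 3 shared samples")
  if (is(expressedL1, "ExpressedSet")) expressedL1 <- featureIds(expressedL1)
  calls <- contextCalls[!is.na(contextCalls$host_gene), , drop = FALSE]
  if (!is.null(expressedL1))
    calls <- calls[calls$l1_id %in% expressedL1, , drop = FALSE]
  calls <- calls[calls$l1_id %in% rownames(normL1) &
                   calls$host_gene %in% rownames(normGenes), , drop = FALSE]
  pairs <- do.call(rbind, lapply(seq_len(nrow(calls)), function(i) {
    x <- normL1[calls$l1_id[i], shared]
    y <- normGenes[calls$host_gene[i], shared]
    if (sd(x) == 0 || sd(y) == 0)
      return(data.frame(l1_id = calls$l1_id[i], gene_id = calls$host_gene[i],
                        r = NA_real_, n = length(shared), method = method,
                        flag = "zero variance", stringsAsFactors = FALSE))
    data.frame(l1_id = calls$l1_id[i], gene_id = calls$host_gene[i],
               r = cor(x, y, method = method), n = length(shared),
               method = method, flag = "", stringsAsFactors = FALSE)
  }))
  if (is.null(pairs))
    pairs <- data.frame(l1_id = character(), gene_id = character(),
                        r = numeric(), n = integer(), method = character(),
                        flag = character(), stringsAsFactors = FALSE)
  ok <- !is.na(pairs$r)
  list(pairs = pairs,
       fractionNegative = if (any(ok)) mean(pairs$r[ok] < 0) else NA_real_)
}

#' Correlation between two per-sample metrics
#'
#' Pearson correlation with a two-sided p value, e.g. between the number
#' of intron-contained reads per sample and the summed normalized
#' full-length L1 expression.
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @param method correlation method passed to [stats::cor.test()].
#' @return list with `r` and `p`.
#' @export
metricCorrelation <- function(x, y, method = "pearson") {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input: correlation undefined")
  ct <- cor.test(x, y, method = method)
  list(r = unname(ct$estimate), p = ct$p.value)
}
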
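#' @import methods
#' @importFrom stats median rnbinom rnorm rpois runif sd setNames phyper
#'   cor cor.test wilcox.test pt complete.cases
#' @importFrom utils head tail
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Every stochastic operation in the package funnels through this so that
# results are pure functions of their (config, seed) arguments.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Single-chromosome GRanges helper used throughout the simulator.
grFrom <- function(chrom, start, end, strand = "*", ...) {
  if (length(start) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = start, end = end),
                         strand = strand, ...)
}

assertScalarNumber <- function(x, name, lower = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower else x >= lower)
  if (!ok) stop(sprintf("'%s' must be a finite number %s %s", name,
                        if (strict) ">" else ">=", lower))
  invisible(x)
}
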
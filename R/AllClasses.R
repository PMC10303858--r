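#' Simulation parameters for the synthetic cohort generator
#'
#' `SimParams` bundles every knob of the synthetic-data generator: cohort
#' layout (controls, cases, which cases carry the L1 effect), annotation
#' geometry (genome length, gene and L1 counts, the fraction of L1 loci
#' that are full length, i.e. longer than 5 kb), injected effects
#' (fold upregulation of intronic full-length L1s in affected cases,
#' dysregulated genes, L1/host-gene anticorrelation couplings) and the
#' negative-binomial noise model (dispersion, per-feature baseline-mean
#' range, per-sample size-factor range).
#'
#' Counts are drawn as NB(mean = mu, variance = mu + dispersion * mu^2),
#' the standard RNA-seq noise model. With a fixed `seed` every generator
#' is a pure function of this object.
#'
#' @slot seed integer RNG seed.
#' @slot chrom chromosome name of the simulated genome.
#' @slot genomeLength length (bp) of the single simulated chromosome.
#' @slot nGenes,nL1 number of gene models / L1 loci to place.
#' @slot flFraction fraction of L1 loci longer than 5000 bp.
#' @slot l1ContextProps named proportions (intronic, exonic, intergenic)
#'   used to stratify L1 placement.
#' @slot nControls,nCases cohort sizes.
#' @slot affectedCases indices (into the case samples) of the cases that
#'   carry the L1 upregulation.
#' @slot l1UpFraction fraction of intronic full-length L1 loci upregulated
#'   in affected cases.
#' @slot l1Fold linear-scale fold applied to upregulated L1 means.
#' @slot geneDeCount number of genes perturbed in affected cases.
#' @slot geneFold linear-scale fold applied to perturbed genes (half of
#'   them up, half down).
#' @slot anticorrPairs number of L1/host-gene pairs with imposed negative
#'   coupling.
#' @slot anticorrFactor factor dividing the host-gene mean whenever its
#'   coupled L1 is upregulated.
#' @slot nbDispersion negative-binomial dispersion alpha.
#' @slot baseMeanRange,sizeFactorRange 2-vectors giving the per-feature
#'   baseline-mean and per-sample library-scale intervals.
#'
#' @examples
#' sp <- SimParams(seed = 1, nGenes = 20, nL1 = 12)
#' nCases(sp)
#' @export
setClass("SimParams",
  representation(
    seed = "integer",
    chrom = "character",
    genomeLength = "numeric",
    nGenes = "integer",
    nL1 = "integer",
    flFraction = "numeric",
    l1ContextProps = "numeric",
    nControls = "integer",
    nCases = "integer",
    affectedCases = "integer",
    l1UpFraction = "numeric",
    l1Fold = "numeric",
    geneDeCount = "integer",
    geneFold = "numeric",
    anticorrPairs = "integer",
    anticorrFactor = "numeric",
    nbDispersion = "numeric",
    baseMeanRange = "numeric",
    sizeFactorRange = "numeric"
  )
)

setValidity("SimParams", function(object) {
  msg <- character()
  frac <- c(flFraction = object@flFraction, l1UpFraction = object@l1UpFraction)
  if (any(frac < 0 | frac > 1))
    msg <- c(msg, "fractions must lie in [0, 1]")
  if (object@nGenes < 1L || object@nL1 < 1L)
    msg <- c(msg, "nGenes and nL1 must be >= 1")
  if (object@genomeLength <= 0)
    msg <- c(msg, "genomeLength must be positive")
  if (length(object@l1ContextProps) != 3L ||
      !setequal(names(object@l1ContextProps),
                c("intronic", "exonic", "intergenic")) ||
      any(object@l1ContextProps < 0) ||
      abs(sum(object@l1ContextProps) - 1) > 1e-8)
    msg <- c(msg, "l1ContextProps must be named (intronic, exonic, intergenic) proportions summing to 1")
  if (length(object@affectedCases) &&
      (any(object@affectedCases < 1L) || any(object@affectedCases > object@nCases)))
    msg <- c(msg, "affectedCases must be a subset of 1..nCases")
  if (anyDuplicated(object@affectedCases))
    msg <- c(msg, "affectedCases must be unique")
  if (object@l1Fold <= 0 || object@geneFold <= 0 || object@anticorrFactor <= 0)
    msg <- c(msg, "all folds must be > 0")
  if (object@nbDispersion < 0)
    msg <- c(msg, "nbDispersion must be >= 0")
  rng <- rbind(object@baseMeanRange, object@sizeFactorRange)
  if (ncol(rng) != 2L || any(rng <= 0) || any(rng[, 1] > rng[, 2]))
    msg <- c(msg, "baseMeanRange and sizeFactorRange must be positive increasing 2-vectors (0 excluded)")
  if (length(msg)) msg else TRUE
})

#' Construct simulation parameters
#'
#' @param seed integer RNG seed.
#' @param chrom chromosome name.
#' @param genomeLength simulated chromosome length in bp.
#' @param nGenes,nL1 number of gene models and L1 loci.
#' @param flFraction fraction of L1 loci with length > 5000 bp.
#' @param l1ContextProps named placement proportions
#'   (intronic, exonic, intergenic).
#' @param nControls,nCases control / case sample counts.
#' @param affectedCases case indices carrying the L1 upregulation.
#' @param l1UpFraction fraction of intronic full-length L1s upregulated in
#'   affected cases.
#' @param l1Fold linear fold change applied to upregulated L1s.
#' @param geneDeCount number of dysregulated genes in affected cases.
#' @param geneFold fold change applied to dysregulated genes.
#' @param anticorrPairs number of L1/host-gene anticorrelation couplings.
#' @param anticorrFactor divisor applied to the host-gene mean in samples
#'   where its coupled L1 is upregulated.
#' @param nbDispersion negative-binomial dispersion alpha
#'   (variance = mu + alpha mu^2); 0 gives Poisson counts.
#' @param baseMeanRange per-feature baseline mean interval.
#' @param sizeFactorRange per-sample library-scale interval.
#' @return a validated [SimParams-class] object.
#' @export
SimParams <- function(seed = 1L,
                      chrom = "chrS",
                      genomeLength = 8e6,
                      nGenes = 80L,
                      nL1 = 60L,
                      flFraction = 0.5,
                      l1ContextProps = c(intronic = 0.6, exonic = 0.1,
                                         intergenic = 0.3),
                      nControls = 9L,
                      nCases = 9L,
                      affectedCases = 1:3,
                      l1UpFraction = 0.4,
                      l1Fold = 8,
                      geneDeCount = 50L,
                      geneFold = 4,
                      anticorrPairs = 5L,
                      anticorrFactor = 2,
                      nbDispersion = 0.05,
                      baseMeanRange = c(300, 2000),
                      sizeFactorRange = c(0.6, 1.6)) {
  new("SimParams",
      seed = as.integer(seed), chrom = chrom,
      genomeLength = as.numeric(genomeLength),
      nGenes = as.integer(nGenes), nL1 = as.integer(nL1),
      flFraction = flFraction, l1ContextProps = l1ContextProps,
      nControls = as.integer(nControls), nCases = as.integer(nCases),
      affectedCases = as.integer(affectedCases),
      l1UpFraction = l1UpFraction, l1Fold = l1Fold,
      geneDeCount = as.integer(geneDeCount), geneFold = geneFold,
      anticorrPairs = as.integer(anticorrPairs),
      anticorrFactor = anticorrFactor,
      nbDispersion = nbDispersion,
      baseMeanRange = as.numeric(baseMeanRange),
      sizeFactorRange = as.numeric(sizeFactorRange))
}

#' @describeIn SimParams-class number of case samples
#' @param object a `SimParams` object.
#' @export
setGeneric("nCases", function(object) standardGeneric("nCases"))
#' @rdname SimParams-class
#' @export
setMethod("nCases", "SimParams", function(object) object@nCases)

#' @describeIn SimParams-class number of control samples
#' @export
setGeneric("nControls", function(object) standardGeneric("nControls"))
#' @rdname SimParams-class
#' @export
setMethod("nControls", "SimParams", function(object) object@nControls)

#' @describeIn SimParams-class indices of affected case samples
#' @export
setGeneric("affectedCases", function(object) standardGeneric("affectedCases"))
#' @rdname SimParams-class
#' @export
setMethod("affectedCases", "SimParams", function(object) object@affectedCases)

setMethod("show", "SimParams", function(object) {
  cat("SimParams\n")
  cat(sprintf("  genome: %s (%.3g bp), %d genes, %d L1 loci (FL fraction %.2f)\n",
              object@chrom, object@genomeLength, object@nGenes, object@nL1,
              object@flFraction))
  cat(sprintf("  cohort: %d controls, %d cases (affected: %s)\n",
              object@nControls, object@nCases,
              paste(object@affectedCases, collapse = ",")))
  cat(sprintf("  effects: l1Fold %.3g on %.0f%% of intronic FL L1s, %d DE genes (fold %.3g), %d anticorr pairs (factor %.3g)\n",
              object@l1Fold, 100 * object@l1UpFraction, object@geneDeCount,
              object@geneFold, object@anticorrPairs, object@anticorrFactor))
  cat(sprintf("  noise: NB dispersion %.3g, base means [%g, %g], size factors [%g, %g], seed %d\n",
              object@nbDispersion, object@baseMeanRange[1], object@baseMeanRange[2],
              object@sizeFactorRange[1], object@sizeFactorRange[2], object@seed))
})

#' Resampling enrichment result
#'
#' Holds the observed overlap count between a target set and an annotation
#' set together with the null distribution obtained from size-matched
#' random draws out of the expressed universe: null mean, null sd, the
#' derived z score, and (as an extra cross-check not part of the original
#' resampling procedure) the exact hypergeometric tail probability.
#'
#' The z score is `(observed - nullMean) / nullSd` when `nullSd > 0`, and
#' `NA` (flagged in `note`) otherwise.
#'
#' @slot set annotation set name.
#' @slot observed observed overlap count.
#' @slot nullMean,nullSd moments of the resampled null.
#' @slot z enrichment z score (`NA` when the null is degenerate).
#' @slot n number of resamples.
#' @slot seed RNG seed used for the draws.
#' @slot pHyper exact hypergeometric upper-tail probability
#'   (`NA` for interval-based enrichments where no hypergeometric null
#'   applies).
#' @slot note diagnostic flag, e.g. "degenerate null (sd = 0)".
#' @export
setClass("EnrichmentResult",
  representation(set = "character", observed = "numeric",
                 nullMean = "numeric", nullSd = "numeric",
                 z = "numeric", n = "integer", seed = "integer",
                 pHyper = "numeric", note = "character"))

setValidity("EnrichmentResult", function(object) {
  if (object@nullSd > 0 && !is.na(object@z) &&
      abs(object@z - (object@observed - object@nullMean) / object@nullSd) > 1e-8)
    return("z inconsistent with (observed - nullMean)/nullSd")
  if (object@nullSd == 0 && !is.na(object@z))
    return("z must be NA when the null sd is 0")
  TRUE
})

#' @describeIn EnrichmentResult-class the enrichment z score
#' @param object an `EnrichmentResult`.
#' @export
setGeneric("enrichmentZ", function(object) standardGeneric("enrichmentZ"))
#' @rdname EnrichmentResult-class
#' @export
setMethod("enrichmentZ", "EnrichmentResult", function(object) object@z)

#' @describeIn EnrichmentResult-class observed overlap count
#' @export
setGeneric("observedOverlap", function(object) standardGeneric("observedOverlap"))
#' @rdname EnrichmentResult-class
#' @export
setMethod("observedOverlap", "EnrichmentResult", function(object) object@observed)

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf("EnrichmentResult '%s': observed %g, null %0.3f +/- %0.3f (n = %d), z = %s\n",
              object@set, object@observed, object@nullMean, object@nullSd,
              object@n, ifelse(is.na(object@z), "NA", sprintf("%0.3f", object@z))))
  if (!is.na(object@pHyper))
    cat(sprintf("  hypergeometric cross-check: P(X >= observed) = %0.4g\n",
                object@pHyper))
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
})

#' Turn one or more enrichment results into a data.frame
#'
#' @param results an `EnrichmentResult` or a list of them.
#' @return a data.frame with one row per result.
#' @export
enrichmentTable <- function(results) {
  if (is(results, "EnrichmentResult")) results <- list(results)
  do.call(rbind, lapply(results, function(r)
    data.frame(set = r@set, observed = r@observed, null_mean = r@nullMean,
               null_sd = r@nullSd, z = r@z, n = r@n, seed = r@seed,
               p_hyper = r@pHyper, stringsAsFactors = FALSE)))
}

#' Expressed-feature set
#'
#' Feature identifiers passing the expressed-feature filters together with
#' the thresholds used, so downstream stages can report how the universe
#' was defined.
#'
#' @slot ids feature identifiers passing the filters.
#' @slot minMean minimum mean raw count across all samples (inclusive).
#' @slot minLength strict minimum feature length in bp (`NA` when the
#'   length filter was not applied).
#' @slot subfamilies subfamily whitelist patterns (may include globs such
#'   as `"L1PA*"`); empty when not applied.
#' @export
setClass("ExpressedSet",
  representation(ids = "character", minMean = "numeric",
                 minLength = "numeric", subfamilies = "character"))

setMethod("show", "ExpressedSet", function(object) {
  filters <- sprintf("mean >= %g", object@minMean)
  if (!is.na(object@minLength))
    filters <- c(filters, sprintf("length > %g", object@minLength))
  if (length(object@subfamilies))
    filters <- c(filters, sprintf("subfamily in {%s}",
                                  paste(object@subfamilies, collapse = ", ")))
  cat(sprintf("ExpressedSet: %d features (%s)\n", length(object@ids),
              paste(filters, collapse = "; ")))
})

#' @describeIn ExpressedSet-class the feature identifiers in the set
#' @param object an `ExpressedSet`.
#' @export
setGeneric("featureIds", function(object) standardGeneric("featureIds"))
#' @rdname ExpressedSet-class
#' @export
setMethod("featureIds", "ExpressedSet", function(object) object@ids)
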
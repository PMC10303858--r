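#' Per-sample z-score differential expression
#'
#' The replicate-free outlier statistic at the center of the package:
#' for each feature, a case sample's z score is its normalized (linear
#' scale) expression minus the mean of the control samples, divided by
#' the standard deviation of the control samples. Control samples are
#' scored leave-one-out: each control is compared against the
#' distribution of all other controls, so every sample in the cohort
#' gets a z. Entries where the control sd is 0 are `undefined` and never
#' counted as differentially expressed. Calls use strict inequalities:
#' `up` when z > `zThreshold`, `down` when z < -`zThreshold`, `ns`
#' otherwise.
#'
#' No multiple-testing correction is applied; the fixed |z| threshold is
#' the decision rule, and with ~`t` tails the expected false-positive
#' rate per (feature, sample) can be annotated downstream.
#'
#' @param norm normalized count matrix (features x samples).
#' @param samples sample sheet with `sample_id` and `group`
#'   (`"control"` / `"case"`); at least 3 controls are required so the
#'   leave-one-out comparisons keep >= 2 references.
#' @param features optional [ExpressedSet-class] or character vector
#'   restricting the feature universe.
#' @param zThreshold DE threshold on |z| (default 3, strict).
#' @param sdType `"sample"` (n - 1 denominator, default) or
#'   `"population"` (n).
#' @param pseudocount added to numerator and denominator of the log2
#'   fold change (default 1).
#' @return a `SummarizedExperiment` with assays `z`, `log2fc` and
#'   `status` (`up`/`down`/`ns`/`undefined`) and the sample sheet as
#'   `colData`.
#' @examples
#' m <- rbind(f1 = c(10, 20, 30, 40))
#' colnames(m) <- c("c1", "c2", "c3", "s1")
#' sm <- data.frame(sample_id = colnames(m),
#'                  group = c("control", "control", "control", "case"))
#' SummarizedExperiment::assay(perSampleZ(m, sm), "z")[, "s1"]  # 2
#' @export
perSampleZ <- function(norm, samples, features = NULL, zThreshold = 3,
                       sdType = c("sample", "population"), pseudocount = 1) {
  sdType <- match.arg(sdType)
  if (is(features, "ExpressedSet")) features <- featureIds(features)
  if (!is.null(features)) norm <- norm[rownames(norm) %in% features, ,
                                       drop = FALSE]
  stopifnot(all(samples$sample_id %in% colnames(norm)))
  norm <- norm[, samples$sample_id, drop = FALSE]
  ctrl <- samples$sample_id[samples$group == "control"]
  if (length(ctrl) < 3L)
    stop("need at least 3 control samples (leave-one-out requires >= 2 remaining)")

  sdFun <- if (sdType == "sample") function(m) apply(m, 1L, sd)
           else function(m) apply(m, 1L, function(x) sqrt(mean((x - mean(x))^2)))

  z <- log2fc <- matrix(NA_real_, nrow(norm), ncol(norm),
                        dimnames = dimnames(norm))
  for (s in colnames(norm)) {
    ref <- if (s %in% ctrl) setdiff(ctrl, s) else ctrl
    mu <- rowMeans(norm[, ref, drop = FALSE])
    sdv <- sdFun(norm[, ref, drop = FALSE])
    zi <- (norm[, s] - mu) / sdv
    zi[!is.finite(zi)] <- NA_real_
    z[, s] <- zi
    ratio <- (norm[, s] + pseudocount) / (mu + pseudocount)
    log2fc[, s] <- ifelse(ratio > 0, log2(pmax(ratio, .Machine$double.xmin)),
                          NA_real_)
  }
  status <- matrix("ns", nrow(z), ncol(z), dimnames = dimnames(z))
  status[is.na(z)] <- "undefined"
  status[!is.na(z) & z > zThreshold] <- "up"
  status[!is.na(z) & z < -zThreshold] <- "down"

  SummarizedExperiment::SummarizedExperiment(
    assays = list(z = z, log2fc = log2fc, status = status),
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id),
    metadata = list(zThreshold = zThreshold, sdType = sdType,
                    pseudocount = pseudocount, controls = ctrl))
}

#' Net upregulation score per sample
#'
#' Number of features with z above the threshold minus the number with z
#' below its negative, per sample; `undefined` entries are excluded.
#'
#' @param zt result of [perSampleZ()].
#' @param sample optional sample id(s) to restrict to.
#' @return data.frame with `sample_id`, `n_up`, `n_down`, `net`.
#' @export
netUpregulated <- function(zt, sample = NULL) {
  status <- SummarizedExperiment::assay(zt, "status")
  if (!is.null(sample)) status <- status[, sample, drop = FALSE]
  nUp <- as.integer(colSums(status == "up"))
  nDown <- as.integer(colSums(status == "down"))
  data.frame(sample_id = colnames(status), n_up = nUp, n_down = nDown,
             net = nUp - nDown, row.names = NULL, stringsAsFactors = FALSE)
}

#' Log2 fold change against the control mean
#'
#' `log2((x + pseudocount) / (mean(controls) + pseudocount))` per
#' (feature, sample), on normalized linear values; control samples use
#' the leave-one-out control mean, consistent with [perSampleZ()].
#'
#' @inheritParams perSampleZ
#' @return matrix of log2 fold changes (features x samples).
#' @export
log2FoldChange <- function(norm, samples, pseudocount = 1) {
  SummarizedExperiment::assay(
    perSampleZ(norm, samples, pseudocount = pseudocount), "log2fc")
}

#' Count differentially expressed features per sample
#'
#' Tally of |z| calls past the threshold (up plus down), per sample;
#' `undefined` entries excluded.
#'
#' @param zt result of [perSampleZ()].
#' @return data.frame with `sample_id` and `n_de`.
#' @export
deGeneCounts <- function(zt) {
  nu <- netUpregulated(zt)
  data.frame(sample_id = nu$sample_id, n_de = nu$n_up + nu$n_down,
             stringsAsFactors = FALSE)
}

#' Serialize a z-score table to TSV
#'
#' Long format: one row per (feature, sample) with `z`, `log2fc`,
#' `status`.
#'
#' @param zt result of [perSampleZ()].
#' @param path output TSV path.
#' @export
writeZScoreTable <- function(zt, path) {
  z <- SummarizedExperiment::assay(zt, "z")
  fc <- SummarizedExperiment::assay(zt, "log2fc")
  st <- SummarizedExperiment::assay(zt, "status")
  dt <- data.table::data.table(
    feature_id = rep(rownames(z), ncol(z)),
    sample_id = rep(colnames(z), each = nrow(z)),
    z = as.vector(z), log2fc = as.vector(fc), status = as.vector(st))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
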
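test_that("median-of-ratios reproduces the analytic cases", {
  # two identical samples -> unit factors
  m <- matrix(c(10, 30, 10, 30), 2,
              dimnames = list(c("f1", "f2"), c("s1", "s2")))
  expect_equal(sizeFactorsMoR(m), c(s1 = 1, s2 = 1))
  # sample2 = 2 x sample1 -> (1/sqrt(2), sqrt(2))
  m2 <- matrix(c(10, 25, 20, 50), 2,
               dimnames = list(c("f1", "f2"), c("s1", "s2")))
  expect_equal(sizeFactorsMoR(m2), c(s1 = 1 / sqrt(2), s2 = sqrt(2)),
               tolerance = 1e-12)
  # rows with a zero are excluded from the reference
  m3 <- matrix(c(0, 10, 5, 10), 2,
               dimnames = list(c("f1", "f2"), c("s1", "s2")))
  expect_equal(sizeFactorsMoR(m3), c(s1 = 1, s2 = 1))
  # all rows contain a zero -> explicit error
  m4 <- matrix(c(0, 10, 5, 0), 2,
               dimnames = list(c("f1", "f2"), c("s1", "s2")))
  expect_error(sizeFactorsMoR(m4), "pre-filter")
})

test_that("size factors match the DESeq2 estimator on random matrices", {
  skip_if_not_installed("DESeq2")
  set.seed(14)
  for (rep in 1:5) {
    # odd feature count: the ratio-space median and DESeq2's log-space
    # median then pick the same middle element instead of interpolating
    m <- matrix(rnbinom(310, mu = 200, size = 10), 31, 10,
                dimnames = list(sprintf("f%02d", 1:31), sprintf("s%02d", 1:10)))
    m[m == 0] <- 1
    expect_equal(unname(sizeFactorsMoR(m)),
                 unname(DESeq2::estimateSizeFactorsForMatrix(m)),
                 tolerance = 1e-8)
  }
})

test_that("size factors are scale-equivariant", {
  set.seed(8)
  m <- matrix(rpois(200, 100) + 1, 20, 10,
              dimnames = list(sprintf("f%02d", 1:20), sprintf("s%02d", 1:10)))
  sf <- sizeFactorsMoR(m)
  m2 <- m; m2[, 3] <- m2[, 3] * 5
  sf2 <- sizeFactorsMoR(m2)
  # scaling one column by c multiplies its factor by c*k and others by k
  k <- sf2[1] / sf[1]
  expect_equal(unname(sf2[-3] / sf[-3]), rep(unname(k), 9), tolerance = 1e-9)
  expect_equal(unname(sf2[3] / sf[3]), unname(5 * k), tolerance = 1e-9)
})

test_that("normalization divides by factors and removes library scale", {
  m <- matrix(c(10, 40, 20, 80), 2,
              dimnames = list(c("f1", "f2"), c("s1", "s2")))
  expect_equal(normalizeCounts(m, c(s1 = 1, s2 = 1)), m)
  half <- normalizeCounts(m, c(s1 = 1, s2 = 2))
  expect_equal(half[, "s2"], m[, "s2"] / 2)
  # round trip: raw = normalized * sf
  sf <- c(s1 = 0.8, s2 = 1.6)
  expect_equal(sweep(normalizeCounts(m, sf), 2, sf, "*"), m)
  expect_error(normalizeCounts(m, c(s1 = 1)), "no size factor")
  # a feature scaling exactly with library size becomes constant
  raw <- rbind(spike = c(100, 200, 400))
  colnames(raw) <- c("a", "b", "c")
  sfs <- c(a = 1, b = 2, c = 4)
  expect_equal(unname(normalizeCounts(raw, sfs)["spike", ]), rep(100, 3))
})

test_that("expressed-feature filters apply strict and inclusive boundaries", {
  cnt <- rbind(a = rep(200, 4), b = rep(199.99, 4), c = rep(1000, 4),
               d = rep(1000, 4))
  colnames(cnt) <- sprintf("s%d", 1:4)
  lens <- c(a = 6000, b = 6000, c = 5000, d = 5800)
  subf <- c(a = "L1HS", b = "L1PA7", c = "L1PA2", d = "L1ME1")
  es <- selectExpressed(cnt, minMean = 200, lengths = lens, minLength = 5000,
                        subfamilies = subf, whitelist = c("L1HS", "L1PA*"))
  # a: mean exactly 200 kept; b: mean 199.99 dropped;
  # c: length exactly 5000 dropped (strictly longer required);
  # d: subfamily L1ME1 not whitelisted
  expect_identical(featureIds(es), "a")
  expect_error(selectExpressed(cnt, minLength = 5000), "length")
  expect_error(selectExpressed(cnt, subfamilies = NULL,
                               whitelist = c("L1HS")), "subfamily")
})

test_that("MilliDiv summary stratifies expressed loci", {
  l1 <- gr(c(100, 8000, 16000, 30000), c(6100, 14000, 22000, 36000),
           names = sprintf("L1PA2:L1:LINE:%03d", 1:4))
  mcols(l1)$subfamily <- c("L1PA2", "L1PA2", "L1HS", "L1HS")
  mcols(l1)$milliDiv <- c(10, 20, 5, 12.5)
  s <- milliDivSummary(l1, names(l1)[c(1, 3)])
  expect_equal(s$mean_all[s$subfamily == "L1PA2"], 15)
  expect_equal(s$mean_expressed[s$subfamily == "L1PA2"], 10)
  expect_equal(s$mean_all[s$subfamily == "L1HS"], 8.75)
  expect_equal(s$mean_expressed[s$subfamily == "L1HS"], 5)
  expect_error(milliDivSummary(gr(1, 10, names = "x"), "x"), "milliDiv")
})

test_that("expressed loci are younger than the full annotation on average", {
  # expressed loci concentrate in the young (low MilliDiv) subfamilies and,
  # within subfamilies, in the less diverged copies, so the pooled mean
  # divergence of the expressed stratum sits below the annotation-wide mean
  ok <- 0L
  for (s in 1:10) {
    sp <- smallSim(s)
    ann <- simulateAnnotation(sp)
    cnt <- assay(simulateCounts(sp, ann$genes, ann$l1)$l1SE, "counts")
    es <- selectExpressed(cnt, minMean = 200,
                          lengths = setNames(width(ann$l1), names(ann$l1)),
                          minLength = 5000)
    md <- mcols(ann$l1)$milliDiv
    isExpr <- names(ann$l1) %in% featureIds(es)
    if (any(isExpr) && !all(isExpr) && mean(md[isExpr]) < mean(md)) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("retained-intron filtering applies all four conditions", {
  rec <- data.frame(
    chrom = "chr1", start = 1:5 * 100L, end = 1:5 * 100L + 50L,
    name = sprintf("i%d", 1:5),
    IRratio = c(0.1, 0.09, 0.5, 0.5, 0.5),
    IntronDepth = c(3, 10, 2.9, 10, 10),
    Warnings = c("-", "-", "-", "LowCover", "-"),
    overlaps_known_feature = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  kept <- filterRetainedIntrons(rec)
  # only the first row passes: both thresholds inclusive, clean warnings,
  # no overlap with a known feature
  expect_identical(kept$name, "i1")
})
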
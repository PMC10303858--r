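constTrack <- function(L, value = 2, chrom = "chr1") {
  t <- gr(1, L, chrom = chrom)
  mcols(t)$score <- value
  t
}

test_that("a constant track yields a constant matrix and flat mean", {
  track <- constTrack(100000, 2.5)
  # heterogeneous region lengths: body rescaling must be length-weighted
  regions <- gr(c(20000, 50000, 70000), c(26000, 52345, 70600),
                names = c("r1", "r2", "r3"))
  pm <- profileMatrix(track, regions, flank = 1000, bodyBins = 20,
                      flankBinSize = 50)
  expect_identical(dim(pm), c(3L, 60L))
  expect_true(all(abs(pm - 2.5) < 1e-9))
  expect_equal(meanProfile(pm), rep(2.5, 60), tolerance = 1e-9)
})

test_that("minus-strand regions are reported 5' to 3'", {
  # signal only left of the region: for a minus-strand region that flank
  # is downstream, so it must appear in the right-hand bins
  track <- gr(c(1, 4001, 5001), c(4000, 5000, 20000))
  mcols(track)$score <- c(0, 9, 0)
  region <- gr(5001, 11000, strand = "-", names = "rm")
  pm <- profileMatrix(track, region, flank = 1000, bodyBins = 10,
                      flankBinSize = 100)
  expect_identical(dim(pm), c(1L, 30L))
  expect_true(all(pm[1, 1:20] == 0))
  expect_true(all(pm[1, 21:30] == 9))
  plus <- profileMatrix(track, `strand<-`(region, value = "+"),
                        flank = 1000, bodyBins = 10, flankBinSize = 100)
  expect_equal(unname(pm[1, ]), rev(unname(plus[1, ])))
})

test_that("binning matches a per-base brute-force oracle", {
  set.seed(12)
  L <- 30000L
  for (rep in 1:5) {
    # random piecewise track covering the genome
    cuts <- sort(sample(2:(L - 1), 20))
    s <- c(1L, cuts + 1L); e <- c(cuts, L)
    track <- gr(s, e)
    mcols(track)$score <- round(runif(length(s), 0, 10), 2)
    base <- rep(track$score, width(track))  # per-base signal
    region <- gr(10000, 10000 + sample(500:4000, 1), names = "r")
    flank <- 500L; B <- 8L; fb <- 100L
    pm <- profileMatrix(track, region, flank = flank, bodyBins = B,
                        flankBinSize = fb)
    edges <- c(seq(start(region) - 1 - flank, start(region) - 1, by = fb),
               start(region) - 1 + seq_len(B - 1) * width(region) / B,
               seq(end(region), end(region) + flank, by = fb))
    oracle <- vapply(seq_len(length(edges) - 1L), function(k) {
      lo <- edges[k]; hi <- edges[k + 1]
      idx <- seq(floor(lo) + 1L, ceiling(hi))
      w <- pmin(hi, idx) - pmax(lo, idx - 1L)
      sum(w * base[idx]) / (hi - lo)
    }, 0)
    expect_equal(unname(pm[1, ]), oracle, tolerance = 1e-9)
  }
})

test_that("uncovered bins fall back to zero", {
  track <- gr(1000, 2000)
  mcols(track)$score <- 4
  region <- gr(1200, 1800, names = "r")
  pm <- profileMatrix(track, region, flank = 500, bodyBins = 6,
                      flankBinSize = 100)
  # body fully covered at 4; outer flank bins beyond the track are 0
  expect_true(all(pm[1, 6:11] == 4))
  expect_true(pm[1, 1] == 0 && pm[1, 16] == 0)
})

test_that("mirroring regions and track leaves the mean profile unchanged", {
  L <- 50000L
  set.seed(3)
  cuts <- sort(sample(2:(L - 1), 15))
  s <- c(1L, cuts + 1L); e <- c(cuts, L)
  track <- gr(s, e)
  mcols(track)$score <- round(runif(length(s), 0, 5), 2)
  regions <- gr(c(10000, 30000), c(14000, 33000), strand = "+",
                names = c("a", "b"))
  pm <- profileMatrix(track, regions, flank = 1000, bodyBins = 12,
                      flankBinSize = 100)
  # mirror the coordinate system around the genome midpoint
  mirror <- function(g) gr(L - end(g) + 1L, L - start(g) + 1L,
                           strand = "-", names = names(g))
  mtrack <- gr(L - e + 1L, L - s + 1L)
  mcols(mtrack)$score <- track$score
  mpm <- profileMatrix(sort(mtrack), mirror(regions), flank = 1000,
                       bodyBins = 12, flankBinSize = 100)
  expect_equal(meanProfile(mpm), meanProfile(pm), tolerance = 1e-9)
})

test_that("mean profile averages regions and handles single rows", {
  track <- constTrack(10000, 1)
  r1 <- profileMatrix(track, gr(3000, 4000, names = "one"),
                      flank = 500, bodyBins = 4, flankBinSize = 100)
  expect_equal(meanProfile(r1), unname(r1[1, ]))
  # two constant regions at c1 and c2 average to (c1+c2)/2
  tr <- gr(c(1, 5001), c(5000, 10000))
  mcols(tr)$score <- c(2, 6)
  pm <- profileMatrix(tr, gr(c(1001, 6001), c(2000, 7000)),
                      flank = 0, bodyBins = 5, flankBinSize = 50)
  expect_equal(unname(meanProfile(pm)), rep(4, 5))
})

test_that("simulated enrichment shows up over the region body", {
  regions <- gr(c(20000, 60000), c(26000, 66000), names = c("r1", "r2"))
  track <- simulateSignalTrack(regions, "chr1", 1e5, enrichLevel = 6,
                               backgroundLevel = 1, noise = 0.3, seed = 2)
  pm <- profileMatrix(track, regions, flank = 5000, bodyBins = 20,
                      flankBinSize = 500)
  mp <- meanProfile(pm)
  body <- mp[11:30]; flank <- mp[c(1:10, 31:40)]
  expect_gt(mean(body), mean(flank) + 3)
})
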
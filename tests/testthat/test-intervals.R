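test_that("intersectAny follows closed-interval overlap semantics", {
  a <- gr(c(100, 100), c(199, 199), names = c("a1", "a2"))
  # half-open [100,200) vs [199,300) share base 199; vs [200,300) share none
  b <- gr(c(199, 200), c(299, 299), names = c("b1", "b2"))
  res <- intersectAny(a[1], b[1])
  expect_true(res$hit)
  res2 <- intersectAny(a[1], b[2])
  expect_false(res2$hit)
  # ids of overlapping features are reported per query
  both <- intersectAny(gr(150, 250), b)
  expect_setequal(as.character(both$ids[[1]]), c("b1", "b2"))
  # empty sets allowed
  expect_length(intersectAny(GRanges(), b)$hit, 0L)
})

test_that("subtract reproduces the intron construction", {
  gene <- gr(1, 1000)
  exons <- gr(c(1, 801), c(200, 1000))
  intr <- subtractIntervals(gene, exons)
  expect_identical(start(intr), 201L)
  expect_identical(end(intr), 800L)
  # a minus empty = a merged
  a <- gr(c(10, 15, 50), c(20, 30, 60))
  m <- subtractIntervals(a, GRanges())
  expect_identical(start(m), c(10L, 50L))
  expect_identical(end(m), c(30L, 60L))
})

test_that("intersect and subtract agree with a per-base oracle", {
  set.seed(71)
  L <- 10000L
  for (rep in 1:60) {
    a <- randIntervals(sample(3:25, 1), L)
    b <- randIntervals(sample(3:25, 1), L)
    expect_identical(intersectAny(a, b)$hit,
                     vapply(seq_along(a), function(i)
                       any(bfCover(a[i], L) & bfCover(b, L)), TRUE))
    sub <- subtractIntervals(a, b)
    oracle <- bfSubtract(a, b, L)
    expect_identical(ranges(sub), ranges(oracle))
  }
})

test_that("subtract satisfies the double-complement identity", {
  set.seed(5)
  L <- 10000L
  for (rep in 1:10) {
    a <- randIntervals(10, L); b <- randIntervals(10, L)
    # a \ (a \ b) covers exactly a intersect b
    lhs <- subtractIntervals(a, subtractIntervals(a, b))
    expect_identical(bfCover(lhs, L), bfCover(a, L) & bfCover(b, L))
  }
})

test_that("closest feature resolves direction, overlap and ties", {
  q <- gr(1000, 1099)
  feats <- gr(c(1200, 700), c(1300, 799), names = c("down", "up"))
  # 100 bp downstream beats 200 bp upstream
  res <- closestFeature(q, feats)
  expect_identical(res$id, "down")
  expect_identical(res$distance, 100)
  # overlap gives distance 0
  expect_identical(closestFeature(q, gr(1050, 1060, names = "in"))$distance, 0)
  # exact tie -> smaller start wins
  tie <- gr(c(1200, 800), c(1250, 899), names = c("right", "left"))
  expect_identical(closestFeature(q, tie)$id, "left")
  # no feature on the chromosome -> explicit no-neighbor result
  off <- closestFeature(q, gr(1, 10, chrom = "chr9", names = "x"))
  expect_true(is.na(off$id))
  expect_identical(off$note, "no neighbor")
})

test_that("closest matches its brute-force oracle on random instances", {
  set.seed(23)
  for (rep in 1:40) {
    q <- randIntervals(1, 10000L)
    f <- randIntervals(12, 10000L)
    res <- closestFeature(q, f)
    bf <- bfClosest(q, f)
    expect_identical(res$id, bf$id)
    expect_identical(abs(res$distance), as.numeric(bf$dist))
  }
})

test_that("containment counting uses 100%-within semantics", {
  region <- gr(100, 300)
  fr <- data.frame(read_id = c("r1", "r2"),
                   chrom1 = "chr1", start1 = c(150L, 250L), end1 = c(250L, 350L),
                   chrom2 = "chr1", start2 = c(160L, 260L), end2 = c(260L, 360L),
                   strand1 = "+", strand2 = "-", mapq = 60L,
                   proper_pair = TRUE, stringsAsFactors = FALSE)
  # r1: both mates inside; r2: both partial -> only r1's two mates count
  expect_identical(countContainedFragments(fr, region), 2L)
  # spliced read blocks [120,140)+[500,520): span and blocks both leave the region
  spliced <- GRangesList(r = gr(c(121, 501), c(140, 520)))
  expect_identical(countContainedFragments(spliced, region, splitBlocks = TRUE), 0L)
  expect_identical(countContainedFragments(spliced, region, splitBlocks = FALSE), 0L)
  # blocks contained in a split region set count only with splitBlocks
  two <- gr(c(100, 480), c(300, 600))
  expect_identical(countContainedFragments(spliced, two, splitBlocks = TRUE), 1L)
  expect_identical(countContainedFragments(spliced, two, splitBlocks = FALSE), 0L)
})

test_that("containment agrees with a per-base oracle", {
  set.seed(31)
  L <- 5000L
  for (rep in 1:40) {
    regions <- randIntervals(6, L)
    cov <- bfCover(regions, L)
    n <- 30L
    s1 <- sample.int(L - 100, n); s2 <- sample.int(L - 100, n)
    fr <- data.frame(read_id = sprintf("r%02d", 1:n),
                     chrom1 = "chr1", start1 = s1, end1 = s1 + 99L,
                     chrom2 = "chr1", start2 = s2, end2 = s2 + 99L,
                     strand1 = "+", strand2 = "-", mapq = 60L,
                     proper_pair = TRUE, stringsAsFactors = FALSE)
    oracle <- sum(vapply(s1, function(s) all(cov[s:(s + 99)]), TRUE)) +
      sum(vapply(s2, function(s) all(cov[s:(s + 99)]), TRUE))
    expect_identical(countContainedFragments(fr, regions), oracle)
  }
})

test_that("random intronic segments stay inside introns and are seeded", {
  introns <- gr(c(1000, 50000, 200000), c(20000, 58000, 300000))
  seg <- randomIntronicSegments(introns, 200L, 6000L, seed = 8)
  expect_length(seg, 200L)
  expect_identical(unique(width(seg)), 6000L)
  expect_true(all(IRanges::overlapsAny(seg, introns, type = "within")))
  expect_identical(seg, randomIntronicSegments(introns, 200L, 6000L, seed = 8))
  # single eligible intron of exactly the requested length -> all identical
  one <- randomIntronicSegments(gr(c(100, 900), c(6099, 1000)), 10L, 6000L,
                                seed = 2)
  expect_true(all(start(one) == 100L & end(one) == 6099L))
  expect_error(randomIntronicSegments(gr(1, 100), 5L, 6000L), "no intron")
})
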
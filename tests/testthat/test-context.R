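test_that("context classification partitions loci with exon precedence", {
  genes <- tinyGenes()
  l1 <- gr(c(5000, 1100, 100000, 39000),
           c(11000, 7000, 106000, 40050),
           names = c("intronic1", "exonTouch", "outside", "exonTouch2"))
  ctx <- classifyContext(l1, genes)
  expect_identical(ctx$context,
                   c("intronic", "exonic", "intergenic", "exonic"))
  # exactly one context each; counts sum to the total
  expect_identical(sum(table(ctx$context)), length(l1))
  expect_identical(ctx$host_gene, c("gA", "gA", NA, "gB"))
  # intron-precedence switch flips the mixed cases
  ctx2 <- classifyContext(l1, genes, exonPrecedence = FALSE)
  expect_identical(ctx2$context,
                   c("intronic", "intronic", "intergenic", "intronic"))
})

test_that("host assignment prefers the gene with the larger overlap", {
  genes <- tinyGenes()
  # locus spanning the gap [20000, 30000]: 1 bp in gA, 2001 bp in gB
  l1 <- gr(20000, 32000, names = "span")
  ctx <- classifyContext(l1, genes)
  expect_identical(ctx$host_gene, "gB")
})

test_that("overlap pairs reproduce the brute-force double loop", {
  set.seed(44)
  for (s in 1:6) {
    sp <- smallSim(s)
    run <- simToZ(sp)
    gcnt <- assay(run$sim$genesSE, "counts")
    gnorm <- normalizeCounts(gcnt, sizeFactorsMoR(gcnt))
    ztG <- perSampleZ(gnorm, run$sim$samples)
    smp <- "case_01"
    pairs <- deOverlapPairs(run$zt, ztG, run$ann$l1, run$ann$genes, smp)
    # brute force: every (upregulated L1) x (DE gene) interval overlap
    zl <- assay(run$zt, "z")[, smp]; zg <- assay(ztG, "z")[, smp]
    expected <- 0L
    for (i in names(zl)[!is.na(zl) & zl > 3]) {
      for (g in names(zg)[!is.na(zg) & abs(zg) > 3]) {
        gi <- run$ann$genes[g]; li <- run$ann$l1[i]
        if (as.character(seqnames(gi)) == as.character(seqnames(li)) &&
            start(gi) <= end(li) && end(gi) >= start(li))
          expected <- expected + 1L
      }
    }
    expect_identical(nrow(pairs), expected)
    if (nrow(pairs)) {
      expect_true(all(pairs$l1_z > 3))
      expect_true(all(abs(pairs$gene_z) > 3))
      expect_identical(pairs$gene_direction,
                       ifelse(pairs$gene_z > 0, "Upregulated", "Downregulated"))
    }
  }
})

test_that("anticorrelated genes follow the asymmetric cutoff rule", {
  genes <- tinyGenes()
  l1 <- gr(c(5000, 31000), c(11000, 37000), names = c("l1a", "l1b"))
  zL <- rbind(l1a = 4, l1b = 2.5); colnames(zL) <- "x01"
  zG <- rbind(gA = -0.5, gB = -5); colnames(zG) <- "x01"
  # l1a: z > 3 inside gA with negative gene z -> included without any
  # cutoff on the gene magnitude; l1b fails the L1 cutoff
  got <- anticorrelatedGenes(mkZT(zL), mkZT(zG), l1, genes, "x01")
  expect_identical(got, "gA")
  # positive gene z excluded even with an upregulated L1
  zG2 <- rbind(gA = 0.2, gB = -5); colnames(zG2) <- "x01"
  expect_length(anticorrelatedGenes(mkZT(zL), mkZT(zG2), l1, genes, "x01"), 0L)
})

test_that("anticorrelation recovery finds most coupled hosts", {
  hitRate <- vapply(1:10, function(s) {
    sp <- smallSim(s, anticorrPairs = 6L, anticorrFactor = 3,
                   geneDeCount = 10L)
    ann <- simulateAnnotation(sp)
    sim <- simulateCounts(sp, ann$genes, ann$l1)
    truthHosts <- sim$truth$feature_id[sim$truth$effect == "anticorr_host"]
    if (!length(truthHosts)) return(NA_real_)
    cntL <- assay(sim$l1SE, "counts"); cntG <- assay(sim$genesSE, "counts")
    ztL <- perSampleZ(normalizeCounts(cntL, sizeFactorsMoR(cntL)), sim$samples)
    ztG <- perSampleZ(normalizeCounts(cntG, sizeFactorsMoR(cntG)), sim$samples)
    affected <- strsplit(sim$truth$samples[1], ",")[[1]]
    found <- unique(unlist(lapply(affected, function(a)
      anticorrelatedGenes(ztL, ztG, ann$l1, ann$genes, a))))
    mean(truthHosts %in% found)
  }, 0)
  expect_gte(mean(hitRate, na.rm = TRUE), 0.8)
})

test_that("reference-set overlap counts match construction", {
  l1 <- gr(seq(1000, 10000, by = 1000), seq(1000, 10000, by = 1000) + 500,
           names = sprintf("l%02d", 1:10))
  # reference covering exactly 9 of the 10 loci
  ref <- list(FlnI = l1[1:9], FLI = l1[1], none = gr(90000, 91000))
  ov <- referenceSetOverlap(l1, ref)
  expect_identical(ov$matched[ov$set == "FlnI"], 9L)
  expect_equal(ov$fraction[ov$set == "FlnI"], 0.9)
  expect_identical(ov$matched[ov$set == "FLI"], 1L)
  expect_identical(ov$matched[ov$set == "none"], 0L)
})

test_that("gene-overlap percentages cover the boundary cases", {
  genes <- tinyGenes()
  inside <- gr(c(2000, 31000), c(3000, 32000))
  outside <- gr(c(100000, 200000), c(101000, 201000))
  threeOfFour <- c(inside, outside[1], gr(5000, 6000))
  res <- fractionInExpressedGenes(
    list(all_in = inside, none = outside, mixed = threeOfFour), genes)
  expect_equal(res$pct, c(100, 0, 75))
})
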
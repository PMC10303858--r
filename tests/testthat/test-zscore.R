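mkSheet <- function(nCtrl, nCase) {
  data.frame(
    sample_id = c(sprintf("c%02d", seq_len(nCtrl)),
                  sprintf("x%02d", seq_len(nCase))),
    group = rep(c("control", "case"), c(nCtrl, nCase)),
    dataset = "t", stringsAsFactors = FALSE)
}

test_that("case z scores match the direct arithmetic oracle", {
  m <- rbind(f1 = c(10, 20, 30, 40),
             f2 = c(5, 5, 5, 5),
             f3 = c(1, 2, 3, 2))
  colnames(m) <- c("c01", "c02", "c03", "x01")
  zt <- perSampleZ(m, mkSheet(3, 1))
  z <- assay(zt, "z"); st <- assay(zt, "status")
  # controls {10,20,30}: mean 20, sample sd 10 -> z(40) = 2, not called
  expect_equal(z["f1", "x01"], (40 - 20) / sd(c(10, 20, 30)))
  expect_equal(z["f1", "x01"], 2)
  expect_identical(st["f1", "x01"], "ns")
  # x equal to the control mean -> z = 0
  expect_equal(z["f3", "x01"], 0)
  # all controls equal -> sd 0 -> undefined, never DE
  expect_true(is.na(z["f2", "x01"]))
  expect_identical(st["f2", "x01"], "undefined")
})

test_that("controls are scored leave-one-out", {
  m <- rbind(f1 = c(10, 20, 30, 100))
  colnames(m) <- c("c01", "c02", "c03", "c04")
  sheet <- data.frame(sample_id = colnames(m), group = "control",
                      dataset = "t", stringsAsFactors = FALSE)
  z <- assay(perSampleZ(m, sheet), "z")
  # c04 compared against {10,20,30} only
  expect_equal(z["f1", "c04"], (100 - 20) / 10)
  # c01 against {20,30,100}
  expect_equal(z["f1", "c01"], (10 - 50) / sd(c(20, 30, 100)))
})

test_that("fewer than three controls is an error", {
  m <- rbind(f1 = c(1, 2, 3)); colnames(m) <- c("c01", "c02", "x01")
  expect_error(perSampleZ(m, mkSheet(2, 1)), "at least 3 control")
})

test_that("z is invariant to control order, shifts and positive scaling", {
  set.seed(20)
  m <- matrix(rpois(9 * 12, 50) + 1, 9, 12,
              dimnames = list(sprintf("f%d", 1:9), NULL))
  colnames(m) <- c(sprintf("c%02d", 1:9), sprintf("x%02d", 1:3))
  sheet <- mkSheet(9, 3)
  z0 <- assay(perSampleZ(m, sheet), "z")
  # permuting sample sheet rows never changes any z
  perm <- sheet[sample.int(nrow(sheet)), ]
  expect_equal(assay(perSampleZ(m, perm), "z")[, colnames(z0)], z0)
  # affine transforms of one feature across all samples leave z unchanged
  m2 <- m; m2["f3", ] <- 7 * m2["f3", ] + 100
  expect_equal(assay(perSampleZ(m2, sheet), "z")["f3", ], z0["f3", ])
})

test_that("population-sd variant applies the n denominator", {
  m <- rbind(f1 = c(10, 20, 30, 40))
  colnames(m) <- c("c01", "c02", "c03", "x01")
  zPop <- assay(perSampleZ(m, mkSheet(3, 1), sdType = "population"), "z")
  sdPop <- sqrt(mean((c(10, 20, 30) - 20)^2))
  expect_equal(zPop["f1", "x01"], 20 / sdPop)
})

test_that("DE calls use strict inequalities at the threshold", {
  # controls {1,2,3}: mean 2, sd 1 -> x=5 gives z exactly 3 -> ns
  m <- rbind(f1 = c(1, 2, 3, 5, 5.001, -1.001))
  colnames(m) <- c("c01", "c02", "c03", "x01", "x02", "x03")
  zt <- perSampleZ(m, mkSheet(3, 3))
  expect_equal(assay(zt, "z")["f1", "x01"], 3)
  expect_identical(assay(zt, "status")["f1", "x01"], "ns")
  expect_identical(assay(zt, "status")["f1", "x02"], "up")
  expect_identical(assay(zt, "status")["f1", "x03"], "down")
})

test_that("net upregulation subtracts down calls and skips undefined", {
  z <- rbind(f1 = c(3.5), f2 = c(-4), f3 = c(1), f4 = c(3.01), f5 = NA)
  colnames(z) <- "x01"
  nu <- netUpregulated(mkZT(z))
  expect_identical(nu$n_up, 2L)
  expect_identical(nu$n_down, 1L)
  expect_identical(nu$net, 1L)
  # all |z| < 3 -> net 0
  z2 <- matrix(c(1, -2, 0.5), 3, dimnames = list(NULL, "x01"))
  expect_identical(netUpregulated(mkZT(z2))$net, 0L)
})

test_that("log2 fold change handles pseudocounts as documented", {
  m <- rbind(f1 = c(20, 20, 20, 40),
             f2 = c(0, 0, 0, 40))
  colnames(m) <- c("c01", "c02", "c03", "x01")
  sheet <- mkSheet(3, 1)
  fc0 <- log2FoldChange(m, sheet, pseudocount = 0)
  expect_equal(fc0["f1", "x01"], 1)          # 40 vs mean 20
  expect_equal(fc0["f1", "c01"], 0)          # equal to LOO control mean
  fc1 <- log2FoldChange(m, sheet, pseudocount = 1)
  expect_equal(fc1["f2", "x01"], log2(41))   # zero control mean, eps = 1
})

test_that("per-sample DE counts tally both directions", {
  z <- rbind(f1 = c(4, 0), f2 = c(-5, 0), f3 = c(0, 0))
  colnames(z) <- c("x01", "x02")
  dc <- deGeneCounts(mkZT(z))
  expect_identical(dc$n_de, c(2L, 0L))
})

test_that("null case-call rate stays near the t reference", {
  # with 9 controls the case statistic is t(8) scaled by sqrt(1 + 1/9);
  # check the empirical rate over seeds against 1.5x that tail
  rates <- vapply(1:12, function(s) {
    run <- simToZ(calibSim(s, l1UpFraction = 0, geneDeCount = 0L,
                           anticorrPairs = 0L))
    st <- assay(run$zt, "status")[, run$sim$samples$group == "case"]
    mean(st == "up" | st == "down")
  }, 0)
  bound <- 1.5 * 2 * pt(-3 / sqrt(1 + 1 / 9), df = 8)
  expect_lt(mean(rates), bound)
})
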
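test_that("weightedCq computes log(E)*Cq at the printed worked values", {
  expect_close(weightedCq(1.836, 32.316), 8.527, 5e-4)
  expect_equal(weightedCq(10, 5), 5)                      # log10(10) = 1
  cq <- c(0.5, 7, 31.2)
  expect_equal(weightedCq(2, cq, base = 2), cq)           # log2(2) = 1
  expect_error(weightedCq(1.0, 30), "efficiency")
  expect_error(weightedCq(0.92, 30), "efficiency")        # E-1 style input
  expect_error(weightedCq(1.9, 30, base = 1), "base")
})

test_that("technical replicates average in weighted space", {
  w <- table1Weighted()
  agg <- aggregateTechnical(w)
  expect_close(agg$wcq[agg$sample_type == "A" & agg$gene == "g"],
               8.397, 5e-4)
  expect_equal(agg$n_wells, rep(3L, 6))
  # from raw (E, Cq): three B/ref2 wells
  raw <- data.frame(replicate = "r1", sample_type = "B", gene = "ref2",
                    efficiency = c(1.890, 1.883, 1.911),
                    cq = c(25.308, 25.256, 25.689))
  # printed mean derives from the display-rounded per-well column
  expect_close(aggregateTechnical(raw)$wcq, 7.054, 2e-3)
  # mean of one well is that well
  one <- raw[1, ]
  expect_equal(aggregateTechnical(one)$wcq,
               weightedCq(1.890, 25.308))
})

test_that("deltaCq subtracts the mean reference weighted Cq", {
  agg <- aggregateTechnical(table1Weighted())
  d <- deltaCq(agg, goi = "g", refs = c("ref1", "ref2"))
  expect_close(d$dcq[d$sample_type == "A"], 1.1387, 5e-5)
  expect_close(d$dcq[d$sample_type == "B"], 1.4077, 5e-5)
  # reference-order invariance
  d2 <- deltaCq(agg, goi = "g", refs = c("ref2", "ref1"))
  expect_equal(d2$dcq, d$dcq)
  # self-normalization: goi equal to the single reference gives 0
  selfagg <- data.frame(replicate = "r", sample_type = "A",
                        gene = c("g", "ref"), wcq = c(5.5, 5.5))
  expect_equal(deltaCq(selfagg, goi = "g", refs = "ref")$dcq, 0)
})

test_that("the full pipeline from raw wells matches printed values to
           display-rounding accuracy", {
  d <- deltaCq(examplePlate())
  # raw-path values differ from the printed chain only by the rounding of
  # log(E) in the printed per-well column
  expect_close(d$dcq[d$sample_type == "A"], 1.1387, 2e-3)
  expect_close(d$dcq[d$sample_type == "B"], 1.4077, 1e-2)
})

test_that("deltaDeltaCq: unpaired and paired estimates coincide on
           balanced data", {
  g <- unpairedGroups()
  expect_close(deltaDeltaCq(g$a, g$b), -0.546, 5e-4)
  expect_equal(deltaDeltaCq(g$a, g$b, paired = TRUE),
               deltaDeltaCq(g$a, g$b))
  expect_equal(deltaDeltaCq(g$a, g$a, paired = TRUE), 0)
  # paired mode matches replicate labels, and rejects unmatched ones
  a <- data.frame(replicate = c("r1", "r2"), dcq = c(1, 2))
  b <- data.frame(replicate = c("r2", "r1"), dcq = c(5, 3))
  expect_equal(deltaDeltaCq(a, b, paired = TRUE), mean(c(1 - 3, 2 - 5)))
  b$replicate <- c("r9", "r1")
  expect_error(deltaDeltaCq(a, b, paired = TRUE), "matching")
})

test_that("ratio back-transformation and interval reversal", {
  expect_close(ratioFromDeltaDelta(-0.546), 3.52, 5e-3)
  expect_equal(ratioFromDeltaDelta(0), 1)
  expect_equal(ratioFromDeltaDelta(1), 0.1)
  # the published (1.11, 11.12) pair is exactly the back-transform of
  # these rounded log bounds
  expect_close(backtransformInterval(c(-1.046, -0.047)),
               c(1.11, 11.12), 5e-3)
  expect_equal(backtransformInterval(c(0, 0)), c(1, 1))
  # negating the log interval reciprocates and reverses the ratio interval
  ci <- c(-0.8, 0.3)
  expect_equal(backtransformInterval(-rev(ci)),
               rev(1 / backtransformInterval(ci)))
  expect_error(backtransformInterval(c(1, -1)), "ordered")
})

test_that("geometric-mean identity: arithmetic mean in log scale equals
           the geometric mean", {
  set.seed(42)
  for (i in 1:10) {
    x <- exp(rnorm(7))
    for (b in c(10, 2, exp(1))) {
      expect_equal(b^(mean(log(x, base = b))),
                   prod(x)^(1 / length(x)), tolerance = 1e-12)
    }
  }
})

test_that("the ratio does not depend on the logarithm base", {
  set.seed(7)
  for (i in 1:10) {
    e <- runif(6, 1.7, 2.0); cq <- runif(6, 20, 34)
    w10 <- data.frame(replicate = "r", sample_type = rep(c("A", "B"), 3),
                      gene = rep(c("g", "ref1", "ref2"), each = 2),
                      efficiency = e, cq = cq)
    dd <- function(base) {
      d <- deltaCq(aggregateTechnical(w10, base = base),
                   goi = "g", refs = c("ref1", "ref2"))
      ratioFromDeltaDelta(d$dcq[d$sample_type == "A"] -
                            d$dcq[d$sample_type == "B"], base = base)
    }
    expect_equal(dd(10), dd(2), tolerance = 1e-12)
    expect_equal(dd(10), dd(exp(1)), tolerance = 1e-12)
  }
})

test_that("common-base ratio equals the Pfaffl oracle under gene-wise
           constant efficiencies, and the Livak oracle when E = 2", {
  set.seed(123)
  for (i in 1:20) {
    e_goi <- runif(1, 1.6, 2.1); e_ref <- runif(1, 1.6, 2.1)
    cq <- matrix(runif(12, 18, 34), nrow = 4)  # rows: goiA, goiB, refA, refB
    wellsdf <- data.frame(
      replicate = "r",
      sample_type = rep(rep(c("A", "B"), each = 3), 2),
      gene = rep(c("g", "ref"), each = 6),
      efficiency = rep(c(e_goi, e_ref), each = 6),
      cq = c(cq[1, 1:3], cq[2, 1:3], cq[3, 1:3], cq[4, 1:3]))
    d <- deltaCq(aggregateTechnical(wellsdf), goi = "g", refs = "ref")
    r_cb <- ratioFromDeltaDelta(d$dcq[d$sample_type == "A"] -
                                  d$dcq[d$sample_type == "B"])
    r_pf <- pfafflRatio(cq[1, 1:3], cq[3, 1:3], cq[2, 1:3], cq[4, 1:3],
                        e_goi = e_goi, e_ref = e_ref)
    expect_equal(r_cb, r_pf, tolerance = 1e-12)
  }
  # all E = 2: Pfaffl collapses to Livak and so does the common base
  cq <- runif(12, 18, 34)
  wells2 <- data.frame(replicate = "r",
                       sample_type = rep(rep(c("A", "B"), each = 3), 2),
                       gene = rep(c("g", "ref"), each = 6),
                       efficiency = 2, cq = cq)
  d <- deltaCq(aggregateTechnical(wells2), goi = "g", refs = "ref")
  r_cb <- ratioFromDeltaDelta(d$dcq[d$sample_type == "A"] -
                                d$dcq[d$sample_type == "B"])
  r_lv <- livakRatio(cq[1:3], cq[7:9], cq[4:6], cq[10:12])
  expect_equal(r_cb, r_lv, tolerance = 1e-12)
  expect_equal(pfafflRatio(cq[1:3], cq[7:9], cq[4:6], cq[10:12], 2, 2),
               r_lv, tolerance = 1e-12)
})
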
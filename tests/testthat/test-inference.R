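test_that("unpaired Welch test reproduces the worked two-sample example", {
  g <- unpairedGroups()
  res <- unpairedTest(g$a, g$b)
  expect_close(res@estimate, -0.546, 5e-4)
  expect_close(res@statistic, -3.60, 5e-3)
  expect_close(res@p.value, 0.019, 5e-4)
  expect_close(res@conf.int, c(-0.949, -0.143), 5e-4)
  expect_close(expressionRatio(res), 3.52, 5e-3)
  # Welch df is kept non-integer
  expect_gt(res@df, 4); expect_lt(res@df, 5)
  # invariants tying the slots together
  expect_true(res@conf.int[1] <= res@estimate &&
                res@estimate <= res@conf.int[2])
  expect_equal(expressionRatio(res),
               ratioFromDeltaDelta(logEstimate(res)))
  expect_equal(ratioConfInt(res), backtransformInterval(logConfInt(res)))
})

test_that("pooled-variance mode matches the classical closed form", {
  set.seed(21)
  for (i in 1:10) {
    a <- rnorm(5); b <- rnorm(7, mean = 0.4)
    res <- unpairedTest(a, b, var.equal = TRUE)
    # independent closed-form pooled t
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
      (length(a) + length(b) - 2)
    t_exp <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    expect_equal(res@statistic, t_exp, tolerance = 1e-12)
    expect_equal(res@df, length(a) + length(b) - 2)
  }
})

test_that("degenerate two-group inputs are rejected", {
  expect_error(unpairedTest(1.2, c(1, 2)), ">= 2 values")
  expect_error(unpairedTest(c(1, 1), c(2, 2)), "zero variance")
  expect_error(pairedTest(c(1, 2, 3), c(0, 1, 2)), "identical")
  expect_error(pairedTest(1, 2), ">= 2 pairs")
})

test_that("paired test reproduces the worked paired example", {
  g <- unpairedGroups()
  res <- pairedTest(g$a, g$b)
  expect_close(res@estimate, -0.546, 5e-4)
  expect_close(res@statistic, -3.48, 5e-3)
  expect_equal(res@df, 3)
  expect_close(res@p.value, 0.040, 5e-4)
  expect_close(res@conf.int, c(-1.046, -0.047), 5e-4)
  expect_close(expressionRatio(res), 3.52, 5e-3)
  expect_close(ratioConfInt(res)[1], 1.11, 5e-3)
  # the printed upper bound 11.12 is the back-transform of the rounded log
  # bound; full precision gives ~11.11
  expect_close(ratioConfInt(res)[2], 11.11, 5e-3)
})

test_that("swapping the groups mirrors a paired analysis exactly", {
  g <- unpairedGroups()
  ab <- pairedTest(g$a, g$b); ba <- pairedTest(g$b, g$a)
  expect_equal(ba@estimate, -ab@estimate)
  expect_equal(ba@statistic, -ab@statistic)
  expect_equal(ba@conf.int, -rev(ab@conf.int))
  expect_equal(ba@p.value, ab@p.value)
  expect_equal(expressionRatio(ba), 1 / expressionRatio(ab))
  expect_equal(ratioConfInt(ba), rev(1 / ratioConfInt(ab)))
})

test_that("plate-blocked ANOVA partitions plate variation out of the
           error term", {
  res <- blockedAnova(plateBlockedData(), blocks = "plate")
  src <- res@sources
  expect_close(src$ms[src$source == "sample_type"], 0.096, 5e-4)
  expect_close(src$ms[src$source == "plate"], 0.153, 5e-4)
  expect_equal(src$df[src$source == "Error"], 8)
  # published F values were computed from unrounded source data and are
  # reproduced from the printed inputs to ~0.5%
  expect_equal(src$f[src$source == "sample_type"], 12.864, tolerance = 0.01)
  expect_equal(src$f[src$source == "plate"], 20.487, tolerance = 0.01)
  expect_close(src$p[src$source == "sample_type"], 0.003, 5e-4)
  # balanced decomposition: component SS add to the total
  comp <- src$ss[src$source != "Total"]
  expect_equal(sum(comp), src$ss[src$source == "Total"], tolerance = 1e-9)
  # post-hoc at printed precision
  ph <- posthocPairwise(res)
  ab <- ph[ph$level_a == "A" & ph$level_b == "B", ]
  expect_close(ab$diff, -0.269, 5e-4)
  expect_close(ab$ratio, 1.86, 5e-3)
  expect_close(c(ab$ratio_ci_lower, ab$ratio_ci_upper), c(1.34, 2.57), 5e-3)
  expect_close(ab$p_adjusted, 0.007, 5e-4)
  ac <- ph[ph$level_a == "A" & ph$level_b == "C", ]
  expect_close(ac$ratio, 1.00, 6e-3)
  expect_equal(ac$p_adjusted, 1)                 # Bonferroni capping
})

test_that("without blocking the same data shows no sample-type effect", {
  res <- blockedAnova(plateBlockedData())        # empty block list
  src <- res@sources
  # the printed F itself derives from unrounded source data
  expect_close(src$f[src$source == "sample_type"], 4.064, 2e-3)
  expect_equal(src$df[src$source == "sample_type"], 2)
  expect_equal(src$df[src$source == "Error"], 9)
  expect_close(src$p[src$source == "sample_type"], 0.055, 5e-4)
})

test_that("individual-blocked ANOVA reproduces the paired three-organ
           example", {
  res <- blockedAnova(individualBlockedData(), blocks = "replicate")
  src <- res@sources
  expect_close(src$f[src$source == "sample_type"], 20.222, 6e-4)
  expect_close(src$f[src$source == "replicate"], 2.237, 5e-4)
  expect_close(src$ms[src$source == "sample_type"], 0.342, 5e-4)
  expect_close(src$ms[src$source == "Error"], 0.017, 5e-4)
  ph <- posthocPairwise(res)
  bc <- ph[ph$level_a == "B" & ph$level_b == "C", ]
  expect_close(bc$diff, 0.506, 5e-4)
  expect_close(bc$ratio, 0.31, 5e-3)
  expect_close(c(bc$ratio_ci_lower, bc$ratio_ci_upper), c(0.19, 0.52), 5e-3)
  expect_close(bc$p_adjusted, 0.005, 5e-4)
})

test_that("a two-level blocked ANOVA is the paired t-test (F = t^2)", {
  set.seed(99)
  for (i in 1:5) {
    a <- rnorm(5); b <- rnorm(5, 0.5)
    d <- data.frame(dcq = c(a, b),
                    sample_type = rep(c("A", "B"), each = 5),
                    replicate = rep(paste0("r", 1:5), 2))
    aov_res <- blockedAnova(d, blocks = "replicate")
    t_res <- pairedTest(a, b)
    src <- aov_res@sources
    expect_equal(src$f[src$source == "sample_type"], t_res@statistic^2,
                 tolerance = 1e-9)
    expect_equal(src$p[src$source == "sample_type"], t_res@p.value,
                 tolerance = 1e-9)
    # the single post-hoc comparison reproduces the ANOVA p
    ph <- posthocPairwise(aov_res)
    expect_equal(nrow(ph), 1L)
    expect_equal(ph$t^2, src$f[src$source == "sample_type"],
                 tolerance = 1e-9)
    expect_equal(ph$p_adjusted, src$p[src$source == "sample_type"],
                 tolerance = 1e-9)
  }
})

test_that("shifting every delta-Cq by a constant changes nothing", {
  g <- unpairedGroups()
  r1 <- unpairedTest(g$a, g$b); r2 <- unpairedTest(g$a + 3.7, g$b + 3.7)
  expect_equal(r2@statistic, r1@statistic)
  expect_equal(r2@p.value, r1@p.value)
  expect_equal(expressionRatio(r2), expressionRatio(r1))
  d <- plateBlockedData(); d2 <- d; d2$dcq <- d2$dcq - 11
  a1 <- blockedAnova(d, blocks = "plate")
  a2 <- blockedAnova(d2, blocks = "plate")
  expect_equal(a2@sources$f, a1@sources$f)
  expect_equal(posthocPairwise(a2)$ratio, posthocPairwise(a1)$ratio)
})

test_that("CI and test agree: the interval excludes 0 iff p < alpha", {
  set.seed(314)
  for (i in 1:20) {
    a <- rnorm(4); b <- rnorm(4, mean = runif(1, 0, 1.5))
    for (conf in c(0.9, 0.95)) {
      res <- unpairedTest(a, b, conf.level = conf)
      excludes <- res@conf.int[1] > 0 || res@conf.int[2] < 0
      expect_equal(excludes, res@p.value < 1 - conf)
    }
  }
})

test_that("degenerate and malformed designs are rejected informatively", {
  d <- plateBlockedData()
  # a sample type entirely missing from a block names the cell
  d_bad <- d[!(d$sample_type == "C" & d$plate == "p2"), ]
  expect_error(blockedAnova(d_bad, blocks = "plate"),
               "sample type 'C' has no observation in plate 'p2'")
  # constant response: SS = 0 and F undefined, but no error
  d_const <- d; d_const$dcq <- 1.5
  res <- blockedAnova(d_const, blocks = "plate")
  expect_equal(res@sources$ss, rep(0, nrow(res@sources)))
  expect_true(all(is.na(res@sources$f)))
  expect_equal(nrow(posthocPairwise(res)), 0L)
  # single level
  expect_error(blockedAnova(d[d$sample_type == "A", ], blocks = "plate"),
               ">= 2 sample-type levels")
  # unbalanced but complete: marginal decomposition with a warning,
  # harmonic-mean n flagged in the post-hoc table
  d_unb <- rbind(d, data.frame(dcq = 0.7, sample_type = "A", plate = "p1"))
  expect_warning(expect_warning(
    res_unb <- blockedAnova(d_unb, blocks = "plate"),
    "marginal"), "harmonic")
  ph <- suppressWarnings(posthocPairwise(res_unb))
  expect_lt(ph$n_eff[ph$level_a == "A" & ph$level_b == "B"], 4.5)
})

test_that("advisory normality screen warns but never fails", {
  skewed <- c(0.01, 0.02, 0.05, 0.1, 8, 9, 30, 80)
  ref <- rnorm(8)
  set.seed(5)
  expect_warning(unpairedTest(skewed, ref, check.assumptions = TRUE),
                 "advisory")
  res <- suppressWarnings(unpairedTest(skewed, ref,
                                       check.assumptions = TRUE))
  expect_s4_class(res, "CommonBaseTest")
})
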
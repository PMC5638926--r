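test_that("standardization divides branch rates and applies the omission rule", {
  r <- standardizeDN(c(0.02, 0.02, 0.0), c(0.04, 0.0, 0.03))
  expect_equal(r$ratio[1], 0.5)
  expect_true(r$omitted[2])    # zero reference rate: impossible to standardize
  expect_true(r$omitted[3])    # zero focal rate: impossible to standardize
  expect_true(all(is.na(r$ratio[2:3])))
  expect_error(standardizeDN(-0.1, 0.2), "non-negative")
  expect_error(standardizeDN(Inf, 0.2), "finite")
})

test_that("standardization is scale-equivariant", {
  set.seed(2)
  x <- runif(50); y <- runif(50)
  for (c_ in c(0.1, 3, 1000)) {
    expect_equal(standardizeDN(c_ * x, c_ * y)$ratio,
                 standardizeDN(x, y)$ratio)
  }
})

test_that("Grubbs screen flags a gross outlier and matches the t-quantile form", {
  x <- c(1.0, 1.1, 0.9, 1.05, 8.0)
  expect_equal(grubbsOutliers(x, alpha = 0.005), 5L)
  # direct critical-value cross-check at n = 5
  n <- 5
  tq <- qt(0.005 / (2 * n), n - 2, lower.tail = FALSE)
  crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
  g <- max(abs(x - mean(x)) / sd(x))
  expect_true(g > crit)
  expect_equal(SymbiontErosion:::.grubbs_critical(n, 0.005), crit)
})

test_that("Grubbs screen rejects degenerate input", {
  expect_error(grubbsOutliers(c(1, 1, 1)), "variance")
  expect_error(grubbsOutliers(c(1, 2)), "n >= 3")
})

test_that("Grubbs flags are invariant under affine transformation", {
  set.seed(6)
  x <- c(rnorm(40), 9, -7)
  expect_equal(grubbsOutliers(3 * x - 10), grubbsOutliers(x))
  expect_equal(grubbsOutliers(-2 * x + 1), grubbsOutliers(x))
})

test_that("Grubbs false-flag rate on clean normal samples stays below 1%", {
  flagged <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    length(grubbsOutliers(rnorm(1000), alpha = 0.005)) > 0
  }, logical(1))
  expect_lte(mean(flagged), 0.01)
})

test_that("rank-sum test: exact small-sample value and null behaviour", {
  r <- pathwayRelaxationTest(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r$p_greater, 1 / 20)
  expect_equal(r$direction, "greater")
  same <- pathwayRelaxationTest(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_gt(same$p_two_sided, 0.99)
  expect_error(pathwayRelaxationTest(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("relaxed pathway is detected in most simulated replicates", {
  # chlorophyll-pathway genes evolved at 3x omega on the endosymbiont
  # branch; standardized ratios tested against the background
  topo <- single_sb(0.05)
  n_pw <- 10; n_bg <- 300
  hits <- vapply(1:50, function(s) {
    p_bg <- simParams(n_bg, 300, omega = 0.2, seed = 5000 + s)
    p_pw <- simParams(n_pw, 300, omega = c(.default = 0.2, SB1 = 0.6),
                      seed = 6000 + s)
    bg <- estimateBranchRatesFromStates(simulateOrthologSet(topo, p_bg), topo)
    pw <- estimateBranchRatesFromStates(simulateOrthologSet(topo, p_pw), topo)
    ratio_of <- function(brt) {
      m <- dnMatrix(brt, c("SB1", "OUTANC"))
      standardizeDN(m[, 1], m[, 2])$ratio
    }
    rp <- ratio_of(pw); rb <- ratio_of(bg)
    pathwayRelaxationTest(rp[!is.na(rp)], rb[!is.na(rb)])$p_greater < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("signed-rank test: exact value, symmetry and antisymmetry", {
  r <- pairedRateTest(c(1, 2, 3, 4, 5, 6))
  expect_equal(r$p_value, 2 / 64)
  expect_equal(r$mean_delta, 3.5)
  sym <- pairedRateTest(c(-1, 1, -2, 2, -3, 3, -4, 4))
  expect_gte(sym$p_value, 0.99)
  a <- pairedRateTest(c(0.3, -1.2, 2.5, 0.7, -0.4, 1.8, 0.9))
  b <- pairedRateTest(-c(0.3, -1.2, 2.5, 0.7, -0.4, 1.8, 0.9))
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$mean_delta, -b$mean_delta)
})

test_that("signed-rank test drops zeros but keeps them in the mean", {
  r <- pairedRateTest(c(0, 0, 1, 2, 3, 4, 5, 6))
  expect_equal(r$n_nonzero, 6)
  expect_equal(r$n_total, 8)
  expect_equal(r$mean_delta, mean(c(0, 0, 1:6)))
  expect_equal(r$p_value, 2 / 64)
  expect_error(pairedRateTest(c(0, 0, 0)), "zero")
  expect_error(pairedRateTest(c(1, 2, 3)), "at least 6")
})

test_that("erosionAnalysis assembles a consistent report", {
  topo <- two_sb()
  p <- simParams(120, 150, omega = c(.default = 0.2, SB2 = 0.3), seed = 808)
  brt <- estimateBranchRatesFromStates(simulateOrthologSet(topo, p), topo)
  rep <- erosionAnalysis(brt, topo, std_branch_y = "OUTANC")
  m <- dnMatrix(brt, c("SB1", "SB2"))
  expect_equal(nrow(deltaRecords(rep)), sum(rowSums(is.na(m)) == 0))
  expect_equal(deltaRecords(rep)$delta,
               deltaRecords(rep)$dn_sb1 - deltaRecords(rep)$dn_sb2)
  expect_true(all(c("mean_delta", "p_value") %in% names(pairedTest(rep))))
  std <- standardizedRates(rep)
  expect_true(all(is.na(std$ratio[std$omitted])))
  expect_true(all(std$ratio[!std$omitted] > 0))
})
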
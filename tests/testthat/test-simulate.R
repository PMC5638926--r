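test_that("simulation is byte-reproducible given (seed, gene_index)", {
  topo <- two_sb()
  p <- simParams(5, 40, seed = 42)
  a <- simulateGeneAlignment(topo, p, 3)
  b <- simulateGeneAlignment(topo, p, 3)
  expect_identical(alignedRows(a), alignedRows(b))
  d <- simulateGeneAlignment(topo, simParams(5, 40, seed = 43), 3)
  expect_false(identical(alignedRows(a), alignedRows(d)))
})

test_that("zero branch lengths copy the root sequence to every leaf", {
  topo <- two_sb()
  p <- simParams(2, 30, seed = 1, branch_lengths = 0)
  rows <- alignedRows(simulateGeneAlignment(topo, p, 1))
  expect_length(unique(rows), 1L)
})

test_that("omega = 0 forbids amino-acid change on every branch", {
  topo <- two_sb()
  p <- simParams(3, 80, omega = 0, branch_lengths = 0.3, seed = 5)
  for (g in 1:3) {
    prots <- translateCDS(alignedRows(simulateGeneAlignment(topo, p, g)))
    expect_length(unique(prots), 1L)
  }
})

test_that("leaf sequences contain no stop codons or gaps", {
  topo <- two_sb()
  p <- simParams(3, 60, omega = 0.5, branch_lengths = 0.2, seed = 9)
  rows <- alignedRows(simulateGeneAlignment(topo, p, 2))
  expect_false(any(grepl("-", rows, fixed = TRUE)))
  expect_false(any(grepl("\\*", translateCDS(rows))))
})

test_that("invalid parameters are rejected", {
  expect_error(simParams(10, 50, codon_frequencies = rep(1 / 60, 61)),
               "simplex")
  expect_error(simParams(0, 50), ">= 1")
  expect_error(simParams(10, 50, omega = -1), "non-negative")
  topo <- two_sb()
  expect_error(simulateGeneAlignment(topo, simParams(2, 10, seed = 1), 5),
               "out of range")
})

test_that("simulated divergence matches the generator-integral oracle", {
  # OUT1 and OUT2 are separated by two branches; compare mean pairwise
  # NG86 dN against the analytic expectation from the instantaneous rates
  topo <- two_sb(0.05)
  p <- simParams(500, 300, kappa = 2, omega = 0.1, seed = 101)
  sim <- simulateOrthologSet(topo, p)
  sense <- senseCodons()
  dn <- vapply(split(seq_along(sim$gene), sim$gene), function(cols) {
    pairwiseNG86(sense[sim$states["OUT1", cols]],
                 sense[sim$states["OUT2", cols]])$dN
  }, numeric(1))
  expected <- oracle_expected_dn(kappa = 2, omega = 0.1, t_total = 0.1)
  expect_lt(abs(mean(dn) - expected) / expected, 0.20)
})

test_that("per-gene and batch simulators agree in distribution", {
  topo <- two_sb()
  p <- simParams(200, 100, omega = 0.2, seed = 77)
  sim <- simulateOrthologSet(topo, p)
  batch_dn <- rateTable(estimateBranchRatesFromStates(sim, topo))
  batch_mean <- mean(batch_dn$dN[batch_dn$branch == "SB1"], na.rm = TRUE)
  alns <- lapply(1:200, function(g) simulateGeneAlignment(topo, p, g))
  per <- rateTable(estimateBranchRates(alns, topo))
  per_mean <- mean(per$dN[per$branch == "SB1"], na.rm = TRUE)
  expect_lt(abs(batch_mean - per_mean) / per_mean, 0.25)
})
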
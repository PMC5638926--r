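test_that("invariant columns reconstruct to the shared codon", {
  topo <- two_sb()
  aln <- CodonAlignment(setNames(rep("ATGATG", 5), taxonNames(topo)))
  anc <- reconstructAncestralCodons(aln, topo)
  expect_true(all(anc == "ATG"))
})

test_that("balanced 4-leaf column splits into the two observed codons", {
  topo <- simTopology(newick = "((L1:1,L2:1):1,(L3:1,L4:1):1);")
  aln <- CodonAlignment(c(L1 = "AAA", L2 = "AAA", L3 = "AAG", L4 = "AAG"))
  anc <- reconstructAncestralCodons(aln, topo)
  internal <- anc[setdiff(rownames(anc), taxonNames(topo)), 1]
  expect_setequal(unique(internal[c("N2", "N3")]), c("AAA", "AAG"))
  # total cost 1: exactly one change along the whole tree
  post <- SymbiontErosion:::.topo_postorder(topo)
  lab <- rownames(anc)
  cost <- sum(vapply(seq_len(nrow(post)), function(e)
    nt_diff(anc[post$parent[e], 1], anc[post$child[e], 1]), numeric(1)))
  expect_equal(cost, 1)
})

test_that("reconstruction cost equals exhaustive Sankoff on random 4-leaf columns", {
  topo <- simTopology(newick = "((L1:1,L2:1):1,(L3:1,L4:1):1);")
  post <- SymbiontErosion:::.topo_postorder(topo)
  sense <- senseCodons()
  set.seed(31)
  for (k in 1:200) {
    leaves <- sample(sense, 4, replace = TRUE)
    aln <- CodonAlignment(setNames(leaves, c("L1", "L2", "L3", "L4")))
    anc <- reconstructAncestralCodons(aln, topo)
    cost <- sum(vapply(seq_len(nrow(post)), function(e)
      nt_diff(anc[post$parent[e], 1], anc[post$child[e], 1]), numeric(1)))
    expect_equal(cost, oracle_sankoff_cost_4leaf(leaves),
                 label = paste(leaves, collapse = " "))
  }
})

test_that("zero-change alignments give zero dN on every branch", {
  topo <- two_sb()
  aln <- CodonAlignment(setNames(rep("ATGAAACCCGGG", 5), taxonNames(topo)))
  df <- rateTable(estimateBranchRates(aln, topo))
  expect_true(all(df$dN == 0))
  expect_true(all(df$Nd == 0))
})

test_that("two-taxon branch dN sums to the pairwise NG86 estimate", {
  # GCA -> CCA is a single-nucleotide non-synonymous change between codons
  # with identical site partitions, so the additive-branch and pairwise
  # estimates must coincide to numerical precision at low divergence
  expect_equal(codonSiteClasses("GCA"), codonSiteClasses("CCA"),
               ignore_attr = TRUE)
  topo <- simTopology(newick = "(A:0.1,B:0.1);")
  filler <- rep("ATG", 1999)
  rows <- c(A = paste(c("GCA", filler), collapse = ""),
            B = paste(c("CCA", filler), collapse = ""))
  df <- rateTable(estimateBranchRates(CodonAlignment(rows), topo))
  pw <- pairwiseNG86(rows[["A"]], rows[["B"]])
  expect_equal(sum(df$dN), pw$dN, tolerance = 1e-9)
  expect_equal(sum(df$Nd), pw$Nd)
})

test_that("raising omega on one branch raises that branch's mean dN", {
  topo <- two_sb()
  means <- vapply(c(0.05, 0.2, 0.5), function(w) {
    p <- simParams(150, 150, omega = c(.default = 0.2, SB1 = w), seed = 55)
    df <- rateTable(estimateBranchRatesFromStates(
      simulateOrthologSet(topo, p), topo))
    mean(df$dN[df$branch == "SB1"], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("estimated branch dN tracks simulator truth with slope near 1", {
  topo <- two_sb(0.05)
  grid <- c(0.05, 0.2, 0.5)
  est <- true <- numeric(0)
  for (w in grid) {
    p <- simParams(500, 300, kappa = 2, omega = w, seed = 200 + round(100 * w))
    df <- rateTable(estimateBranchRatesFromStates(
      simulateOrthologSet(topo, p), topo))
    est <- c(est, mean(df$dN[df$branch == "SB1"], na.rm = TRUE))
    true <- c(true, oracle_expected_dn(2, w, 0.05))
  }
  slope <- coef(lm(est ~ true))[["true"]]
  expect_gt(slope, 0.8)
  expect_lt(slope, 1.2)
})

test_that("missing taxa are reported", {
  topo <- two_sb()
  aln <- CodonAlignment(c(SB1 = "ATG", SB2 = "ATG"))
  expect_error(estimateBranchRates(aln, topo), "missing taxa")
})
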
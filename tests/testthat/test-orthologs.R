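test_that("self-score is the BLOSUM62 diagonal sum", {
  expect_equal(scoreProteinPair("MKV", "MKV"), 5 + 5 + 4)
})

test_that("length-1 score equals exhaustive enumeration over alignments", {
  # the only alignments of two length-1 proteins: substitute, or gap both
  for (pair in list(c("M", "K"), c("W", "W"), c("A", "V"), c("C", "P"))) {
    expect_equal(scoreProteinPair(pair[1], pair[2]),
                 oracle_len1_score(pair[1], pair[2]),
                 label = paste(pair, collapse = "/"))
  }
})

test_that("alignment score is symmetric on random pairs", {
  set.seed(3)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:25) {
    a <- paste(sample(aas, sample(30:60, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(30:60, 1), replace = TRUE), collapse = "")
    expect_equal(scoreProteinPair(a, b), scoreProteinPair(b, a))
  }
})

test_that("empty sequences are rejected", {
  expect_error(scoreProteinPair("", "MKV"), "empty")
})

make_random_proteins <- function(n, len, seed) {
  set.seed(seed)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  setNames(vapply(seq_len(n), function(i)
    paste(sample(aas, len, replace = TRUE), collapse = ""), character(1)),
    sprintf("g%03d", seq_len(n)))
}

test_that("identical gene sets pair every gene with its copy", {
  prots <- make_random_proteins(12, 60, seed = 8)
  rbh <- reciprocalBestHits(prots, setNames(prots, names(prots)))
  expect_equal(nrow(rbh), 12)
  expect_equal(rbh$idA, rbh$idB)
})

test_that("tied top scores exclude the gene from pairing", {
  a <- c(a1 = "MKVLAEKRTGWYHDEQNSAPFCIMKVLAEKRTGW")
  b <- c(b1 = a[["a1"]], b2 = a[["a1"]])   # two identical partners: tie
  rbh <- reciprocalBestHits(a, b)
  expect_equal(nrow(rbh), 0)
})

test_that("RBH output is a matching and robust to an unrelated added gene", {
  prots <- make_random_proteins(10, 60, seed = 21)
  other <- make_random_proteins(10, 60, seed = 22)
  names(other) <- sprintf("h%03d", 1:10)
  rbh0 <- reciprocalBestHits(prots, other)
  expect_false(anyDuplicated(rbh0$idA) > 0)
  expect_false(anyDuplicated(rbh0$idB) > 0)
  # add one unrelated random gene: existing confident pairs survive
  extra <- c(other, make_random_proteins(1, 60, seed = 99))
  names(extra)[11] <- "extra"
  rbh1 <- reciprocalBestHits(prots, extra)
  expect_true(all(paste(rbh0$idA, rbh0$idB) %in%
                    paste(rbh1$idA, rbh1$idB) |
                  rbh0$idA %in% rbh1$idA[rbh1$idB == "extra"]))
})

test_that("short genes are excluded from pairing", {
  a <- c(s1 = "MKV", g1 = make_random_proteins(1, 50, 4)[[1]])
  rbh <- reciprocalBestHits(a, a)
  expect_equal(rbh$idA, "g1")
})

test_that("fabricated genome pair without lesions pairs every ortholog to truth", {
  topo <- two_sb()
  fab <- fabricateGenomePair(topo, simParams(60, 120, seed = 13))
  rbh <- reciprocalBestHits(fab$genomes$A$proteins, fab$genomes$B$proteins)
  expect_equal(nrow(rbh), 60)
  expect_equal(rbh$idA, rbh$idB)   # fabricated orthologs share identifiers
})

test_that("star extension marks completeness per taxon", {
  topo <- two_sb()
  fab <- fabricateGenomePair(topo, simParams(15, 120, seed = 17))
  sets <- c(list(SB1 = fab$genomes$A$proteins, SB2 = fab$genomes$B$proteins),
            lapply(fab$outgroups, `[[`, "proteins"))
  tup <- orthologTuples(sets)
  expect_equal(nrow(tup), 15)
  expect_true(all(c("SB1", "SB2", "OUT1", "OUT2", "OUT3") %in% names(tup)))
  expect_true(any(tup$complete))
  f <- tempfile(fileext = ".tsv")
  writeOrthologTable(tup, f)
  expect_equal(readOrthologTable(f)$SB1, tup$SB1)
})
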
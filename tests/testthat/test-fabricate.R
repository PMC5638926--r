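test_that("lesion specifications are validated", {
  expect_error(lesionSpec("g", "A", "FRAMESHIFT_INS", payload = 3L),
               "divisible")
  expect_error(lesionSpec("g", "A", "NONSENSE"), "unknown lesion kind")
  expect_error(lesionSpec("g", "C", "DELETION"), "genome")
})

test_that("no lesions: full gene complement, all truth statuses INTACT", {
  topo <- two_sb()
  fab <- fabricateGenomePair(topo, simParams(20, 60, seed = 5))
  expect_equal(length(fab$genomes$A$cds), 20)
  expect_equal(length(fab$genomes$B$cds), 20)
  expect_true(all(fab$truth$status == "INTACT"))
  expect_equal(length(fab$genomes$A$annotation), 20)
})

test_that("a premature-stop lesion plants a stop codon at the stated position", {
  topo <- two_sb()
  les <- lesionSpec("gene_0003", "B", "PREMATURE_STOP", position = 10L)
  fab <- fabricateGenomePair(topo, simParams(10, 60, seed = 6), lesions = les)
  tr <- fab$truth[fab$truth$gene_id == "gene_0003" & fab$truth$genome == "B", ]
  expect_equal(tr$status, "PSEUDOGENE")
  # locate the damaged gene in the genome and read codon 10 (0-based)
  loci <- fab$genomes$B$loci
  hit <- loci[loci$ID == "gene_0003"]
  seg <- Biostrings::subseq(fab$genomes$B$sequence,
                            GenomicRanges::start(hit), GenomicRanges::end(hit))
  if (as.character(GenomicRanges::strand(hit)) == "-")
    seg <- Biostrings::reverseComplement(seg)
  expect_equal(as.character(Biostrings::subseq(seg, 31, 33)), "TAA")
  # lesioned gene is excluded from the intact annotation and protein set
  expect_false("gene_0003" %in% fab$genomes$B$annotation$ID)
  expect_false("gene_0003" %in% names(fab$genomes$B$proteins))
  expect_true("gene_0003" %in% names(fab$genomes$A$proteins))
})

test_that("the two-pathway erosion profile yields the documented truth counts", {
  topo <- two_sb()
  pw <- pathwayDefinitions()
  fab <- fabricateGenomePair(topo, simParams(40, 150, seed = 2),
                             pathways = pw,
                             lesions = erosionLesionProfile(150))
  tr <- unique(fab$truth[, c("gene_id", "genome", "status")])
  chl <- pw$gene_id[pw$pathway == "chlorophyll_a"]
  b12 <- pw$gene_id[pw$pathway == "vitamin_b12" & !pw$excluded]
  a_chl <- tr[tr$genome == "A" & tr$gene_id %in% chl, ]
  expect_equal(sum(a_chl$status == "PSEUDOGENE"), 1)   # bciB only
  expect_equal(sum(a_chl$status == "INTACT"), 9)
  b_b12 <- tr[tr$genome == "B" & tr$gene_id %in% b12, ]
  expect_equal(sum(b_b12$status != "INTACT"), 14)      # 14 of the 17
  expect_equal(sum(b_b12$status == "ABSENT"), 2)
  expect_equal(sum(b_b12$status == "INTACT"), 3)
  # genome A's vitamin B12 genes are untouched
  a_b12 <- tr[tr$genome == "A" & tr$gene_id %in% b12, ]
  expect_true(all(a_b12$status == "INTACT"))
})

test_that("fabrication is byte-reproducible", {
  topo <- two_sb()
  p <- simParams(8, 50, seed = 77)
  les <- lesionSpec("gene_0002", "B", "FRAMESHIFT_DEL", 5L, 1L)
  f1 <- fabricateGenomePair(topo, p, lesions = les)
  f2 <- fabricateGenomePair(topo, p, lesions = les)
  expect_identical(as.character(f1$genomes$A$sequence),
                   as.character(f2$genomes$A$sequence))
  expect_identical(as.character(f1$genomes$B$sequence),
                   as.character(f2$genomes$B$sequence))
  expect_identical(f1$truth, f2$truth)
})

test_that("every intact CDS translates without internal stops", {
  topo <- two_sb()
  fab <- fabricateGenomePair(topo, simParams(30, 80, seed = 30),
                             lesions = erosionLesionProfile(80),
                             pathways = pathwayDefinitions())
  for (gn in c("A", "B")) {
    prots <- fab$genomes[[gn]]$proteins
    expect_false(any(grepl("*", prots, fixed = TRUE)))
  }
})

test_that("conflicting lesions are rejected", {
  topo <- two_sb()
  p <- simParams(5, 50, seed = 1)
  both <- rbind(lesionSpec("gene_0001", "B", "DELETION"),
                lesionSpec("gene_0001", "B", "PREMATURE_STOP", 3L))
  expect_error(fabricateGenomePair(topo, p, lesions = both), "deleted gene")
  dup <- rbind(lesionSpec("gene_0001", "B", "PREMATURE_STOP", 3L),
               lesionSpec("gene_0001", "B", "FRAMESHIFT_INS", 3L))
  expect_error(fabricateGenomePair(topo, p, lesions = dup), "overlapping")
  ghost <- lesionSpec("nope", "B", "DELETION")
  expect_error(fabricateGenomePair(topo, p, lesions = ghost), "not fabricated")
  beyond <- lesionSpec("gene_0001", "B", "PREMATURE_STOP", 500L)
  expect_error(fabricateGenomePair(topo, p, lesions = beyond), "beyond")
})

test_that("fabricated genomes serialize to the standard formats", {
  topo <- two_sb()
  fab <- fabricateGenomePair(topo, simParams(6, 40, seed = 12))
  dir <- tempfile()
  writeFabricatedGenomes(fab, dir)
  fa <- Biostrings::readDNAStringSet(file.path(dir, "genomeA.fna"))
  expect_equal(unname(Biostrings::width(fa)),
               length(fab$genomes$A$sequence))
  gff <- rtracklayer::import(file.path(dir, "genomeA.gff3"))
  expect_equal(length(gff), 6)
  expect_setequal(as.character(gff$ID), names(fab$genomes$A$cds))
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth), nrow(fab$truth))
})
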
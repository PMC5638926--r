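# a fixed, deterministic CDS used as the clean reference throughout
make_cds <- function(n_codons = 120, seed = 19) {
  set.seed(seed)
  body <- paste(sample(setdiff(senseCodons(), c("ATG")), n_codons - 1,
                       replace = TRUE), collapse = "")
  paste0("ATG", body, "TAA")
}

test_that("a clean CDS aligns in a single frame with full coverage", {
  cds <- make_cds()
  prot <- translateCDS(cds)
  hit <- frameshiftAwareAlign(prot, cds)
  expect_equal(hit$n_shifts, 0)
  expect_equal(hit$n_stops, 0)
  expect_equal(hit$coverage, 1)
  expect_equal(hit$strand, "+")
})

test_that("a single deleted base is found as one frame switch near its site", {
  cds <- make_cds(150)
  prot <- translateCDS(cds)
  # delete 1 nt inside codon 50 (1-based codon coordinates)
  at <- 3 * 49 + 2
  mut <- paste0(substr(cds, 1, at - 1), substr(cds, at + 1, nchar(cds)))
  hit <- frameshiftAwareAlign(prot, mut)
  expect_equal(hit$n_shifts, 1)
  expect_lte(abs(hit$shifts - 50), 3)
  expect_equal(hit$n_stops, 0)
})

test_that("an in-frame stop is crossed and reported at its codon", {
  cds <- make_cds(150)
  prot <- translateCDS(cds)
  at <- 3 * 49 + 1
  mut <- paste0(substr(cds, 1, at - 1), "TAA", substr(cds, at + 3, nchar(cds)))
  hit <- frameshiftAwareAlign(prot, mut)
  expect_equal(hit$n_stops, 1)
  expect_equal(hit$stops, 50)
})

test_that("alignment is strand-symmetric", {
  cds <- make_cds(100)
  prot <- translateCDS(cds)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  fwd <- frameshiftAwareAlign(prot, cds)
  rev <- frameshiftAwareAlign(prot, rc)
  expect_equal(rev$score, fwd$score)
  expect_equal(rev$strand, "-")
})

test_that("window shorter than one codon is rejected", {
  expect_error(frameshiftAwareAlign("MKV", "ATGAAA"), "9 nt")
})

test_that("classification rules map alignment features to statuses", {
  cds <- make_cds(150)
  prot <- translateCDS(cds)
  self <- SymbiontErosion:::.self_score(prot)
  clean <- frameshiftAwareAlign(prot, cds)
  expect_equal(classifyGene(clean, self), "INTACT")
  # stop + frameshift: two evidence classes, PSEUDOGENE
  at <- 3 * 49 + 1
  mut <- paste0(substr(cds, 1, at - 1), "TAA", substr(cds, at + 3, nchar(cds)))
  mut <- paste0(substr(mut, 1, 250), substr(mut, 252, nchar(mut)))
  hit <- frameshiftAwareAlign(prot, mut)
  expect_gte(hit$n_stops, 1)
  expect_gte(hit$n_shifts, 1)
  expect_equal(classifyGene(hit, self), "PSEUDOGENE")
  # unrelated sequence: ABSENT
  junk <- make_cds(150, seed = 999)
  expect_equal(classifyGene(frameshiftAwareAlign(prot, junk), self), "ABSENT")
})

scan_fixture <- function() {
  topo <- two_sb()
  pw <- pathwayDefinitions()
  fab <- fabricateGenomePair(topo, simParams(40, 300, seed = 7),
                             pathways = pw,
                             lesions = erosionLesionProfile(300))
  fill <- fab$outgroups[[1]]$proteins
  protA <- fab$genomes$A$proteins
  protB <- fab$genomes$B$proteins
  list(fab = fab, pw = pw,
       refs_for_B = c(protA, fill[setdiff(fab$gene_ids, names(protA))]),
       refs_for_A = c(protB, fill[setdiff(fab$gene_ids, names(protB))]))
}

test_that("scan recovers the injected truth exactly, with no false calls", {
  fx <- scan_fixture()
  stA <- scanGenome(fx$refs_for_A, fx$fab$genomes$A$sequence,
                    fx$fab$genomes$A$annotation, genome_id = "A")
  stB <- scanGenome(fx$refs_for_B, fx$fab$genomes$B$sequence,
                    fx$fab$genomes$B$annotation, genome_id = "B")
  called <- rbind(statusTable(stA), statusTable(stB))
  truth <- unique(fx$fab$truth[, c("gene_id", "genome", "status")])
  m <- merge(truth, called, by = c("gene_id", "genome"))
  expect_equal(nrow(m), nrow(truth))
  expect_equal(m$status.y, m$status.x)
  # zero false calls on un-lesioned genes is implied by exact agreement
  intact <- m[m$status.x == "INTACT", ]
  expect_true(all(intact$status.y == "INTACT"))

  # pathway matrix reproduces the documented erosion pattern
  pm <- pathwayStatusMatrix(list(stA, stB), fx$pw)
  chl <- pm$matrix[pm$matrix$pathway == "chlorophyll_a", ]
  expect_equal(sum(chl$A == "PSEUDOGENE"), 1)
  expect_equal(sum(chl$A == "INTACT"), 9)
  expect_equal(chl$gene_id[chl$A == "PSEUDOGENE"], "bciB")
  b12 <- pm$matrix[pm$matrix$pathway == "vitamin_b12", ]
  expect_equal(sum(b12$B != "INTACT"), 14)
  expect_true(all(b12$A == "INTACT"))
})

test_that("statuses are invariant under reverse-complementing the genome", {
  topo <- two_sb()
  fab <- fabricateGenomePair(topo, simParams(8, 200, seed = 44),
                             lesions = lesionSpec("gene_0004", "B",
                                                  "PREMATURE_STOP", 60L))
  fill <- fab$outgroups[[1]]$proteins
  refs <- c(fab$genomes$A$proteins,
            fill[setdiff(fab$gene_ids, names(fab$genomes$A$proteins))])
  g <- fab$genomes$B
  st1 <- scanGenome(refs, g$sequence, g$annotation, genome_id = "B")
  L <- length(g$sequence)
  rc <- Biostrings::reverseComplement(g$sequence)
  ann <- g$annotation
  flipped <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(ann),
    ranges = IRanges::IRanges(start = L - GenomicRanges::end(ann) + 1L,
                              end = L - GenomicRanges::start(ann) + 1L),
    strand = ifelse(as.character(GenomicRanges::strand(ann)) == "+", "-", "+"),
    ID = ann$ID)
  st2 <- scanGenome(refs, rc, flipped, genome_id = "B")
  t1 <- statusTable(st1); t2 <- statusTable(st2)
  expect_equal(t2$status[match(t1$gene_id, t2$gene_id)], t1$status)
})

test_that("pathway matrix errors when a pathway gene was never scanned", {
  st <- GeneStatusMatrix(data.frame(
    gene_id = "chlB", genome = "A", status = "INTACT", coverage = 1,
    evidence = ""))
  expect_error(pathwayStatusMatrix(st, pathwayDefinitions()), "not scanned")
})
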
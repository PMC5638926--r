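## Fabrication of an annotated endosymbiont genome pair with known ground
## truth. Each ortholog is simulated on the species topology; the SB1 and
## SB2 leaf sequences become the genes of genomes A and B, the outgroup
## leaves become free-living CDS sets. Gene lesions (premature stops,
## frameshifts, truncations, whole-gene deletions) are then injected at
## specified codon positions, and every injected lesion is recorded in a
## truth table. Lesioned genes keep their (damaged) sequence in the genome
## but are dropped from the annotation and from the intact CDS/protein
## sets -- they are exactly what the pseudogene scanner must rediscover in
## non-coding sequence.

.LESION_KINDS <- c("PREMATURE_STOP", "FRAMESHIFT_INS", "FRAMESHIFT_DEL",
                   "TRUNCATION", "DELETION")

#' Specify gene lesions
#'
#' Builds a validated lesion table for [fabricateGenomePair()].
#'
#' @param gene_id Gene identifier (character).
#' @param genome `"A"` or `"B"`.
#' @param kind One of PREMATURE_STOP, FRAMESHIFT_INS, FRAMESHIFT_DEL,
#'   TRUNCATION, DELETION.
#' @param position 0-based codon index of the lesion within the CDS
#'   (ignored for DELETION).
#' @param payload Number of inserted/deleted bases for frameshifts (must
#'   not be divisible by 3), ignored otherwise.
#' @return data.frame of lesions (vectorized over its arguments).
#' @export
#' @examples
#' lesionSpec("bciB", "A", c("FRAMESHIFT_DEL", "PREMATURE_STOP"), c(40, 80))
lesionSpec <- function(gene_id, genome, kind, position = 0L, payload = 1L) {
  df <- data.frame(gene_id = gene_id, genome = genome, kind = kind,
                   position = as.integer(position),
                   payload = as.integer(payload), stringsAsFactors = FALSE)
  bad <- !df$kind %in% .LESION_KINDS
  if (any(bad)) stop("unknown lesion kind: ", paste(unique(df$kind[bad]), collapse = ", "))
  fs <- grepl("^FRAMESHIFT", df$kind)
  if (any(df$payload[fs] %% 3L == 0L))
    stop("frameshift payloads must not be divisible by 3")
  if (any(df$position < 0L)) stop("positions are 0-based codon indices >= 0")
  if (!all(df$genome %in% c("A", "B"))) stop("genome must be 'A' or 'B'")
  df
}

#' The two-pathway erosion lesion profile
#'
#' A ready-made lesion table reproducing the characteristic asymmetric
#' erosion pattern of the two endosymbiont genomes: in genome A a single
#' chlorophyll-a pathway gene (bciB) is disrupted by a frameshift plus an
#' in-frame stop, while in genome B 14 of the 17 analysed cobalamin
#' pathway genes are pseudogenized (stops, frameshifts, severe
#' truncations) or deleted outright.
#'
#' Truncations are placed so that just under half of the reference protein
#' survives: long enough that the remnant is still recognizably the gene
#' (above the presence score floor), short enough to fall below the
#' severe-truncation coverage threshold. Truncations cutting far more of
#' the gene lose recognizability altogether and are called ABSENT rather
#' than PSEUDOGENE -- a detectability limit, not an error.
#'
#' @param codons_per_gene Codon length the genes will be fabricated with
#'   (positions scale with it; default 300).
#' @return Lesion data.frame as produced by [lesionSpec()].
#' @export
erosionLesionProfile <- function(codons_per_gene = 300) {
  b12 <- c("cbiA", "cbiB", "cbiC", "cbiD", "cbiE", "cbiF", "cbiG", "cbiH",
           "cbiJ", "cbiK", "cbiL", "cbiT", "cobA", "cobQ")   # 14 of the 17
  kinds <- rep(c("PREMATURE_STOP", "FRAMESHIFT_INS", "FRAMESHIFT_DEL",
                 "TRUNCATION", "DELETION"), length.out = length(b12))
  mid <- as.integer(round(codons_per_gene / 3))
  trunc_at <- as.integer(round(0.48 * (codons_per_gene + 2)))
  rbind(
    lesionSpec("bciB", "A", c("FRAMESHIFT_DEL", "PREMATURE_STOP"),
               position = as.integer(round(c(0.15, 0.3) * codons_per_gene)),
               payload = c(1L, 1L)),
    lesionSpec(b12, "B", kinds,
               position = ifelse(kinds == "TRUNCATION", trunc_at, mid),
               payload = ifelse(kinds == "FRAMESHIFT_DEL", 2L, 1L))
  )
}

## apply one gene's lesions to its CDS (nucleotide string); returns the
## damaged sequence, or NA_character_ for deletion
.apply_lesions <- function(cds, lesions) {
  if ("DELETION" %in% lesions$kind) {
    if (nrow(lesions) > 1L)
      stop("lesion on a deleted gene: ", lesions$gene_id[1])
    return(NA_character_)
  }
  n_codons <- nchar(cds) %/% 3L
  if (any(lesions$position >= n_codons))
    stop("lesion position beyond gene length for ", lesions$gene_id[1])
  if (anyDuplicated(lesions$position))
    stop("overlapping lesions at the same position in ", lesions$gene_id[1])
  ## apply right-to-left so earlier codon indices stay valid
  lesions <- lesions[order(-lesions$position), , drop = FALSE]
  for (i in seq_len(nrow(lesions))) {
    pos <- lesions$position[i]
    at <- 3L * pos                      # nt offset of codon start
    cds <- switch(lesions$kind[i],
      PREMATURE_STOP = paste0(substr(cds, 1L, at), "TAA",
                              substr(cds, at + 4L, nchar(cds))),
      FRAMESHIFT_INS = paste0(substr(cds, 1L, at),
                              strrep("A", lesions$payload[i]),
                              substr(cds, at + 1L, nchar(cds))),
      FRAMESHIFT_DEL = paste0(substr(cds, 1L, at),
                              substr(cds, at + 1L + lesions$payload[i],
                                     nchar(cds))),
      TRUNCATION = substr(cds, 1L, at))
  }
  cds
}

#' Fabricate an annotated genome pair with injected lesions
#'
#' Simulates `n_genes` ortholog families on the topology and assembles two
#' annotated genomes (A = SB1 leaf, B = SB2 leaf): genes are laid out in
#' order, on random strands, separated by uniform-random intergenic
#' spacers of 50-500 nt. Every CDS gets a start codon and a terminal stop.
#' Lesions are injected per [lesionSpec()]; lesioned genes remain in the
#' genome sequence but are removed from the annotation and the intact
#' CDS/protein sets, and deleted genes are removed entirely. Outgroup leaf
#' sequences are returned as free-living CDS sets. Reproducible: byte-
#' identical output for identical `(params, lesions)`.
#'
#' @param topology A two-endosymbiont [simTopology()].
#' @param params A [simParams()] bundle; `n_genes` genes are fabricated.
#' @param pathways Optional pathway table (`pathway`, `gene_id`,
#'   `excluded`); non-excluded pathway genes name the first genes, the
#'   rest are `gene_0001`, ... Pathway gene lists must be disjoint.
#' @param lesions Lesion data.frame from [lesionSpec()] /
#'   [erosionLesionProfile()], or `NULL` for none.
#' @return List with elements `genomes` (per genome: `sequence`
#'   (DNAString), `annotation` (GRanges of intact CDS), `cds`, `proteins`
#'   (named vectors)), `outgroups` (per taxon: `cds`, `proteins`), `truth`
#'   (data.frame gene_id, genome, status, lesion_kind, position) and
#'   `gene_ids`.
#' @export
fabricateGenomePair <- function(topology, params, pathways = NULL,
                                lesions = NULL) {
  stopifnot(inherits(topology, "SimTopology"), inherits(params, "SimParams"))
  if (!identical(topology$mode, "two-sb"))
    stop("genome fabrication needs the two-endosymbiont topology")
  n <- params$n_genes
  ids <- sprintf("gene_%04d", seq_len(n))
  if (!is.null(pathways)) {
    pw <- pathways
    if (!is.null(pw$excluded)) pw <- pw[!pw$excluded, , drop = FALSE]
    if (anyDuplicated(pw$gene_id))
      stop("pathway gene lists must be disjoint")
    take <- seq_len(min(nrow(pw), n))   # small runs carry a pathway subset
    ids[take] <- pw$gene_id[take]
  }
  if (!is.null(lesions) && !all(lesions$gene_id %in% ids))
    stop("lesioned gene IDs not fabricated: ",
         paste(setdiff(lesions$gene_id, ids), collapse = ", "))

  ## simulate ortholog families gene by gene (per-gene reproducible)
  taxa <- topology$tree$tip.label
  cds <- matrix(NA_character_, n, length(taxa), dimnames = list(ids, taxa))
  for (g in seq_len(n)) {
    aln <- simulateGeneAlignment(topology, params, g)
    rows <- alignedRows(aln)
    cds[g, ] <- paste0("ATG", rows[taxa], "TAA")
  }

  truth_rows <- list()
  genomes <- list()
  for (gn in c("A", "B")) {
    taxon <- if (gn == "A") "SB1" else "SB2"
    seqs <- stats::setNames(cds[, taxon], ids)
    les <- if (is.null(lesions)) NULL else lesions[lesions$genome == gn, , drop = FALSE]
    status <- stats::setNames(rep("INTACT", n), ids)
    damaged <- seqs
    if (!is.null(les) && nrow(les)) {
      for (gid in unique(les$gene_id)) {
        lg <- les[les$gene_id == gid, , drop = FALSE]
        damaged[[gid]] <- .apply_lesions(seqs[[gid]], lg)
        status[[gid]] <- if ("DELETION" %in% lg$kind) "ABSENT" else "PSEUDOGENE"
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          gene_id = gid, genome = gn, status = status[[gid]],
          lesion_kind = lg$kind, position = lg$position,
          stringsAsFactors = FALSE)
      }
    }
    intact <- names(status)[status == "INTACT"]
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      gene_id = intact, genome = gn, status = "INTACT",
      lesion_kind = NA_character_, position = NA_integer_,
      stringsAsFactors = FALSE)

    ## assemble: spacer + gene + spacer + gene ... + spacer
    present <- names(damaged)[!is.na(damaged)]
    asm <- .with_seed(.mix_seed(params$seed, 10L^6 + match(gn, c("A", "B"))), {
      spacer <- function() paste(sample(.NUC, sample(50:500, 1L),
                                        replace = TRUE), collapse = "")
      strand <- sample(c("+", "-"), length(present), replace = TRUE)
      segs <- character(0)
      starts <- ends <- integer(length(present))
      off <- 0L
      for (k in seq_along(present)) {
        sp <- spacer()
        gene_nt <- damaged[[present[k]]]
        placed <- if (strand[k] == "+") gene_nt else
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(gene_nt)))
        segs <- c(segs, sp, placed)
        starts[k] <- off + nchar(sp) + 1L
        ends[k] <- starts[k] + nchar(gene_nt) - 1L
        off <- ends[k]
      }
      segs <- c(segs, spacer())
      list(seq = paste(segs, collapse = ""), starts = starts, ends = ends,
           strand = strand)
    })
    keep <- status[present] == "INTACT"
    ann <- GenomicRanges::GRanges(
      seqnames = paste0("genome", gn),
      ranges = IRanges::IRanges(start = asm$starts[keep], end = asm$ends[keep]),
      strand = asm$strand[keep],
      type = "CDS", ID = present[keep], phase = 0L)
    genomes[[gn]] <- list(
      sequence = Biostrings::DNAString(asm$seq),
      annotation = ann,
      loci = GenomicRanges::GRanges(
        seqnames = paste0("genome", gn),
        ranges = IRanges::IRanges(start = asm$starts, end = asm$ends),
        strand = asm$strand, ID = present),
      cds = damaged[names(damaged) %in% present[keep]],
      proteins = vapply(damaged[names(damaged) %in% present[keep]],
                        translateCDS, character(1)))
  }

  outgroups <- lapply(stats::setNames(nm = setdiff(taxa, c("SB1", "SB2"))),
    function(tx) {
      s <- stats::setNames(cds[, tx], ids)
      list(cds = s, proteins = vapply(s, translateCDS, character(1)))
    })

  truth <- do.call(rbind, truth_rows)
  truth <- truth[order(truth$genome, match(truth$gene_id, ids)), , drop = FALSE]
  rownames(truth) <- NULL
  list(genomes = genomes, outgroups = outgroups, truth = truth,
       gene_ids = ids)
}

#' Write fabricated genomes to standard formats
#'
#' Emits, per genome, a nucleotide FASTA, a GFF3 annotation of the intact
#' CDS features, CDS and protein FASTA files, plus a TSV truth table.
#'
#' @param fab Result of [fabricateGenomePair()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
writeFabricatedGenomes <- function(fab, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (gn in names(fab$genomes)) {
    g <- fab$genomes[[gn]]
    fa <- file.path(dir, sprintf("genome%s.fna", gn))
    s <- Biostrings::DNAStringSet(list(g$sequence))
    names(s) <- paste0("genome", gn)
    Biostrings::writeXStringSet(s, fa)
    gff <- file.path(dir, sprintf("genome%s.gff3", gn))
    rtracklayer::export(g$annotation, gff, format = "gff3")
    cdsf <- file.path(dir, sprintf("genome%s_cds.fna", gn))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(g$cds), cdsf)
    protf <- file.path(dir, sprintf("genome%s_proteins.faa", gn))
    Biostrings::writeXStringSet(Biostrings::AAStringSet(g$proteins), protf)
    paths <- c(paths, fa, gff, cdsf, protf)
  }
  for (tx in names(fab$outgroups)) {
    f <- file.path(dir, sprintf("%s_cds.fna", tx))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(fab$outgroups[[tx]]$cds), f)
    fp <- file.path(dir, sprintf("%s_proteins.faa", tx))
    Biostrings::writeXStringSet(Biostrings::AAStringSet(fab$outgroups[[tx]]$proteins), fp)
    paths <- c(paths, f, fp)
  }
  tf <- file.path(dir, "truth.tsv")
  utils::write.table(fab$truth, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, tf))
}
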
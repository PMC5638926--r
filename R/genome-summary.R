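## Genome overview statistics and functional-repertoire set comparison.

#' Genome summary statistics
#'
#' Computes the genome-overview numbers: chromosome length, GC fraction
#' (G+C over unambiguous A/C/G/T only), protein-coding gene and pseudogene
#' counts from the annotation's feature types, and the fraction of the
#' genome covered by annotated features.
#'
#' @param sequence Genome sequence: a `DNAString`/`DNAStringSet`, a plain
#'   string, or the path of a FASTA file.
#' @param annotation Optional `GRanges` with a `type` metadata column, or
#'   the path of a GFF3 file.
#' @param genome_id Label for the summary row.
#' @return One-row data.frame: `genome`, `length_bp`, `gc_fraction`,
#'   `coding_genes`, `pseudogenes`, `annotated_fraction`.
#' @export
#' @examples
#' genomeSummary("GGCC")$gc_fraction   # 1
genomeSummary <- function(sequence, annotation = NULL, genome_id = "genome") {
  if (is.character(sequence) && length(sequence) == 1L && file.exists(sequence))
    sequence <- Biostrings::readDNAStringSet(sequence)
  if (is.character(sequence))
    sequence <- Biostrings::DNAStringSet(sequence)
  if (methods::is(sequence, "DNAString"))
    sequence <- Biostrings::DNAStringSet(list(sequence))
  af <- colSums(Biostrings::alphabetFrequency(sequence))
  total_len <- sum(Biostrings::width(sequence))
  acgt <- sum(af[c("A", "C", "G", "T")])
  gc <- if (acgt > 0) sum(af[c("G", "C")]) / acgt else NA_real_
  coding <- pseudo <- 0L
  annfrac <- NA_real_
  if (!is.null(annotation)) {
    if (is.character(annotation)) annotation <- rtracklayer::import(annotation)
    type <- as.character(annotation$type)
    if (!length(type)) type <- rep("CDS", length(annotation))
    coding <- sum(type == "CDS")
    if (!coding) coding <- sum(type == "gene")
    pseudo <- sum(type == "pseudogene")
    covered <- sum(IRanges::width(IRanges::reduce(IRanges::ranges(annotation))))
    annfrac <- covered / total_len
  }
  data.frame(genome = genome_id, length_bp = total_len, gc_fraction = gc,
             coding_genes = coding, pseudogenes = pseudo,
             annotated_fraction = annfrac, stringsAsFactors = FALSE)
}

#' Compare two functional-identifier repertoires
#'
#' Exact set comparison of (deduplicated) identifier sets, e.g. the KO ID
#' repertoires of two genomes.
#'
#' @param idsA,idsB Character vectors of identifiers.
#' @return list: `shared`, `uniqueA`, `uniqueB` (counts), `shared_ids`,
#'   `uniqueA_ids`, `uniqueB_ids`, `nA`, `nB`.
#' @export
#' @examples
#' compareIdSets(c("k1", "k2"), c("k2", "k3"))[c("shared", "uniqueA", "uniqueB")]
compareIdSets <- function(idsA, idsB) {
  a <- unique(idsA); b <- unique(idsB)
  sh <- intersect(a, b)
  ua <- setdiff(a, b); ub <- setdiff(b, a)
  list(shared = length(sh), uniqueA = length(ua), uniqueB = length(ub),
       shared_ids = sh, uniqueA_ids = ua, uniqueB_ids = ub,
       nA = length(a), nB = length(b))
}
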
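## Protein multiple alignment (deterministic star/progressive merging)
## and codon back-threading: each amino-acid column is expanded to its
## source codon, so downstream counting operates on codons that really
## occur in the CDS.

## one pairwise global alignment of s against centre c, summarized on
## centre coordinates: ins[k] = residues of s inserted after centre
## position k (k = 0..Lc), and chr[k] = the character of s aligned to
## centre position k ("-" for deletion)
.align_to_centre <- function(s, centre) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(s), Biostrings::AAString(centre), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  Lc <- nchar(centre)
  ins <- vector("list", Lc + 1L)
  for (k in seq_len(Lc + 1L)) ins[[k]] <- character(0)
  chr <- character(Lc)
  k <- 0L
  for (i in seq_along(as)) {
    if (as[i] == "-") {
      ins[[k + 1L]] <- c(ins[[k + 1L]], ap[i])
    } else {
      k <- k + 1L
      chr[k] <- ap[i]
    }
  }
  list(ins = ins, chr = chr)
}

#' Deterministic protein multiple alignment
#'
#' Aligns a set of proteins by pairwise global alignment (BLOSUM62,
#' affine 11/1) of every sequence against a fixed centre sequence, then
#' merges the pairwise alignments on the centre's coordinates
#' ("once a gap, always a gap"). The centre is the first sequence in
#' `guide_order` (default: input order), so with the species-topology
#' taxon order the focal endosymbiont anchors the alignment. Deterministic.
#'
#' @param proteins Named character vector of protein sequences (>= 2).
#' @param guide_order Optional character vector of names; the first is the
#'   centre.
#' @return Named character vector of aligned rows (equal lengths).
#' @export
#' @examples
#' alignProteinSet(c(a = "MKV", b = "MV"))
alignProteinSet <- function(proteins, guide_order = NULL) {
  if (length(proteins) < 2L) stop("need at least two sequences")
  if (is.null(names(proteins)) || anyDuplicated(names(proteins)))
    stop("proteins must carry unique names")
  if (any(!nzchar(proteins))) stop("empty protein sequence")
  ord <- if (is.null(guide_order)) names(proteins)
         else c(guide_order, setdiff(names(proteins), guide_order))
  ord <- ord[ord %in% names(proteins)]
  centre_name <- ord[1L]
  centre <- proteins[[centre_name]]
  others <- ord[-1L]
  prs <- lapply(proteins[others], .align_to_centre, centre = centre)
  Lc <- nchar(centre)
  ins_max <- integer(Lc + 1L)
  for (p in prs) ins_max <- pmax(ins_max, lengths(p$ins))
  cchr <- strsplit(centre, "")[[1]]
  build_row <- function(ins, chr) {
    parts <- character(0)
    for (k in 0:Lc) {
      seg <- ins[[k + 1L]]
      pad <- strrep("-", ins_max[k + 1L] - length(seg))
      parts <- c(parts, paste0(paste(seg, collapse = ""), pad),
                 if (k < Lc) chr[k + 1L] else NULL)
    }
    paste(parts, collapse = "")
  }
  empty_ins <- lapply(seq_len(Lc + 1L), function(i) character(0))
  out <- c(stats::setNames(build_row(empty_ins, cchr), centre_name),
           vapply(prs, function(p) build_row(p$ins, p$chr), character(1)))
  out[names(proteins)]
}

#' Thread codons through a protein alignment
#'
#' Expands every amino-acid column of a protein alignment to the source
#' codon of each sequence's CDS; gap columns become `"---"`. Each CDS must
#' translate exactly (translation table 11, a terminal stop codon is
#' allowed and stripped) to its degapped protein row -- a mismatch signals
#' an annotation/CDS inconsistency and is an error.
#'
#' @param protein_alignment Named character vector of aligned protein rows.
#' @param cds Named character vector of nucleotide CDS, names matching the
#'   alignment rows.
#' @param geneID Optional gene identifier for the result.
#' @return A [CodonAlignment-class].
#' @export
#' @examples
#' backThreadCodons(c(a = "M-K"), c(a = "ATGAAA"))
backThreadCodons <- function(protein_alignment, cds, geneID = NA_character_) {
  nm <- names(protein_alignment)
  if (is.null(nm) || !all(nm %in% names(cds)))
    stop("CDS missing for row(s): ",
         paste(setdiff(nm, names(cds)), collapse = ", "))
  rows <- vapply(nm, function(tx) {
    prot <- protein_alignment[[tx]]
    codons <- .split_codons(toupper(cds[[tx]]))[[1]]
    aa <- .translate_codons(codons)
    if (length(aa) && aa[length(aa)] == "*") {
      aa <- aa[-length(aa)]
      codons <- codons[-length(codons)]
    }
    res <- strsplit(prot, "")[[1]]
    if (sum(res != "-") != length(aa) ||
        !identical(paste(aa, collapse = ""), paste(res[res != "-"], collapse = "")))
      stop("CDS of '", tx, "' does not translate to its protein row")
    out <- rep("---", length(res))
    out[res != "-"] <- codons
    paste(out, collapse = "")
  }, character(1))
  CodonAlignment(rows, geneID = geneID)
}
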
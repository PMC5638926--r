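## One-to-one ortholog extraction by reciprocal best hit (RBH) on global
## protein alignment score, extended to the outgroup taxa by star
## extension against the focal endosymbiont's proteins.

.MIN_ORTHOLOG_AA <- 30L   # alignment scores are unstable below this

#' Global protein alignment score
#'
#' Needleman-Wunsch global score under BLOSUM62 with affine gap penalties
#' (open 11, extend 1; the first gap position costs 12, as in BLAST).
#' Symmetric in its arguments.
#'
#' @param a,b Protein sequences (strings over the 20 amino acids plus X).
#' @return Numeric alignment score.
#' @export
#' @examples
#' scoreProteinPair("MKV", "MKV")   # self-score: 5 + 5 + 4
scoreProteinPair <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty protein sequence")
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    scoreOnly = TRUE)
}

## all-vs-all score matrix (rows = A, cols = B)
.protein_score_matrix <- function(setA, setB) {
  A <- Biostrings::AAStringSet(setA)
  out <- matrix(NA_real_, length(setA), length(setB),
                dimnames = list(names(setA), names(setB)))
  for (j in seq_along(setB)) {
    out[, j] <- Biostrings::pairwiseAlignment(
      A, Biostrings::AAString(setB[[j]]), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
  }
  out
}

## strict unique row maxima: index of the top column, NA on ties
.unique_argmax <- function(m) {
  apply(m, 1L, function(r) {
    i <- which.max(r)
    if (sum(r == r[i]) > 1L) NA_integer_ else i
  })
}

#' Reciprocal-best-hit ortholog pairing
#'
#' Pairs gene `a` of set A with gene `b` of set B iff `b` is `a`'s unique
#' highest-scoring partner under [scoreProteinPair()] and vice versa; a
#' tie for the top score on either side excludes the gene. Genes shorter
#' than 30 residues are not considered. Deterministic.
#'
#' @param genesA,genesB Named character vectors of protein sequences.
#' @return data.frame with columns `idA`, `idB`, `score`; zero rows when
#'   nothing pairs.
#' @export
reciprocalBestHits <- function(genesA, genesB) {
  if (!length(genesA) || !length(genesB)) stop("need at least one gene per set")
  if (is.null(names(genesA)) || is.null(names(genesB)))
    stop("gene sets must be named")
  genesA <- genesA[nchar(genesA) >= .MIN_ORTHOLOG_AA]
  genesB <- genesB[nchar(genesB) >= .MIN_ORTHOLOG_AA]
  if (!length(genesA) || !length(genesB))
    return(data.frame(idA = character(0), idB = character(0),
                      score = numeric(0)))
  S <- .protein_score_matrix(genesA, genesB)
  bestB <- .unique_argmax(S)        # per A row
  bestA <- .unique_argmax(t(S))     # per B column
  ia <- which(!is.na(bestB))
  mutual <- ia[!is.na(bestA[bestB[ia]]) & bestA[bestB[ia]] == ia]
  data.frame(idA = names(genesA)[mutual],
             idB = names(genesB)[bestB[mutual]],
             score = S[cbind(mutual, bestB[mutual])],
             stringsAsFactors = FALSE)
}

#' Multi-taxon ortholog tuples by star extension
#'
#' Builds ortholog tuples across all taxa: the SB1/SB2 pairing comes from
#' [reciprocalBestHits()], and each outgroup taxon is attached by RBH of
#' its genes against the SB1 set (star extension around SB1, rather than
#' all-pairs RBH). A tuple is `complete` when every taxon contributes a
#' member.
#'
#' @param protein_sets Named list of named protein vectors, one per taxon;
#'   the first element is the star centre (SB1).
#' @return data.frame with one ID column per taxon (`NA` when absent) and
#'   a logical `complete` column.
#' @export
orthologTuples <- function(protein_sets) {
  stopifnot(is.list(protein_sets), length(protein_sets) >= 2L,
            !is.null(names(protein_sets)))
  taxa <- names(protein_sets)
  centre <- protein_sets[[1L]]
  out <- data.frame(idA = names(centre), stringsAsFactors = FALSE)
  names(out) <- taxa[1L]
  for (tx in taxa[-1L]) {
    rbh <- reciprocalBestHits(centre, protein_sets[[tx]])
    out[[tx]] <- rbh$idB[match(out[[taxa[1L]]], rbh$idA)]
  }
  out$complete <- rowSums(is.na(out[taxa])) == 0L
  out
}

#' Write / read an ortholog table
#'
#' TSV serialization of [orthologTuples()] output (one row per tuple, one
#' column per taxon, `NA` for absent members).
#'
#' @param tuples data.frame from [orthologTuples()].
#' @param file Path to write to / read from.
#' @return `readOrthologTable` returns the data.frame.
#' @export
writeOrthologTable <- function(tuples, file) {
  utils::write.table(tuples, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname writeOrthologTable
#' @export
readOrthologTable <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}
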
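## Nei-Gojobori (1986) pairwise counting with Jukes-Cantor correction.

## Jukes-Cantor multiple-hit correction of a raw proportion; saturated
## proportions (p >= 3/4) give NA.
.jc_correct <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - (4 / 3) * p[ok])
  out
}

## Core counting on two integer codon-index vectors (no gaps).
.ng86_counts <- function(ia, ib) {
  tb <- .codon_tables()
  N <- (sum(tb$n_sites[ia]) + sum(tb$n_sites[ib])) / 2
  S <- (sum(tb$s_sites[ia]) + sum(tb$s_sites[ib])) / 2
  diffs <- ia != ib
  if (any(diffs)) {
    Nd <- sum(tb$ND[cbind(ia[diffs], ib[diffs])])
    Sd <- sum(tb$SD[cbind(ia[diffs], ib[diffs])])
  } else {
    Nd <- Sd <- 0
  }
  c(N = N, S = S, Nd = Nd, Sd = Sd)
}

#' Pairwise dN and dS by Nei-Gojobori counting
#'
#' Counts synonymous and non-synonymous sites and differences between two
#' aligned coding sequences and converts the proportions to distances with
#' the Jukes-Cantor multiple-hit correction. Sites are averaged over the
#' two sequences; multi-step codon differences are averaged over all
#' minimal mutational paths, excluding paths that pass through a stop codon
#' (unless every path does). Codon columns containing a gap in either
#' sequence are discarded (complete deletion).
#'
#' @param a,b Aligned coding sequences of equal length: nucleotide strings
#'   whose length is divisible by 3, or character vectors of codons. Gap
#'   codons are written `"---"`.
#' @return A one-row data.frame with columns `N`, `S`, `Nd`, `Sd`, `pN`,
#'   `pS`, `dN`, `dS` and logical `saturated` (`TRUE` when either
#'   proportion reached the Jukes-Cantor singularity, in which case the
#'   corresponding distance is `NA` rather than silently dropped).
#' @references Nei M, Gojobori T (1986) Mol Biol Evol 3:418-426.
#' @export
#' @examples
#' pairwiseNG86("ATGAAA", "ATGAAG")   # one synonymous difference
pairwiseNG86 <- function(a, b) {
  ca <- if (length(a) == 1L && nchar(a[1]) > 3L) .split_codons(toupper(a))[[1]] else toupper(a)
  cb <- if (length(b) == 1L && nchar(b[1]) > 3L) .split_codons(toupper(b))[[1]] else toupper(b)
  if (length(ca) != length(cb))
    stop("aligned sequences must have equal codon length")
  keep <- !grepl("-", ca, fixed = TRUE) & !grepl("-", cb, fixed = TRUE)
  ca <- ca[keep]; cb <- cb[keep]
  ia <- .codon_index(ca); ib <- .codon_index(cb)
  if (anyNA(ia) || anyNA(ib))
    stop("stop codon or invalid codon in gap-free columns")
  cnt <- .ng86_counts(ia, ib)
  pN <- if (cnt["N"] > 0) cnt["Nd"] / cnt["N"] else NA_real_
  pS <- if (cnt["S"] > 0) cnt["Sd"] / cnt["S"] else NA_real_
  dN <- .jc_correct(pN)
  dS <- .jc_correct(pS)
  data.frame(N = unname(cnt["N"]), S = unname(cnt["S"]),
             Nd = unname(cnt["Nd"]), Sd = unname(cnt["Sd"]),
             pN = unname(pN), pS = unname(pS),
             dN = unname(dN), dS = unname(dS),
             saturated = (is.na(dN) & !is.na(pN)) | (is.na(dS) & !is.na(pS)),
             row.names = NULL)
}
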
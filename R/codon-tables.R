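## Codon bookkeeping for NG86-style counting under the bacterial genetic
## code (translation table 11). All tables are built once at load time and
## kept in a package-private environment: the 61 sense codons in
## lexicographic order, their translations, per-codon synonymous /
## non-synonymous site fractions, and 61 x 61 matrices of path-averaged
## synonymous and non-synonymous difference counts.

.tbl <- new.env(parent = emptyenv())

.NUC <- c("A", "C", "G", "T")

.is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

#' @importFrom Biostrings getGeneticCode
.build_codon_tables <- function() {
  code <- Biostrings::getGeneticCode("11")
  all64 <- names(code)
  sense <- all64[code != "*"]
  sense <- sort(sense)            # lexicographic: the package's tie-break order
  stopifnot(length(sense) == 61L)
  aa <- unname(code[sense])
  idx <- seq_along(sense)
  names(idx) <- sense

  translate1 <- function(codon) unname(code[codon])
  is_stop <- function(codon) code[codon] == "*"

  ## Fractional site classes: for each position, the fraction of the three
  ## single-nucleotide neighbours that are synonymous, with neighbours that
  ## are stop codons removed from the denominator.
  n_sites <- s_sites <- numeric(61L)
  for (i in idx) {
    codon <- sense[i]
    nts <- strsplit(codon, "")[[1]]
    s <- 0
    for (pos in 1:3) {
      alt <- .NUC[.NUC != nts[pos]]
      nb <- vapply(alt, function(x) {
        v <- nts; v[pos] <- x; paste(v, collapse = "")
      }, character(1))
      keep <- !is_stop(nb)
      if (any(keep))
        s <- s + mean(translate1(nb[keep]) == aa[i])
    }
    s_sites[i] <- s
    n_sites[i] <- 3 - s
  }

  ## Path-averaged pairwise difference counts: for codon pairs differing at
  ## k positions, average syn/non-syn step counts over the k! minimal
  ## mutational paths; paths passing through a stop codon are excluded
  ## unless every path does.
  ND <- SD <- matrix(0, 61L, 61L, dimnames = list(sense, sense))
  NT <- matrix(0L, 61L, 61L, dimnames = list(sense, sense))
  perms <- list(
    `1` = list(1L),
    `2` = list(c(1L, 2L), c(2L, 1L)),
    `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
               c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )
  split_codons <- strsplit(sense, "")
  for (i in 1:61) {
    ci <- split_codons[[i]]
    for (j in 1:61) {
      if (i == j) next
      cj <- split_codons[[j]]
      pos <- which(ci != cj)
      k <- length(pos)
      NT[i, j] <- k
      path_syn <- path_non <- numeric(0)
      path_clean <- logical(0)
      for (ord in perms[[as.character(k)]]) {
        cur <- ci
        syn <- non <- 0
        clean <- TRUE
        for (p in pos[ord]) {
          nxt <- cur
          nxt[p] <- cj[p]
          a1 <- code[paste(cur, collapse = "")]
          a2 <- code[paste(nxt, collapse = "")]
          if (a2 == "*" && paste(nxt, collapse = "") != sense[j]) clean <- FALSE
          if (a1 == a2) syn <- syn + 1 else non <- non + 1
          cur <- nxt
        }
        path_syn <- c(path_syn, syn)
        path_non <- c(path_non, non)
        path_clean <- c(path_clean, clean)
      }
      use <- if (any(path_clean)) path_clean else rep(TRUE, length(path_syn))
      SD[i, j] <- mean(path_syn[use])
      ND[i, j] <- mean(path_non[use])
    }
  }

  ## Integer-scaled non-synonymous counts (x6 clears the 1/2 and 1/6
  ## denominators) used as the secondary parsimony cost.
  ND6 <- round(ND * 6)
  storage.mode(ND6) <- "integer"

  assign("sense", sense, envir = .tbl)
  assign("aa", aa, envir = .tbl)
  assign("idx", idx, envir = .tbl)
  assign("n_sites", n_sites, envir = .tbl)
  assign("s_sites", s_sites, envir = .tbl)
  assign("ND", ND, envir = .tbl)
  assign("SD", SD, envir = .tbl)
  assign("NT", NT, envir = .tbl)
  assign("ND6", ND6, envir = .tbl)
  assign("code", code, envir = .tbl)
  invisible(NULL)
}

.codon_tables <- function() {
  if (!exists("sense", envir = .tbl)) .build_codon_tables()
  .tbl
}

#' Sense codons of the bacterial genetic code
#'
#' The 61 sense codons of translation table 11 in lexicographic order. This
#' ordering defines the integer codon indices used throughout the package
#' (and the deterministic lexicographic tie-break in ancestral
#' reconstruction).
#'
#' @return Character vector of length 61.
#' @export
#' @examples
#' head(senseCodons())
senseCodons <- function() .codon_tables()$sense

## codon character vector -> integer indices (1..61); stops/gaps -> NA
.codon_index <- function(codons) {
  tb <- .codon_tables()
  unname(tb$idx[codons])
}

## nucleotide string(s) -> list of codon character vectors
.split_codons <- function(x) {
  lapply(x, function(s) {
    n <- nchar(s)
    if (n %% 3L != 0L)
      stop("sequence length not divisible by 3")
    substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
  })
}

#' Synonymous and non-synonymous site fractions of a codon
#'
#' Partitions the three positions of a sense codon into fractional
#' synonymous and non-synonymous sites in the Nei-Gojobori (1986) manner:
#' at each position the fraction of single-nucleotide neighbours whose
#' translation is unchanged, with neighbours that are stop codons excluded
#' from the denominator. The two fractions always sum to 3.
#'
#' @param codon A sense codon (3-letter string over ACGT), or a vector of
#'   them.
#' @return A two-column matrix with columns `n_sites` and `s_sites`, one
#'   row per input codon.
#' @export
#' @examples
#' codonSiteClasses("ATG")   # 3 non-synonymous sites
#' codonSiteClasses("TTT")   # 1/3 synonymous site
codonSiteClasses <- function(codon) {
  tb <- .codon_tables()
  codon <- toupper(codon)
  i <- .codon_index(codon)
  if (anyNA(i))
    stop("not a sense codon under translation table 11: ",
         paste(codon[is.na(i)], collapse = ", "))
  cbind(n_sites = tb$n_sites[i], s_sites = tb$s_sites[i])
}

## Translate a vector of codon strings under table 11 ("-"-codons -> "-").
.translate_codons <- function(codons) {
  tb <- .codon_tables()
  out <- unname(tb$code[codons])
  out[codons == "---"] <- "-"
  if (anyNA(out))
    stop("untranslatable codon(s): ",
         paste(unique(codons[is.na(out)]), collapse = ", "))
  out
}

#' Translate a CDS under the bacterial genetic code
#'
#' @param cds Nucleotide string (length divisible by 3) or a vector of them.
#' @param strip.terminal.stop Drop a trailing stop codon if present.
#' @return Character vector of protein sequences (stops as `*`).
#' @export
translateCDS <- function(cds, strip.terminal.stop = TRUE) {
  vapply(.split_codons(toupper(cds)), function(cod) {
    aa <- .translate_codons(cod)
    if (strip.terminal.stop && length(aa) && aa[length(aa)] == "*")
      aa <- aa[-length(aa)]
    paste(aa, collapse = "")
  }, character(1))
}
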
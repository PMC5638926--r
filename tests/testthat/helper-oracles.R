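# Independent oracles: everything here re-derives expectations from first
# principles (neighbour enumeration, exhaustive path / assignment search,
# direct integration of the generator) without touching the package's
# internal counting tables.

CODE11 <- Biostrings::getGeneticCode("11")
NUCS <- c("A", "C", "G", "T")

oracle_neighbours <- function(codon) {
  nts <- strsplit(codon, "")[[1]]
  out <- list()
  for (pos in 1:3) for (x in setdiff(NUCS, nts[pos])) {
    v <- nts; v[pos] <- x
    out[[length(out) + 1]] <- list(pos = pos, codon = paste(v, collapse = ""))
  }
  out
}

# site classes by direct neighbour enumeration
oracle_site_classes <- function(codon) {
  aa <- CODE11[[codon]]
  s <- 0
  for (pos in 1:3) {
    nb <- vapply(Filter(function(n) n$pos == pos, oracle_neighbours(codon)),
                 function(n) n$codon, character(1))
    keep <- CODE11[nb] != "*"
    if (any(keep)) s <- s + mean(CODE11[nb[keep]] == aa)
  }
  c(n = 3 - s, s = s)
}

# path-averaged difference counts by explicit path enumeration
oracle_path_counts <- function(c1, c2) {
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  pos <- which(a != b)
  if (!length(pos)) return(c(nd = 0, sd = 0))
  perms <- if (length(pos) == 1) list(pos) else {
    idx <- if (length(pos) == 2) list(1:2, 2:1) else
      lapply(list(c(1,2,3),c(1,3,2),c(2,1,3),c(2,3,1),c(3,1,2),c(3,2,1)),
             identity)
    lapply(idx, function(o) pos[o])
  }
  res <- lapply(perms, function(ord) {
    cur <- a; nd <- sdd <- 0; clean <- TRUE
    for (p in ord) {
      nxt <- cur; nxt[p] <- b[p]
      aa1 <- CODE11[[paste(cur, collapse = "")]]
      aa2 <- CODE11[[paste(nxt, collapse = "")]]
      if (aa2 == "*" && !identical(nxt, b)) clean <- FALSE
      if (aa1 == aa2) sdd <- sdd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(nd = nd, sd = sdd, clean = clean)
  })
  cl <- vapply(res, `[[`, logical(1), "clean")
  use <- if (any(cl)) res[cl] else res
  c(nd = mean(vapply(use, `[[`, numeric(1), "nd")),
    sd = mean(vapply(use, `[[`, numeric(1), "sd")))
}

# expected per-branch non-synonymous divergence by integrating the
# generator's instantaneous rates at stationarity
oracle_expected_dn <- function(kappa, omega, t_total,
                               freqs = rep(1 / 61, 61)) {
  Q <- codonRateMatrix(kappa, omega, freqs)
  nonsyn <- attr(Q, "nonsyn")
  flux_n <- sum(freqs * rowSums(Q * nonsyn))
  n_per_codon <- sum(freqs * codonSiteClasses(senseCodons())[, "n_sites"])
  pN <- t_total * flux_n / n_per_codon
  -0.75 * log(1 - (4 / 3) * pN)
}

# brute-force minimal parsimony cost of one column on the balanced 4-leaf
# tree ((L1,L2),(L3,L4)) with unit cost per nucleotide difference
nt_diff <- function(c1, c2) {
  sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
}

oracle_sankoff_cost_4leaf <- local({
  sense <- NULL
  NT <- NULL
  MINROOT <- NULL
  function(leaves) {
    if (is.null(NT)) {
      sense <<- senseCodons()
      NT <<- outer(sense, sense, Vectorize(nt_diff))
      # min over root states of d(root, l) + d(root, r)
      MINROOT <<- matrix(0, 61, 61)
      for (l in 1:61) for (r in 1:61)
        MINROOT[l, r] <<- min(NT[, l] + NT[, r])
    }
    i <- match(leaves, sense)
    costL <- NT[, i[1]] + NT[, i[2]]
    costR <- NT[, i[3]] + NT[, i[4]]
    min(outer(costL, costR, "+") + MINROOT)
  }
})

# exhaustive global alignment score over all alignments of two length-1
# protein sequences under BLOSUM62 / affine(11, 1)
oracle_len1_score <- function(a, b) {
  B <- local({ e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e); e$BLOSUM62 })
  max(B[a, b], -2 * (11 + 1))
}

two_sb <- function(b = 0.05) simTopology("two-sb", branch.length = b)
single_sb <- function(b = 0.05) simTopology("single-sb", branch.length = b)
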
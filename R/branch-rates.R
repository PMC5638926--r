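## Branch-specific dN estimation: weighted-parsimony ancestral codons on
## the fixed topology, then NG86 counting of differences between the two
## endpoint sequences of every branch, with Jukes-Cantor correction.
##
## The parsimony objective is lexicographic: minimize total nucleotide
## changes first, then the (path-averaged) number of non-synonymous
## changes, then prefer the lexicographically smallest codon. The first
## two criteria are folded into one integer edge cost (primary * 1024 +
## 6 * path-averaged non-synonymous count, the factor 6 clearing the
## path-average denominators); the third is the argmin order of the DP.

.sankoff_cost_matrix <- function() {
  tb <- .codon_tables()
  if (is.null(.sim_cache$sankoff_cost)) {
    m <- tb$NT * 1024L + tb$ND6
    storage.mode(m) <- "integer"
    .sim_cache$sankoff_cost <- m
  }
  .sim_cache$sankoff_cost
}

## integer leaf-state matrix (tips x cols, tree tip order) from a
## CodonAlignment; gap or stop codons come back NA
.leaf_state_matrix <- function(alignment, topo) {
  cm <- codonMatrix(alignment)
  tips <- topo$tree$tip.label
  if (!all(tips %in% rownames(cm)))
    stop("alignment is missing taxa: ",
         paste(setdiff(tips, rownames(cm)), collapse = ", "))
  cm <- cm[tips, , drop = FALSE]
  m <- matrix(.codon_index(cm), nrow = nrow(cm),
              dimnames = list(tips, NULL))
  m
}

## Sankoff reconstruction on an integer leaf matrix (no NA columns);
## returns nnode x ncol integer states. Invariant columns bypass the DP.
.reconstruct_states <- function(leaf_states, topo) {
  post <- .topo_postorder(topo)
  ntip <- length(topo$tree$tip.label)
  nnode <- ntip + topo$tree$Nnode
  ncol <- ncol(leaf_states)
  out <- matrix(0L, nnode, ncol)
  out[seq_len(ntip), ] <- leaf_states
  if (ncol == 0L) return(out)
  invariant <- matrixStats_colAllEqual(leaf_states)
  if (any(invariant)) {
    out[(ntip + 1L):nnode, invariant] <-
      rep(leaf_states[1L, invariant], each = nnode - ntip)
  }
  if (any(!invariant)) {
    sub <- .sankoff_reconstruct(leaf_states[, !invariant, drop = FALSE],
                                as.integer(post$parent), as.integer(post$child),
                                as.integer(nnode), as.integer(.topo_root(topo)),
                                .sankoff_cost_matrix())
    out[, !invariant] <- sub
  }
  rownames(out) <- topo$labels
  out
}

## all rows equal per column, without matrixStats
matrixStats_colAllEqual <- function(m) {
  if (nrow(m) == 1L) return(rep(TRUE, ncol(m)))
  colSums(m == rep(m[1L, ], each = nrow(m))) == nrow(m)
}

#' Reconstruct ancestral codon states by weighted parsimony
#'
#' Assigns a codon to every internal node of the topology for each
#' alignment column, minimizing the number of nucleotide changes along the
#' tree (Sankoff dynamic programming over the 61 sense codons). Ties are
#' broken deterministically: first toward assignments with fewer
#' non-synonymous changes, then toward the lexicographically smallest
#' codon. Columns containing a gap in any row are excluded.
#'
#' @param alignment A [CodonAlignment-class] covering all leaf taxa.
#' @param topology A [simTopology()] object.
#' @return Character matrix (nodes x kept columns) of codons; row names
#'   are tip then internal node labels. The kept column indices are in
#'   attribute `columns`.
#' @export
reconstructAncestralCodons <- function(alignment, topology) {
  leaf <- .leaf_state_matrix(alignment, topology)
  keep <- which(colSums(is.na(leaf)) == 0L)
  states <- .reconstruct_states(leaf[, keep, drop = FALSE], topology)
  m <- matrix(senseCodons()[states], nrow = nrow(states),
              dimnames = list(rownames(states), NULL))
  attr(m, "columns") <- keep
  m
}

## per-branch NG86 counts for a (possibly multi-gene) column block
.branch_counts_multi <- function(leaf_states, gene, topo) {
  keep <- colSums(is.na(leaf_states)) == 0L
  leaf_states <- leaf_states[, keep, drop = FALSE]
  gene <- gene[keep]
  states <- .reconstruct_states(leaf_states, topo)
  tb <- .codon_tables()
  post <- .topo_postorder(topo)
  genes <- unique(gene)
  gidx <- match(gene, genes)
  res <- vector("list", nrow(post))
  for (e in seq_len(nrow(post))) {
    par <- states[post$parent[e], ]
    chi <- states[post$child[e], ]
    diff <- par != chi
    nd <- sd <- numeric(length(par))
    if (any(diff)) {
      ij <- cbind(par[diff], chi[diff])
      nd[diff] <- tb$ND[ij]
      sd[diff] <- tb$SD[ij]
    }
    nsite <- (tb$n_sites[par] + tb$n_sites[chi]) / 2
    ssite <- (tb$s_sites[par] + tb$s_sites[chi]) / 2
    agg <- cbind(Nd = nd, Sd = sd, N = nsite, S = ssite)
    sums <- rowsum(agg, gidx, reorder = TRUE)
    res[[e]] <- data.frame(
      gene_id = genes[as.integer(rownames(sums))],
      branch = post$branch[e],
      Nd = sums[, "Nd"], Sd = sums[, "Sd"],
      N = sums[, "N"], S = sums[, "S"],
      row.names = NULL, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, res)
  pN <- ifelse(df$N > 0, df$Nd / df$N, NA_real_)
  pS <- ifelse(df$S > 0, df$Sd / df$S, NA_real_)
  df$dN <- .jc_correct(pN)
  df$dS <- .jc_correct(pS)
  df$saturated <- (is.na(df$dN) & !is.na(pN)) | (is.na(df$dS) & !is.na(pS))
  df[order(match(df$gene_id, genes), df$branch), , drop = FALSE]
}

#' Estimate per-gene, per-branch dN on the fixed topology
#'
#' For each gene alignment: reconstruct ancestral codons by weighted
#' parsimony, then count synonymous and non-synonymous differences
#' (path-averaged, NG86) between the two endpoint sequences of every
#' branch; sites are averaged over the two endpoints and proportions are
#' Jukes-Cantor corrected. Gap-containing codon columns are excluded
#' (complete deletion). Saturated proportions yield `dN = NA` with
#' `saturated = TRUE` rather than being dropped.
#'
#' @param alignments A [CodonAlignment-class] or list of them (all over
#'   the topology's taxa).
#' @param topology A [simTopology()] object.
#' @return A [BranchRateTable-class].
#' @export
#' @examples
#' topo <- simTopology("two-sb")
#' aln <- simulateGeneAlignment(topo, simParams(2, 60, seed = 1), 1)
#' rateTable(estimateBranchRates(aln, topo))
estimateBranchRates <- function(alignments, topology) {
  if (methods::is(alignments, "CodonAlignment")) alignments <- list(alignments)
  mats <- lapply(alignments, .leaf_state_matrix, topo = topology)
  ids <- vapply(seq_along(alignments), function(i) {
    id <- geneID(alignments[[i]])
    if (is.na(id)) sprintf("gene%04d", i) else id
  }, character(1))
  gene <- rep(ids, vapply(mats, ncol, integer(1)))
  leaf <- do.call(cbind, mats)
  BranchRateTable(.branch_counts_multi(leaf, gene, topology))
}

#' Branch rates from batch-simulated codon states
#'
#' Fast-path companion of [estimateBranchRates()] for the integer-state
#' output of [simulateOrthologSet()].
#'
#' @param sim List as returned by [simulateOrthologSet()].
#' @param topology The [simTopology()] the batch was simulated on.
#' @return A [BranchRateTable-class].
#' @export
estimateBranchRatesFromStates <- function(sim, topology) {
  leaf <- sim$states[topology$tree$tip.label, , drop = FALSE]
  gene <- sprintf("gene%04d", sim$gene)
  BranchRateTable(.branch_counts_multi(leaf, gene, topology))
}
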
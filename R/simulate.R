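## Codon-level sequence simulation on the fixed species topology.
##
## The generating process is a GY94-style continuous-time Markov chain on
## the 61 sense codons of translation table 11: single-nucleotide codon
## changes occur at rate proportional to the target codon's equilibrium
## frequency, multiplied by kappa for transitions and by the branch's
## omega (dN/dS) for non-synonymous changes. Multi-nucleotide instantaneous
## changes have rate zero, and stop codons are unreachable, so simulated
## coding sequences never acquire internal stops. The generator is
## normalized per branch so that branch lengths are expected substitutions
## per codon.

.sim_cache <- new.env(parent = emptyenv())

## structural masks shared by every generator matrix
.codon_masks <- function() {
  tb <- .codon_tables()
  if (is.null(.sim_cache$nonsyn)) {
    sense <- tb$sense
    nbr <- tb$NT == 1L
    aa <- tb$aa
    nonsyn <- outer(aa, aa, "!=")
    pos_nt <- function(k) substring(sense, k, k)
    trans <- matrix(FALSE, 61, 61)
    for (k in 1:3) {
      same_other <- Reduce("&", lapply(setdiff(1:3, k), function(m)
        outer(pos_nt(m), pos_nt(m), "==")))
      trans <- trans | (same_other &
        outer(pos_nt(k), pos_nt(k), .is_transition))
    }
    .sim_cache$neighbour <- nbr
    .sim_cache$nonsyn <- nonsyn & nbr
    .sim_cache$transition <- trans & nbr
  }
  .sim_cache
}

#' Instantaneous codon rate matrix of the simulator
#'
#' Builds the normalized 61 x 61 generator of the codon substitution
#' process: `q[i,j] = pi[j] * kappa^[transition] * omega^[non-synonymous]`
#' for single-nucleotide neighbours, zero otherwise, scaled so the
#' expected total substitution rate at stationarity is 1 per codon. The
#' matrix carries the masks of non-synonymous and synonymous changes as
#' attributes so expected synonymous/non-synonymous fluxes can be
#' integrated directly.
#'
#' @param kappa Transition/transversion rate ratio (>= 0).
#' @param omega dN/dS ratio (>= 0).
#' @param codon_frequencies Length-61 simplex over [senseCodons()].
#' @return 61 x 61 generator with attributes `nonsyn` (logical mask of
#'   non-synonymous single-nucleotide changes) and `scale` (the
#'   pre-normalization total rate).
#' @export
codonRateMatrix <- function(kappa, omega, codon_frequencies = rep(1 / 61, 61)) {
  if (kappa < 0 || omega < 0) stop("kappa and omega must be non-negative")
  .check_codon_freqs(codon_frequencies)
  msk <- .codon_masks()
  Q <- matrix(0, 61, 61, dimnames = list(senseCodons(), senseCodons()))
  Q[msk$neighbour] <- rep(codon_frequencies, each = 61)[msk$neighbour]
  Q[msk$transition] <- Q[msk$transition] * kappa
  Q[msk$nonsyn] <- Q[msk$nonsyn] * omega
  diag(Q) <- -rowSums(Q)
  total <- -sum(codon_frequencies * diag(Q))
  if (total <= 0) stop("degenerate generator (zero total rate)")
  Q <- Q / total
  attr(Q, "nonsyn") <- msk$nonsyn
  attr(Q, "scale") <- total
  Q
}

.check_codon_freqs <- function(f) {
  if (length(f) != 61L || any(f < 0) || abs(sum(f) - 1) > 1e-9)
    stop("codon_frequencies must be a length-61 simplex over the sense codons")
  invisible(TRUE)
}

#' Simulation parameter bundle
#'
#' @param n_genes Number of ortholog alignments to simulate.
#' @param codons_per_gene Codon columns per gene.
#' @param kappa Transition/transversion rate ratio.
#' @param omega dN/dS per branch: a single value, or a named vector over
#'   [branchNames()] (entry `.default` fills unnamed branches).
#' @param branch_lengths Optional per-branch expected substitutions per
#'   codon overriding the topology's edge lengths (same naming rules).
#' @param codon_frequencies Length-61 simplex (default uniform).
#' @param seed Integer master seed.
#' @return A list of class `SimParams`.
#' @export
#' @examples
#' p <- simParams(n_genes = 10, codons_per_gene = 100, omega = 0.2, seed = 1)
simParams <- function(n_genes, codons_per_gene, kappa = 2, omega = 0.2,
                      branch_lengths = NULL,
                      codon_frequencies = rep(1 / 61, 61), seed = 1L) {
  if (n_genes < 1 || codons_per_gene < 1) stop("counts must be >= 1")
  if (kappa < 0 || any(omega < 0)) stop("kappa and omega must be non-negative")
  .check_codon_freqs(codon_frequencies)
  structure(list(n_genes = as.integer(n_genes),
                 codons_per_gene = as.integer(codons_per_gene),
                 kappa = kappa, omega = omega,
                 branch_lengths = branch_lengths,
                 codon_frequencies = codon_frequencies,
                 seed = as.integer(seed)),
            class = "SimParams")
}

## deterministic per-gene seed derived from (seed, gene_index); exact in
## double arithmetic, always < 2^31
.mix_seed <- function(seed, gene_index) {
  s <- abs(as.numeric(seed))
  g <- as.numeric(gene_index)
  v <- ((s %% 65536) * 40503 + (s %/% 65536) * 9973 + g * 2654435 + 97) %%
    2147483629
  as.integer(v)
}

## run expr under a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## transition probability matrices per edge, memoized on the numeric key
.edge_pmats <- function(topo, params) {
  om <- .branch_map(topo, params$omega, "omega")
  post <- .topo_postorder(topo)
  lens <- if (is.null(params$branch_lengths)) {
    stats::setNames(post$length, post$branch)
  } else .branch_map(topo, params$branch_lengths, "branch length")[post$branch]
  if (sum(lens) < 0) stop("negative tree length")
  fkey <- paste(format(params$codon_frequencies, digits = 17), collapse = ",")
  lapply(stats::setNames(post$branch, post$branch), function(b) {
    key <- paste(paste(format(c(params$kappa, om[[b]], lens[[b]]), digits = 17),
                       collapse = ","), fkey, sep = "|")
    P <- .sim_cache[[key]]
    if (is.null(P)) {
      Q <- codonRateMatrix(params$kappa, om[[b]], params$codon_frequencies)
      P <- ape::matexpo(Q * lens[[b]])
      P[P < 0] <- 0                       # clip eigendecomposition noise
      P <- P / rowSums(P)
      .sim_cache[[key]] <- P
    }
    P
  })
}

## draw child states (integer codon indices) given parent states and P
.evolve_states <- function(parent, P) {
  child <- integer(length(parent))
  for (c_i in unique(parent)) {
    sel <- parent == c_i
    child[sel] <- sample.int(61L, sum(sel), replace = TRUE, prob = P[c_i, ])
  }
  child
}

## simulate integer codon states for all nodes; returns tips x codons matrix
.simulate_states <- function(topo, pmats, n_codons) {
  post <- .topo_postorder(topo)
  root <- .topo_root(topo)
  ntip <- length(topo$tree$tip.label)
  nnode <- ntip + topo$tree$Nnode
  states <- vector("list", nnode)
  tbf <- .codon_tables()
  states[[root]] <- sample.int(61L, n_codons, replace = TRUE,
                               prob = attr(pmats, "root_freqs"))
  for (e in rev(seq_len(nrow(post)))) {     # preorder: parents first
    states[[post$child[e]]] <-
      .evolve_states(states[[post$parent[e]]], pmats[[post$branch[e]]])
  }
  m <- do.call(rbind, states[seq_len(ntip)])
  rownames(m) <- topo$tree$tip.label
  m
}

#' Simulate one ortholog codon alignment on the study topology
#'
#' Evolves a gap-free codon alignment root-to-tip: the root sequence is
#' drawn from the codon frequencies, each branch applies the transition
#' kernel of its own generator (shared kappa and frequencies, per-branch
#' omega) over its length. Deterministic given `(seed, gene_index)`:
#' each gene has its own reproducible substream, so genes can be simulated
#' independently and in any order.
#'
#' @param topology A [simTopology()] object.
#' @param params A [simParams()] bundle.
#' @param gene_index Gene number in `1..n_genes`.
#' @return A [CodonAlignment-class] over the leaf taxa with
#'   `codons_per_gene` columns and no gaps or internal stops.
#' @export
#' @examples
#' topo <- simTopology("two-sb")
#' aln <- simulateGeneAlignment(topo, simParams(5, 50, seed = 1), 1)
#' aln
simulateGeneAlignment <- function(topology, params, gene_index) {
  stopifnot(inherits(topology, "SimTopology"), inherits(params, "SimParams"))
  if (gene_index < 1 || gene_index > params$n_genes)
    stop("gene_index out of range")
  pmats <- .edge_pmats(topology, params)
  attr(pmats, "root_freqs") <- params$codon_frequencies
  states <- .with_seed(.mix_seed(params$seed, gene_index),
                       .simulate_states(topology, pmats, params$codons_per_gene))
  sense <- senseCodons()
  rows <- apply(states, 1L, function(s) paste(sense[s], collapse = ""))
  CodonAlignment(stats::setNames(rows, rownames(states)),
                 geneID = sprintf("gene%04d", gene_index))
}

#' Simulate a batch of ortholog alignments as integer codon states
#'
#' Fast path for replicate studies: all genes are drawn from one seeded
#' stream, with every gene's columns simulated jointly (identical process
#' to [simulateGeneAlignment()], different stream partitioning). Returns
#' compact integer codon states rather than `CodonAlignment` objects.
#'
#' @param topology A [simTopology()] object.
#' @param params A [simParams()] bundle; `params$seed` seeds the batch.
#' @param n_genes,codons_per_gene Optional overrides of the params fields.
#' @return List with `states` (leaf-taxa x total-codons integer matrix of
#'   codon indices into [senseCodons()]) and `gene` (integer gene index per
#'   column).
#' @export
simulateOrthologSet <- function(topology, params,
                                n_genes = params$n_genes,
                                codons_per_gene = params$codons_per_gene) {
  stopifnot(inherits(topology, "SimTopology"), inherits(params, "SimParams"))
  pmats <- .edge_pmats(topology, params)
  attr(pmats, "root_freqs") <- params$codon_frequencies
  total <- as.integer(n_genes) * as.integer(codons_per_gene)
  states <- .with_seed(params$seed, .simulate_states(topology, pmats, total))
  list(states = states,
       gene = rep(seq_len(n_genes), each = codons_per_gene))
}
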
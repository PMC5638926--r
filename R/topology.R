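## Fixed species topologies relating the two endosymbiont lineages (SB1,
## SB2) to their free-living relatives (OUT1, OUT2, OUT3). The two study
## trees mirror the organismal relationships of the spheroid-body system:
## the endosymbionts are sister to the OUT1/OUT2 clade, with OUT3 as the
## outermost free-living lineage.
##
## Branches are named after the node they lead to. Two conventional
## branches carry the comparative statistics:
##   * branch X: the terminal branch of the focal endosymbiont SB1;
##   * branch Y: in the two-endosymbiont tree, the paired terminal branch
##     of SB2 (the other descendant of the endosymbiont ancestor); in the
##     single-endosymbiont tree, the branch from SB1's parent node to the
##     ancestor of the free-living sister pair OUT1/OUT2 (used to
##     standardize per-gene rates).

#' Construct a study topology
#'
#' Builds the fixed rooted species tree used for simulation and
#' branch-rate estimation, either as one of the two built-in study shapes
#' or from a user newick string.
#'
#' @param mode `"two-sb"` (5 taxa: SB1, SB2, OUT1, OUT2, OUT3) or
#'   `"single-sb"` (4 taxa, without SB2).
#' @param branch.length Length assigned to every edge (expected
#'   substitutions per codon), default 0.05.
#' @param newick Optional rooted newick string overriding `mode`; internal
#'   nodes may be labelled, unlabelled ones are named `N<number>`.
#' @return An object of class `SimTopology`: the `ape` phylogeny plus an
#'   edge table naming every branch after its child node.
#' @export
#' @examples
#' topo <- simTopology("two-sb")
#' branchNames(topo)
#' c(branchX(topo), branchY(topo))
simTopology <- function(mode = c("two-sb", "single-sb"), branch.length = 0.05,
                        newick = NULL) {
  mode <- match.arg(mode)
  if (is.null(newick)) {
    b <- branch.length
    newick <- if (mode == "two-sb") {
      sprintf("(((SB1:%g,SB2:%g)SBANC:%g,(OUT1:%g,OUT2:%g)OUTANC:%g)CORE:%g,OUT3:%g)ROOT;",
              b, b, b, b, b, b, b, b)
    } else {
      sprintf("((SB1:%g,(OUT1:%g,OUT2:%g)OUTANC:%g)CORE:%g,OUT3:%g)ROOT;",
              b, b, b, b, b, b)
    }
  }
  tree <- ape::read.tree(text = newick)
  if (is.null(tree) || !ape::is.rooted(tree))
    stop("topology must be a valid rooted newick tree")
  if (anyDuplicated(tree$tip.label))
    stop("taxon labels must be unique")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0) ||
      sum(tree$edge.length) <= 0)
    stop("branch lengths must be non-negative with positive total")
  nn <- tree$Nnode
  if (is.null(tree$node.label) || !length(tree$node.label))
    tree$node.label <- paste0("N", seq_len(nn))
  blank <- !nzchar(tree$node.label)
  tree$node.label[blank] <- paste0("N", which(blank))
  labels <- c(tree$tip.label, tree$node.label)
  edges <- data.frame(
    branch = labels[tree$edge[, 2]],
    parent = tree$edge[, 1],
    child  = tree$edge[, 2],
    parent_label = labels[tree$edge[, 1]],
    length = tree$edge.length,
    stringsAsFactors = FALSE
  )
  structure(list(tree = tree, mode = mode, edges = edges, labels = labels),
            class = "SimTopology")
}

#' @export
print.SimTopology <- function(x, ...) {
  cat(sprintf("SimTopology (%s): %d taxa [%s]\n", x$mode,
              length(x$tree$tip.label), paste(x$tree$tip.label, collapse = ", ")))
  cat(sprintf("  branches: %s\n", paste(x$edges$branch, collapse = ", ")))
  cat(sprintf("  branch X = %s, branch Y = %s\n", branchX(x), branchY(x)))
  invisible(x)
}

#' @rdname simTopology
#' @param x A `SimTopology`.
#' @export
branchNames <- function(x) x$edges$branch

#' @rdname simTopology
#' @export
taxonNames <- function(x) x$tree$tip.label

#' @rdname simTopology
#' @export
branchX <- function(x) "SB1"

#' @rdname simTopology
#' @export
branchY <- function(x) if (identical(x$mode, "two-sb")) "SB2" else "OUTANC"

## postorder edge indices (children before parents) and root node id
.topo_postorder <- function(topo) {
  tree <- ape::reorder.phylo(topo$tree, "postorder")
  labels <- topo$labels
  data.frame(parent = tree$edge[, 1], child = tree$edge[, 2],
             branch = labels[tree$edge[, 2]],
             length = tree$edge.length, stringsAsFactors = FALSE)
}

.topo_root <- function(topo) length(topo$tree$tip.label) + 1L

## per-branch numeric map (omega or lengths): accept a single value or a
## named vector with optional ".default" entry
.branch_map <- function(topo, values, what = "value") {
  br <- branchNames(topo)
  if (is.null(names(values))) {
    if (length(values) == 1L) return(stats::setNames(rep(values, length(br)), br))
    if (length(values) == length(br)) return(stats::setNames(values, br))
    stop("unnamed ", what, " vector must have length 1 or one entry per branch")
  }
  default <- if (".default" %in% names(values)) values[[".default"]] else NA_real_
  out <- stats::setNames(rep(default, length(br)), br)
  known <- intersect(names(values), br)
  out[known] <- values[known]
  if (anyNA(out))
    stop("missing ", what, " for branch(es): ",
         paste(br[is.na(out)], collapse = ", "), " (no .default given)")
  out
}
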
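## Comparative statistics of genome erosion: branch-ratio standardization
## with its omission rule, the iterative Grubbs outlier screen, pathway
## relaxation tests (rank-sum), and the paired dN-difference signed-rank
## test between the two endosymbiont lineages.

#' Standardize per-gene dN by the sister-branch rate
#'
#' Divides each gene's dN on the focal endosymbiont branch (branch X) by
#' its dN on the reference branch (branch Y), controlling for gene-specific
#' rate variation. Genes for which either value is zero cannot be
#' standardized and are flagged `omitted` (`ratio = NA`), as are genes
#' with missing/saturated values on either branch.
#'
#' @param dn_x,dn_y Non-negative finite dN values (vectors of equal
#'   length); `NA` allowed (propagates to omission).
#' @return data.frame with columns `dn_x`, `dn_y`, `ratio`, `omitted`.
#' @export
#' @examples
#' standardizeDN(c(0.02, 0.02, 0), c(0.04, 0, 0.03))
standardizeDN <- function(dn_x, dn_y) {
  if (length(dn_x) != length(dn_y)) stop("inputs must have equal length")
  if (any(dn_x < 0, na.rm = TRUE) || any(dn_y < 0, na.rm = TRUE))
    stop("dN values must be non-negative")
  if (any(is.infinite(dn_x)) || any(is.infinite(dn_y)))
    stop("dN values must be finite or NA")
  omitted <- is.na(dn_x) | is.na(dn_y) | dn_x == 0 | dn_y == 0
  ratio <- ifelse(omitted, NA_real_, dn_x / dn_y)
  data.frame(dn_x = dn_x, dn_y = dn_y, ratio = ratio, omitted = omitted)
}

## two-sided Grubbs critical value at level alpha for sample size n
.grubbs_critical <- function(n, alpha) {
  t <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

#' Iterative two-sided Grubbs outlier screen
#'
#' Repeatedly applies the two-sided Grubbs test: the most extreme value
#' (largest |x - mean|/sd) is flagged and removed if its statistic exceeds
#' the critical value derived from the t distribution at level `alpha`,
#' until no further rejection. Deterministic; invariant to affine
#' transformations of the sample.
#'
#' @param values Numeric vector, `n >= 3`, positive standard deviation.
#' @param alpha Significance level per step (default 0.005).
#' @return Integer indices (into `values`) of flagged outliers, possibly
#'   empty, in flagging order.
#' @export
#' @examples
#' grubbsOutliers(c(1, 1.1, 0.9, 1.05, 8))
grubbsOutliers <- function(values, alpha = 0.005) {
  if (length(values) < 3L) stop("Grubbs test requires n >= 3")
  if (anyNA(values)) stop("values must not contain NA")
  if (stats::sd(values) == 0) stop("zero variance: Grubbs test undefined")
  flagged <- integer(0)
  live <- seq_along(values)
  repeat {
    x <- values[live]
    n <- length(x)
    if (n < 3L || stats::sd(x) == 0) break
    g <- abs(x - mean(x)) / stats::sd(x)
    i <- which.max(g)
    if (g[i] > .grubbs_critical(n, alpha)) {
      flagged <- c(flagged, live[i])
      live <- live[-i]
    } else break
  }
  flagged
}

#' Pathway relaxation test (rank-sum)
#'
#' Tests whether the standardized rates of a pathway's genes are elevated
#' relative to the genome background with the two-sample Wilcoxon rank-sum
#' test: exact enumeration when both groups have at most 12 untied values,
#' otherwise the normal approximation with midranks, tie-corrected
#' variance and continuity correction. Reports both the one-sided
#' (pathway greater) and the two-sided p-value.
#'
#' @param pathway_values,background_values Numeric vectors (each `n >= 3`);
#'   the pathway's genes must not be part of the background.
#' @return list: `p_greater`, `p_two_sided`, `direction` (`"greater"` or
#'   `"less"`, by median shift), `W`, `n_pathway`, `n_background`.
#' @export
#' @examples
#' pathwayRelaxationTest(c(4, 5, 6), c(1, 2, 3))  # exact p = 1/20
pathwayRelaxationTest <- function(pathway_values, background_values) {
  pw <- pathway_values[!is.na(pathway_values)]
  bg <- background_values[!is.na(background_values)]
  if (length(pw) < 3L || length(bg) < 3L)
    stop("each group needs at least 3 values")
  exact <- length(pw) <= 12L && length(bg) <= 12L &&
    !anyDuplicated(c(pw, bg))
  g <- suppressWarnings(stats::wilcox.test(pw, bg, alternative = "greater",
                                           exact = exact, correct = TRUE))
  t2 <- suppressWarnings(stats::wilcox.test(pw, bg, alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  list(p_greater = g$p.value, p_two_sided = t2$p.value,
       direction = if (stats::median(pw) >= stats::median(bg)) "greater" else "less",
       W = unname(g$statistic), n_pathway = length(pw),
       n_background = length(bg))
}

#' Paired dN-difference test between two lineages
#'
#' One-sample Wilcoxon signed-rank test of the per-ortholog dN differences
#' against zero: zero differences are dropped, absolute differences are
#' midranked, and the two-sided p-value is exact (sign-pattern
#' enumeration) for at most 25 untied non-zero differences, otherwise the
#' tie-corrected normal approximation with continuity correction. The
#' reported mean is over all differences, zeros included.
#'
#' @param deltas Numeric vector of per-ortholog dN differences (focal
#'   lineage minus comparison lineage), or a data.frame with a `delta`
#'   column.
#' @return list: `mean_delta`, `statistic` (signed-rank V), `p_value`
#'   (two-sided), `n_total`, `n_nonzero`.
#' @export
#' @examples
#' pairedRateTest(c(1, 2, 3, 4, 5, 6))  # exact two-sided p = 2/64
pairedRateTest <- function(deltas) {
  if (is.data.frame(deltas)) deltas <- deltas$delta
  deltas <- deltas[!is.na(deltas)]
  nz <- deltas[deltas != 0]
  if (length(nz) == 0L) stop("all differences are zero")
  if (length(nz) < 6L) stop("need at least 6 non-zero differences")
  exact <- length(nz) <= 25L && !anyDuplicated(abs(nz))
  ht <- suppressWarnings(stats::wilcox.test(nz, mu = 0, exact = exact,
                                            correct = TRUE))
  list(mean_delta = mean(deltas), statistic = unname(ht$statistic),
       p_value = ht$p.value, n_total = length(deltas),
       n_nonzero = length(nz))
}

#' Per-ortholog dN differences on the paired endosymbiont branches
#'
#' Extracts, for every gene with finite dN on both endosymbiont terminal
#' branches of the two-endosymbiont topology, the difference
#' `dN(SB1) - dN(SB2)`.
#'
#' @param rates A [BranchRateTable-class] estimated on a two-endosymbiont
#'   topology.
#' @param topology The matching [simTopology()] (mode `"two-sb"`).
#' @return data.frame: `gene_id`, `dn_sb1`, `dn_sb2`, `delta`.
#' @export
deltaDN <- function(rates, topology) {
  if (!identical(topology$mode, "two-sb"))
    stop("paired dN differences require the two-endosymbiont topology")
  m <- dnMatrix(rates, c(branchX(topology), branchY(topology)))
  ok <- rowSums(is.na(m)) == 0L
  data.frame(gene_id = rownames(m)[ok],
             dn_sb1 = m[ok, 1], dn_sb2 = m[ok, 2],
             delta = m[ok, 1] - m[ok, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Full erosion-statistics report
#'
#' Combines the comparative statistics into one [ErosionReport-class]:
#' standardized per-gene rates with the omission rule and the Grubbs
#' outlier screen, rank-sum relaxation tests for each annotated pathway
#' against the genome background, and the paired signed-rank test on the
#' per-ortholog dN differences between the two endosymbiont lineages.
#' The headline paired test uses all non-zero differences; a companion
#' p-value excluding Grubbs-flagged differences is also reported.
#'
#' @param rates [BranchRateTable-class] from the two-endosymbiont run
#'   (drives the paired test), or `NULL` to skip.
#' @param topology Matching two-endosymbiont [simTopology()].
#' @param rates_std,topology_std Optional rate table and topology for the
#'   standardization analysis (defaults: reuse `rates`/`topology`; branch
#'   Y is then the paired endosymbiont branch rather than the free-living
#'   sister branch).
#' @param pathways Optional pathway definition data.frame
#'   (`pathway`, `gene_id`, optional logical `excluded`), e.g.
#'   [pathwayDefinitions()].
#' @param std_branch_x,std_branch_y Branch names used for the
#'   standardization ratio (defaults: branch X and branch Y of
#'   `topology_std`; on a two-endosymbiont tree pass
#'   `std_branch_y = "OUTANC"` to standardize by the free-living sister
#'   branch instead of the paired endosymbiont branch).
#' @param grubbs_alpha Level of the outlier screen (default 0.005).
#' @return An [ErosionReport-class].
#' @export
erosionAnalysis <- function(rates, topology, rates_std = rates,
                            topology_std = topology, pathways = NULL,
                            std_branch_x = branchX(topology_std),
                            std_branch_y = branchY(topology_std),
                            grubbs_alpha = 0.005) {
  ## standardization arm
  mstd <- dnMatrix(rates_std, c(std_branch_x, std_branch_y))
  std <- standardizeDN(mstd[, 1], mstd[, 2])
  std <- cbind(gene_id = rownames(mstd), std, stringsAsFactors = FALSE)
  rownames(std) <- NULL
  std$outlier <- FALSE
  usable <- which(!std$omitted)
  if (length(usable) >= 3L && stats::sd(std$ratio[usable]) > 0)
    std$outlier[usable[grubbsOutliers(std$ratio[usable], grubbs_alpha)]] <- TRUE

  ## pathway arm
  ptests <- data.frame()
  if (!is.null(pathways)) {
    pw <- pathways
    if (!is.null(pw$excluded)) pw <- pw[!pw$excluded, , drop = FALSE]
    rows <- lapply(split(pw$gene_id, pw$pathway), function(genes) {
      inpw <- !std$omitted & std$gene_id %in% genes
      inbg <- !std$omitted & !(std$gene_id %in% pw$gene_id)
      if (sum(inpw) < 3L || sum(inbg) < 3L) return(NULL)
      tst <- pathwayRelaxationTest(std$ratio[inpw], std$ratio[inbg])
      data.frame(n_pathway = tst$n_pathway, n_background = tst$n_background,
                 W = tst$W, p_greater = tst$p_greater,
                 p_two_sided = tst$p_two_sided, direction = tst$direction,
                 stringsAsFactors = FALSE)
    })
    keep <- !vapply(rows, is.null, logical(1))
    if (any(keep)) {
      ptests <- do.call(rbind, rows[keep])
      ptests <- cbind(pathway = names(rows)[keep], ptests,
                      stringsAsFactors = FALSE)
      rownames(ptests) <- NULL
    }
  }

  ## paired arm
  deltas <- data.frame()
  paired <- list()
  if (!is.null(rates) && identical(topology$mode, "two-sb")) {
    deltas <- deltaDN(rates, topology)
    if (nrow(deltas)) {
      deltas$outlier <- FALSE
      nz <- which(deltas$delta != 0)
      if (length(nz) >= 3L && stats::sd(deltas$delta[nz]) > 0)
        deltas$outlier[nz[grubbsOutliers(deltas$delta[nz], grubbs_alpha)]] <- TRUE
      paired <- pairedRateTest(deltas$delta)
      no_out <- deltas$delta[!deltas$outlier]
      paired$p_value_no_outliers <-
        tryCatch(pairedRateTest(no_out)$p_value, error = function(e) NA_real_)
      paired$mean_delta_no_outliers <- mean(no_out)
    }
  }

  ErosionReport(standardized = std, pathwayTests = ptests, deltas = deltas,
                pairedTest = paired,
                meta = list(grubbs_alpha = grubbs_alpha,
                            n_genes_std = nrow(std),
                            n_omitted = sum(std$omitted),
                            n_delta = nrow(deltas)))
}

#' Built-in pathway definitions
#'
#' Gene lists for the two tetrapyrrole-derived biosynthetic pathways under
#' study: chlorophyll a (10 genes, including the divinyl-chlorophyllide
#' reductase gene bciB) and vitamin B12/cobalamin (18 genes, with cobR
#' flagged `excluded` because it is absent from the endosymbionts and
#' their free-living relatives alike).
#'
#' @return data.frame with columns `pathway`, `gene_id`, `excluded`.
#' @export
#' @examples
#' table(pathwayDefinitions()$pathway)
pathwayDefinitions <- function() {
  path <- system.file("extdata", "pathways.tsv", package = "SymbiontErosion",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$excluded <- as.logical(df$excluded)
  df
}
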
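#' @import methods
NULL

#' CodonAlignment: a gap-threaded codon matrix over named taxa
#'
#' Thin wrapper around an aligned [Biostrings::DNAStringSet] whose width is
#' divisible by 3, addressable by codon column. Gap codons are `"---"`.
#'
#' @slot sequences Aligned `DNAStringSet`, equal widths, named by taxon.
#' @slot geneID Identifier of the source gene (may be `NA`).
#' @export
setClass("CodonAlignment",
  slots = c(sequences = "DNAStringSet", geneID = "character"))

setValidity("CodonAlignment", function(object) {
  w <- Biostrings::width(object@sequences)
  if (length(w) == 0L) return("alignment must contain at least one sequence")
  if (length(unique(w)) != 1L) return("all rows must have equal length")
  if (w[1] %% 3L != 0L) return("alignment width must be divisible by 3")
  nm <- names(object@sequences)
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
    return("rows must carry unique non-empty taxon names")
  TRUE
})

#' Construct a CodonAlignment
#'
#' @param sequences Named character vector or `DNAStringSet` of aligned,
#'   equal-length nucleotide rows (width divisible by 3; gaps as `-`).
#' @param geneID Optional source gene identifier.
#' @return A [CodonAlignment-class] object.
#' @export
#' @examples
#' CodonAlignment(c(t1 = "ATGAAA", t2 = "ATGAAG"), geneID = "g1")
CodonAlignment <- function(sequences, geneID = NA_character_) {
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  methods::new("CodonAlignment", sequences = sequences,
               geneID = as.character(geneID))
}

#' @describeIn CodonAlignment Number of codon columns.
#' @param x A `CodonAlignment`.
#' @export
ncolCodons <- function(x) Biostrings::width(x@sequences)[1] %/% 3L

#' @describeIn CodonAlignment Taxon-by-codon character matrix of codons.
#' @export
codonMatrix <- function(x) {
  rows <- as.character(x@sequences)
  m <- do.call(rbind, .split_codons(rows))
  rownames(m) <- names(x@sequences)
  m
}

#' @describeIn CodonAlignment The aligned rows as a named character vector.
#' @export
alignedRows <- function(x) {
  stats::setNames(as.character(x@sequences), names(x@sequences))
}

#' @describeIn CodonAlignment Source gene identifier.
#' @export
geneID <- function(x) x@geneID

setMethod("show", "CodonAlignment", function(object) {
  cat(sprintf("CodonAlignment%s: %d taxa x %d codons\n",
              if (is.na(object@geneID)) "" else sprintf(" [%s]", object@geneID),
              length(object@sequences), ncolCodons(object)))
  invisible(NULL)
})

#' BranchRateTable: per-gene, per-branch substitution counts and rates
#'
#' Long-format table with one row per (gene, branch): NG86 site counts
#' (`N`, `S`), path-averaged difference counts (`Nd`, `Sd`),
#' Jukes-Cantor-corrected rates (`dN`, `dS`) and a `saturated` flag for
#' proportions beyond the correction's reach (kept, not dropped).
#'
#' @slot rates The long-format data.frame.
#' @export
setClass("BranchRateTable", slots = c(rates = "data.frame"))

.brt_cols <- c("gene_id", "branch", "Nd", "Sd", "N", "S", "dN", "dS", "saturated")

setValidity("BranchRateTable", function(object) {
  df <- object@rates
  miss <- setdiff(.brt_cols, names(df))
  if (length(miss)) return(paste("missing column(s):", paste(miss, collapse = ", ")))
  if (any(df$dN < 0, na.rm = TRUE)) return("dN must be non-negative")
  if (any(is.infinite(df$dN))) return("dN must be finite or NA (flagged saturated)")
  TRUE
})

#' @describeIn BranchRateTable Construct from a long-format data.frame.
#' @param rates data.frame with columns gene_id, branch, Nd, Sd, N, S, dN,
#'   dS, saturated.
#' @export
BranchRateTable <- function(rates) {
  methods::new("BranchRateTable", rates = as.data.frame(rates))
}

#' @describeIn BranchRateTable The underlying long-format data.frame.
#' @param x A `BranchRateTable`.
#' @export
rateTable <- function(x) x@rates

#' @describeIn BranchRateTable Wide gene-by-branch matrix of dN values.
#' @param branches Branch names to keep (default: all).
#' @export
dnMatrix <- function(x, branches = NULL) {
  df <- x@rates
  if (!is.null(branches)) df <- df[df$branch %in% branches, , drop = FALSE]
  genes <- unique(df$gene_id)
  brs <- if (is.null(branches)) unique(df$branch) else branches
  m <- matrix(NA_real_, length(genes), length(brs),
              dimnames = list(genes, brs))
  m[cbind(match(df$gene_id, genes), match(df$branch, brs))] <- df$dN
  m
}

setMethod("show", "BranchRateTable", function(object) {
  df <- object@rates
  cat(sprintf("BranchRateTable: %d genes x %d branches (%d saturated entries)\n",
              length(unique(df$gene_id)), length(unique(df$branch)),
              sum(df$saturated, na.rm = TRUE)))
  invisible(NULL)
})

#' GeneStatusMatrix: per-gene, per-genome intactness calls
#'
#' One row per (gene, genome) with a call in INTACT / PSEUDOGENE / ABSENT,
#' the coverage fraction of the reference protein achieved by the best
#' alignment, and a semicolon-separated evidence string (lesion kind and
#' approximate codon position for each disruption found).
#'
#' @slot statuses The calls data.frame.
#' @export
setClass("GeneStatusMatrix", slots = c(statuses = "data.frame"))

setValidity("GeneStatusMatrix", function(object) {
  df <- object@statuses
  need <- c("gene_id", "genome", "status", "coverage", "evidence")
  miss <- setdiff(need, names(df))
  if (length(miss)) return(paste("missing column(s):", paste(miss, collapse = ", ")))
  if (!all(df$status %in% c("INTACT", "PSEUDOGENE", "ABSENT")))
    return("status must be INTACT, PSEUDOGENE or ABSENT")
  bad <- df$status == "PSEUDOGENE" & !nzchar(df$evidence)
  if (any(bad)) return("PSEUDOGENE calls require at least one evidence item")
  TRUE
})

#' @describeIn GeneStatusMatrix Construct from a calls data.frame.
#' @param statuses data.frame with columns gene_id, genome, status,
#'   coverage, evidence.
#' @export
GeneStatusMatrix <- function(statuses) {
  methods::new("GeneStatusMatrix", statuses = as.data.frame(statuses))
}

#' @describeIn GeneStatusMatrix The underlying calls data.frame.
#' @param x A `GeneStatusMatrix`.
#' @export
statusTable <- function(x) x@statuses

setMethod("show", "GeneStatusMatrix", function(object) {
  df <- object@statuses
  tab <- table(df$genome, df$status)
  cat(sprintf("GeneStatusMatrix: %d genes x %d genomes\n",
              length(unique(df$gene_id)), length(unique(df$genome))))
  print(tab)
  invisible(NULL)
})

#' ErosionReport: the comparative-statistics bundle
#'
#' Collects the outputs of the erosion analysis: per-gene standardized
#' rates with omission and outlier flags, pathway relaxation tests, the
#' per-ortholog dN-difference records and the paired signed-rank summary.
#'
#' @slot standardized data.frame of per-gene standardized rates.
#' @slot pathwayTests data.frame of pathway-vs-background tests.
#' @slot deltas data.frame of per-ortholog dN differences.
#' @slot pairedTest list: paired signed-rank summary.
#' @slot meta list of run metadata (sizes, parameters, seed).
#' @export
setClass("ErosionReport",
  slots = c(standardized = "data.frame", pathwayTests = "data.frame",
            deltas = "data.frame", pairedTest = "list", meta = "list"))

#' @describeIn ErosionReport Constructor.
#' @export
ErosionReport <- function(standardized = data.frame(), pathwayTests = data.frame(),
                          deltas = data.frame(), pairedTest = list(),
                          meta = list()) {
  methods::new("ErosionReport", standardized = standardized,
               pathwayTests = pathwayTests, deltas = deltas,
               pairedTest = pairedTest, meta = meta)
}

#' @describeIn ErosionReport Per-ortholog dN-difference records.
#' @param x An `ErosionReport`.
#' @export
deltaRecords <- function(x) x@deltas

#' @describeIn ErosionReport Paired signed-rank summary list.
#' @export
pairedTest <- function(x) x@pairedTest

#' @describeIn ErosionReport Per-gene standardized-rate table.
#' @export
standardizedRates <- function(x) x@standardized

#' @describeIn ErosionReport Pathway relaxation-test table.
#' @export
pathwayTests <- function(x) x@pathwayTests

setMethod("show", "ErosionReport", function(object) {
  cat("ErosionReport\n")
  if (nrow(object@standardized))
    cat(sprintf("  standardized rates: %d genes (%d omitted, %d outliers)\n",
                nrow(object@standardized), sum(object@standardized$omitted),
                sum(object@standardized$outlier, na.rm = TRUE)))
  if (nrow(object@pathwayTests)) {
    cat(sprintf("  pathway tests: %s\n",
                paste(sprintf("%s p=%.3g", object@pathwayTests$pathway,
                              object@pathwayTests$p_greater), collapse = "; ")))
  }
  if (length(object@pairedTest)) {
    cat(sprintf("  paired dN difference: n=%d, mean delta=%.4g, V=%g, p=%.3g\n",
                object@pairedTest$n_nonzero, object@pairedTest$mean_delta,
                object@pairedTest$statistic, object@pairedTest$p_value))
  }
  invisible(NULL)
})
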
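## End-to-end orchestration: simulate (or ingest) an annotated genome
## pair, pair orthologs, build codon alignments, estimate branch rates,
## run the comparative statistics and the pseudogene scan, and write every
## stage's artifacts. Stages log structured count lines so filter
## attrition is auditable.

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Default pipeline configuration
#'
#' @param n_genes,codons_per_gene,kappa,omega,branch_length,seed Simulation
#'   settings (see [simParams()]); `omega` may be a named per-branch
#'   vector with a `.default` entry.
#' @param lesions `"erosion-profile"` for [erosionLesionProfile()], `NULL`
#'   for none, or a lesion data.frame.
#' @param pairing `"rbh"` (reciprocal best hit on protein scores) or
#'   `"truth"` (use fabricated gene identity).
#' @param pseudoscan Run the pseudogene scan stage.
#' @param grubbs_alpha Outlier-screen level.
#' @return Named list of settings for [runPipeline()].
#' @export
pipelineConfig <- function(n_genes = 60, codons_per_gene = 200, kappa = 2,
                           omega = c(.default = 0.2, SB2 = 0.25),
                           branch_length = 0.05, seed = 1L,
                           lesions = "erosion-profile", pairing = "rbh",
                           pseudoscan = TRUE, grubbs_alpha = 0.005) {
  as.list(environment())
}

#' Run the full erosion-analysis pipeline on a fabricated genome pair
#'
#' Executes simulate -> pair -> align -> rates -> stats -> pseudoscan and
#' writes TSV artifacts for every stage. Deterministic and idempotent
#' given the configuration: two runs with the same config produce
#' byte-identical tables.
#'
#' @param config List from [pipelineConfig()] (or a compatible list).
#' @param outdir Output directory for artifacts, or `NULL` to skip
#'   writing.
#' @return list: `fabrication`, `orthologs`, `alignments`, `rates`
#'   ([BranchRateTable-class]), `report` ([ErosionReport-class]),
#'   `statuses` ([GeneStatusMatrix-class] or `NULL`), `pathway_matrix`,
#'   `summaries`, `config`.
#' @export
runPipeline <- function(config = pipelineConfig(), outdir = NULL) {
  cfg <- utils::modifyList(pipelineConfig(), config)
  topo <- simTopology("two-sb", branch.length = cfg$branch_length)
  params <- simParams(cfg$n_genes, cfg$codons_per_gene, kappa = cfg$kappa,
                      omega = cfg$omega, seed = cfg$seed)
  pathways <- pathwayDefinitions()
  lesions <- cfg$lesions
  if (identical(lesions, "erosion-profile")) lesions <- erosionLesionProfile()

  ## stage: simulate / fabricate
  fab <- fabricateGenomePair(topo, params, pathways = pathways,
                             lesions = lesions)
  .log_stage("simulate", "fabricated %d genes per genome; %d lesion records",
             cfg$n_genes, if (is.null(lesions)) 0L else nrow(lesions))

  ## stage: ortholog pairing
  protA <- fab$genomes$A$proteins
  protB <- fab$genomes$B$proteins
  if (identical(cfg$pairing, "rbh")) {
    sets <- c(list(SB1 = protA, SB2 = protB),
              lapply(fab$outgroups, `[[`, "proteins"))
    tuples <- orthologTuples(sets)
  } else {
    shared <- intersect(names(protA), names(protB))
    tuples <- data.frame(SB1 = shared, SB2 = shared, OUT1 = shared,
                         OUT2 = shared, OUT3 = shared,
                         complete = TRUE, stringsAsFactors = FALSE)
  }
  complete <- tuples[tuples$complete, , drop = FALSE]
  .log_stage("orthologs", "%d tuples, %d complete in all taxa",
             nrow(tuples), nrow(complete))

  ## stage: codon alignment (protein MSA + back-threading)
  taxa <- topo$tree$tip.label
  cds_of <- function(tx, id) {
    if (tx == "SB1") fab$genomes$A$cds[[id]]
    else if (tx == "SB2") fab$genomes$B$cds[[id]]
    else fab$outgroups[[tx]]$cds[[id]]
  }
  prot_of <- function(tx, id) {
    if (tx == "SB1") protA[[id]] else if (tx == "SB2") protB[[id]]
    else fab$outgroups[[tx]]$proteins[[id]]
  }
  alignments <- lapply(seq_len(nrow(complete)), function(i) {
    ids <- unlist(complete[i, taxa])
    prots <- vapply(taxa, function(tx) prot_of(tx, ids[[tx]]), character(1))
    cds <- vapply(taxa, function(tx) cds_of(tx, ids[[tx]]), character(1))
    msa <- alignProteinSet(prots, guide_order = taxa)
    backThreadCodons(msa, cds, geneID = complete$SB1[i])
  })
  .log_stage("align", "%d codon alignments built", length(alignments))

  ## stage: branch rates
  rates <- estimateBranchRates(alignments, topo)
  .log_stage("rates", "%d (gene, branch) rate rows",
             nrow(rateTable(rates)))

  ## stage: comparative statistics (standardization against the
  ## free-living sister branch of the two-endosymbiont tree)
  report <- erosionAnalysis(rates, topo, pathways = pathways,
                            std_branch_y = "OUTANC",
                            grubbs_alpha = cfg$grubbs_alpha)
  .log_stage("stats", "%d delta records; paired p = %.3g",
             nrow(deltaRecords(report)),
             if (length(pairedTest(report))) pairedTest(report)$p_value else NA)

  ## stage: pseudogene scan (each genome scanned with the sister genome's
  ## intact proteins as references)
  statuses <- NULL
  pmat <- NULL
  if (isTRUE(cfg$pseudoscan)) {
    ## sister genome's intact proteins, gaps filled from the closest
    ## free-living relative so lesioned-in-both references still exist
    fill <- fab$outgroups[[1]]$proteins
    refs_for_B <- c(protA, fill[setdiff(fab$gene_ids, names(protA))])
    refs_for_A <- c(protB, fill[setdiff(fab$gene_ids, names(protB))])
    stA <- scanGenome(refs_for_A, fab$genomes$A$sequence,
                      fab$genomes$A$annotation, genome_id = "A")
    stB <- scanGenome(refs_for_B, fab$genomes$B$sequence,
                      fab$genomes$B$annotation, genome_id = "B")
    statuses <- GeneStatusMatrix(rbind(statusTable(stA), statusTable(stB)))
    pmat <- pathwayStatusMatrix(statuses, pathways)
    .log_stage("pseudoscan", "%d statuses (%d pseudogenes, %d absent)",
               nrow(statusTable(statuses)),
               sum(statusTable(statuses)$status == "PSEUDOGENE"),
               sum(statusTable(statuses)$status == "ABSENT"))
  }

  ## stage: genome summaries
  summaries <- do.call(rbind, lapply(names(fab$genomes), function(gn)
    genomeSummary(fab$genomes[[gn]]$sequence, fab$genomes[[gn]]$annotation,
                  genome_id = gn)))

  res <- list(fabrication = fab, orthologs = tuples, alignments = alignments,
              rates = rates, report = report, statuses = statuses,
              pathway_matrix = pmat, summaries = summaries, config = cfg)
  if (!is.null(outdir)) writePipelineArtifacts(res, outdir)
  res
}

#' Write pipeline artifacts
#'
#' @param result Result list of [runPipeline()].
#' @param outdir Directory to write TSV artifacts into.
#' @return Invisibly, the written paths.
#' @export
writePipelineArtifacts <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    wt(result$orthologs, "orthologs.tsv"),
    wt(rateTable(result$rates), "branch_rates.tsv"),
    wt(standardizedRates(result$report), "standardized_dn.tsv"),
    wt(deltaRecords(result$report), "delta_dn.tsv"),
    wt(result$summaries, "genome_summary.tsv"))
  if (nrow(pathwayTests(result$report)))
    paths <- c(paths, wt(pathwayTests(result$report), "pathway_tests.tsv"))
  if (!is.null(result$statuses))
    paths <- c(paths, wt(statusTable(result$statuses), "gene_status.tsv"),
               wt(result$pathway_matrix$matrix, "pathway_status_matrix.tsv"))
  pt <- pairedTest(result$report)
  if (length(pt))
    paths <- c(paths, wt(data.frame(metric = names(unlist(pt)),
                                    value = unlist(pt)), "paired_test.tsv"))
  writeFabricatedGenomes(result$fabrication, file.path(outdir, "genomes"))
  invisible(paths)
}
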
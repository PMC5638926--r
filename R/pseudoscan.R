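## Rule-based pseudogene detection. Reference proteins (e.g. the intact
## orthologs of the sister genome) are aligned against candidate genomic
## windows with a frameshift-aware protein-to-DNA dynamic program that may
## cross in-frame stop codons (penalty) and switch reading frame (penalty).
## A gene is then ABSENT when no window reaches the score threshold,
## PSEUDOGENE when the best alignment crosses an internal stop, switches
## frame, or covers too little of the reference (severe truncation), and
## INTACT otherwise.

.FS_DEFAULTS <- list(gap_open = 11L, gap_ext = 1L, stop_pen = 8L,
                     fs_pen = 12L, ambig_score = -2L,
                     truncation_frac = 0.5, min_score_frac = 0.4)

.blosum_tables <- function() {
  if (is.null(.sim_cache$blosum)) {
    B <- get(utils::data("BLOSUM62", package = "Biostrings",
                         envir = environment())[1], envir = environment())
    storage.mode(B) <- "integer"
    code <- .codon_tables()$code
    codon_aa <- integer(64)
    k <- 0L
    for (a in .NUC) for (b in .NUC) for (c in .NUC) {
      k <- k + 1L
      aa <- code[paste0(a, b, c)]
      codon_aa[k] <- if (aa == "*") -1L else match(aa, rownames(B)) - 1L
    }
    .sim_cache$blosum <- B
    .sim_cache$codon_aa <- codon_aa
  }
  list(B = .sim_cache$blosum, codon_aa = .sim_cache$codon_aa)
}

.aa_to_int <- function(protein) {
  B <- .blosum_tables()$B
  v <- match(strsplit(toupper(protein), "")[[1]], rownames(B))
  v[is.na(v)] <- match("X", rownames(B))
  as.integer(v - 1L)
}

.dna_to_int <- function(dna) {
  v <- match(strsplit(toupper(dna), "")[[1]], .NUC)
  v[is.na(v)] <- 5L
  as.integer(v - 1L)
}

#' Frameshift-aware protein-to-DNA alignment
#'
#' Locally aligns a reference protein against a genomic window, allowing
#' the aligned codons to switch among the three forward frames (penalty
#' `fs_pen` per switch, modelling 1-nt insertions/deletions) and to cross
#' stop codons (penalty `stop_pen` per crossed stop). Residue scores are
#' BLOSUM62; gaps are affine (open 11, extend 1). Both strands are
#' scanned and the better one is kept.
#'
#' @param reference_protein Reference protein sequence (string).
#' @param genomic_window Nucleotide window (string, >= 9 nt).
#' @param params Optional overrides of the scoring defaults
#'   (`gap_open`, `gap_ext`, `stop_pen`, `fs_pen`, `ambig_score`).
#' @param strands Strands to scan (default both; the better one is kept).
#' @return list: `score`, `strand` (`"+"`/`"-"`), `coverage` (aligned
#'   residues / reference length), `n_stops`, `n_shifts`, `stops` and
#'   `shifts` (1-based reference residue positions), `ref_range`,
#'   `window_range` (1-based on the scanned strand).
#' @export
#' @examples
#' cds <- "ATGAAAGTTCTGGCTGCTGCTAAACGT"
#' frameshiftAwareAlign(translateCDS(paste0(cds, "TAA")), cds)$n_shifts
frameshiftAwareAlign <- function(reference_protein, genomic_window,
                                 params = list(), strands = c("+", "-")) {
  if (nchar(genomic_window) < 9L) stop("window shorter than 9 nt")
  if (!nzchar(reference_protein)) stop("empty reference protein")
  p <- utils::modifyList(.FS_DEFAULTS, params)
  tb <- .blosum_tables()
  ref <- .aa_to_int(reference_protein)
  run <- function(win) {
    .fs_align(ref, .dna_to_int(win), tb$B, tb$codon_aa,
              p$gap_open, p$gap_ext, p$stop_pen, p$fs_pen, p$ambig_score)
  }
  fwd <- if ("+" %in% strands) run(genomic_window) else list(score = -Inf)
  rev <- if ("-" %in% strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(genomic_window)))
    run(rc)
  } else list(score = -Inf)
  best <- if (rev$score > fwd$score) c(rev, strand = "-") else c(fwd, strand = "+")
  m <- nchar(reference_protein)
  list(score = best$score, strand = best$strand,
       coverage = best$n_aligned / m,
       n_stops = length(best$stops), n_shifts = length(best$shifts),
       stops = best$stops, shifts = best$shifts,
       ref_range = c(best$ref_first, best$ref_last),
       window_range = c(best$dna_first, best$dna_last))
}

## self-score of a protein under BLOSUM62 (diagonal sum)
.self_score <- function(protein) {
  B <- .blosum_tables()$B
  i <- .aa_to_int(protein) + 1L
  sum(B[cbind(i, i)])
}

## candidate windows: annotated loci +/- 1 kb plus all unannotated
## (intergenic) stretches, long regions split into <= max_len chunks
## overlapping by 300 nt
.build_windows <- function(genome_length, annotation, flank = 1000L,
                           overlap = 300L, max_len = 3500L) {
  loci <- IRanges::ranges(annotation)
  cand <- c(
    IRanges::restrict(loci + flank, start = 1L, end = genome_length),
    IRanges::gaps(IRanges::reduce(loci), start = 1L, end = genome_length)
  )
  cand <- cand[IRanges::width(cand) >= 9L]
  chunks <- lapply(seq_along(cand), function(i) {
    s <- IRanges::start(cand)[i]; e <- IRanges::end(cand)[i]
    if (e - s + 1L <= max_len) return(IRanges::IRanges(s, e))
    starts <- seq(s, e - overlap, by = max_len - overlap)
    IRanges::IRanges(starts, pmin(starts + max_len - 1L, e))
  })
  out <- do.call(c, chunks)
  unique(out)
}

## 8-mer prescreen: does any exact reference 8-mer occur in a 6-frame
## translation of the window?
.kmer_set <- function(protein, k = 8L) {
  n <- nchar(protein)
  if (n < k) return(protein)
  unique(substring(protein, 1:(n - k + 1L), k:n))
}

.window_kmers <- function(win, k = 8L) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(win)))
  code <- .codon_tables()$code
  frame_kmers <- function(s) {
    L <- nchar(s)
    prots <- character(0)
    for (f in 0:2) {
      n_codons <- (L - f) %/% 3L
      if (n_codons >= 1L) {
        starts <- f + seq(1L, by = 3L, length.out = n_codons)
        aa <- unname(code[substring(s, starts, starts + 2L)])
        aa[is.na(aa)] <- "X"
        prots <- c(prots, strsplit(paste(aa, collapse = ""), "*",
                                   fixed = TRUE)[[1]])
      }
    }
    unlist(lapply(prots[nchar(prots) >= k], .kmer_set, k = k),
           use.names = FALSE)
  }
  list(fwd = frame_kmers(win), rev = frame_kmers(rc))
}

#' Scan a genome for a reference gene set and classify each gene
#'
#' For every reference protein, aligns it ([frameshiftAwareAlign()])
#' against candidate windows of the genome -- annotated gene loci plus
#' 1 kb of flank, and all intergenic stretches, overlapping by 300 nt --
#' and classifies the gene: `ABSENT` when the best score is below
#' `min_score_frac` of the reference self-score, else `PSEUDOGENE` when
#' the best alignment crosses an internal stop, switches frame, or covers
#' less than `truncation_frac` of the reference, else `INTACT`. An exact
#' 8-mer peptide prescreen (6-frame) skips windows that cannot match.
#'
#' @param references Named character vector of reference proteins.
#' @param genome_sequence `DNAString` (or string) of the genome.
#' @param annotation `GRanges` of annotated CDS features.
#' @param genome_id Label for the genome column of the result.
#' @param truncation_frac Coverage below which a gene counts as severely
#'   truncated (default 0.5).
#' @param min_score_frac Fraction of the reference self-score required to
#'   call presence (default 0.4).
#' @param params Scoring overrides passed to [frameshiftAwareAlign()].
#' @param prescreen Disable the 8-mer prescreen by setting `FALSE`.
#' @return A [GeneStatusMatrix-class] with one row per reference gene.
#' @export
scanGenome <- function(references, genome_sequence, annotation,
                       genome_id = "genome", truncation_frac = 0.5,
                       min_score_frac = 0.4, params = list(),
                       prescreen = TRUE) {
  if (!methods::is(genome_sequence, "DNAString"))
    genome_sequence <- Biostrings::DNAString(genome_sequence)
  glen <- length(genome_sequence)
  wins <- .build_windows(glen, annotation)
  win_seq <- vapply(seq_along(wins), function(i)
    as.character(Biostrings::subseq(genome_sequence, IRanges::start(wins)[i],
                                    IRanges::end(wins)[i])), character(1))
  win_km <- if (prescreen) lapply(win_seq, .window_kmers) else NULL
  rows <- lapply(names(references), function(gid) {
    ref <- references[[gid]]
    selfsc <- .self_score(ref)
    refkm <- if (prescreen) .kmer_set(ref) else NULL
    cand <- seq_along(win_seq)
    strands <- rep(list(c("+", "-")), length(win_seq))
    if (prescreen) {
      hitf <- vapply(win_km, function(ws) any(refkm %in% ws$fwd), logical(1))
      hitr <- vapply(win_km, function(ws) any(refkm %in% ws$rev), logical(1))
      cand <- which(hitf | hitr)
      strands <- lapply(seq_along(win_seq), function(i)
        c("+", "-")[c(hitf[i], hitr[i])])
    }
    best <- NULL
    for (i in cand) {
      hit <- frameshiftAwareAlign(ref, win_seq[[i]], params = params,
                                  strands = strands[[i]])
      if (is.null(best) || hit$score > best$score) { best <- hit; best$win <- i }
    }
    if (is.null(best) || best$score < min_score_frac * selfsc) {
      return(data.frame(gene_id = gid, genome = genome_id, status = "ABSENT",
                        coverage = if (is.null(best)) 0 else best$coverage,
                        evidence = "", score = if (is.null(best)) NA_real_ else best$score,
                        stringsAsFactors = FALSE))
    }
    ev <- character(0)
    if (best$n_stops > 0)
      ev <- c(ev, paste0("PREMATURE_STOP@", paste(best$stops, collapse = ",")))
    if (best$n_shifts > 0)
      ev <- c(ev, paste0("FRAMESHIFT@", paste(best$shifts, collapse = ",")))
    if (best$coverage < truncation_frac)
      ev <- c(ev, sprintf("TRUNCATION(cov=%.2f)", best$coverage))
    status <- if (length(ev)) "PSEUDOGENE" else "INTACT"
    data.frame(gene_id = gid, genome = genome_id, status = status,
               coverage = best$coverage,
               evidence = paste(ev, collapse = ";"), score = best$score,
               stringsAsFactors = FALSE)
  })
  GeneStatusMatrix(do.call(rbind, rows))
}

#' Classify one aligned gene
#'
#' Applies the status rules to a single [frameshiftAwareAlign()] result.
#'
#' @param hit Result list of [frameshiftAwareAlign()].
#' @param self_score BLOSUM62 self-score of the reference protein.
#' @param truncation_frac,min_score_frac Thresholds as in [scanGenome()].
#' @return One of `"ABSENT"`, `"PSEUDOGENE"`, `"INTACT"`.
#' @export
classifyGene <- function(hit, self_score, truncation_frac = 0.5,
                         min_score_frac = 0.4) {
  if (hit$score < min_score_frac * self_score) return("ABSENT")
  if (hit$n_stops > 0 || hit$n_shifts > 0 || hit$coverage < truncation_frac)
    return("PSEUDOGENE")
  "INTACT"
}

#' Pathway-by-genome status matrix
#'
#' Arranges per-gene statuses into the pathway presentation: one row per
#' pathway gene, one status column per genome, with per-pathway summary
#' counts.
#'
#' @param statuses A [GeneStatusMatrix-class] covering all genomes (e.g.
#'   rbind of per-genome scans), or a list of them.
#' @param pathways Pathway definition data.frame (`pathway`, `gene_id`,
#'   optional `excluded`).
#' @return list with `matrix` (data.frame pathway, gene_id, one column
#'   per genome) and `summary` (per pathway x genome counts of
#'   INTACT/PSEUDOGENE/ABSENT).
#' @export
pathwayStatusMatrix <- function(statuses, pathways) {
  if (is.list(statuses) && !methods::is(statuses, "GeneStatusMatrix"))
    statuses <- GeneStatusMatrix(do.call(rbind, lapply(statuses, statusTable)))
  df <- statusTable(statuses)
  pw <- pathways
  if (!is.null(pw$excluded)) pw <- pw[!pw$excluded, , drop = FALSE]
  genomes <- sort(unique(df$genome))
  missing <- setdiff(pw$gene_id, df$gene_id)
  if (length(missing))
    stop("pathway gene(s) not scanned: ", paste(missing, collapse = ", "))
  m <- data.frame(pathway = pw$pathway, gene_id = pw$gene_id,
                  stringsAsFactors = FALSE)
  for (gn in genomes) {
    sub <- df[df$genome == gn, , drop = FALSE]
    m[[gn]] <- sub$status[match(pw$gene_id, sub$gene_id)]
  }
  long <- do.call(rbind, lapply(genomes, function(gn)
    data.frame(pathway = m$pathway, genome = gn,
               status = factor(m[[gn]], levels = c("INTACT", "PSEUDOGENE", "ABSENT")))))
  summary <- as.data.frame(table(long$pathway, long$genome, long$status))
  names(summary) <- c("pathway", "genome", "status", "count")
  list(matrix = m, summary = summary)
}
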
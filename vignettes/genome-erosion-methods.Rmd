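---
title: "Methods: quantifying differential genome erosion between endosymbiont lineages"
author: "SymbiontErosion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying differential genome erosion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SymbiontErosion)
```

## The scientific problem

Endosymbiotic bacteria descended from free-living ancestors lose genes:
relaxed selection on dispensable functions lets non-synonymous mutations
accumulate, pathways break gene by gene, and genomes shrink. When two
sibling endosymbiont lineages share one reduction event but then evolve
independently, their erosion speeds can differ, and that difference should
be visible twice over — in the per-gene non-synonymous rates of the genes
both genomes still share, and in the pattern of which pathways have
already collapsed into pseudogenes in which genome. This package measures
both signals on a fixed five-taxon species tree: the two endosymbionts
(`SB1`, `SB2`) sister to each other, a free-living sister pair
(`OUT1`, `OUT2`), and an outer free-living lineage (`OUT3`).

Two branches carry the comparative quantities. Branch X is always the
terminal branch of the focal endosymbiont SB1. Branch Y is, on the
two-endosymbiont tree, the paired terminal branch of SB2 (the quantity of
interest is the per-gene difference of the two); on the four-taxon tree
without SB2 it is the branch from SB1's parent node to the free-living
sister ancestor, used to standardize rates.

## Branch-specific dN: counting, not maximum likelihood

Per-gene, per-branch dN is estimated by a counting pipeline:

1. **Ancestral codons by weighted parsimony.** Each gap-free alignment
   column is assigned internal-node codons minimizing the total number of
   nucleotide changes on the tree (Sankoff dynamic programming over the 61
   sense codons of translation table 11). Ties are broken deterministically:
   first toward assignments implying fewer non-synonymous changes —
   conservative for dN, the quantity under test — then toward the
   lexicographically smallest codon. Both tie-break criteria are folded
   into a single integer edge cost (primary × 1024 + 6 × path-averaged
   non-synonymous count), so one min-sum DP realizes the lexicographic
   objective exactly.
2. **NG86 counting per branch.** Between the two endpoint codons of every
   branch, synonymous/non-synonymous differences are counted with
   multi-step codon differences averaged over all minimal mutational
   paths; paths through stop codons are excluded unless every path is.
   Site totals use the fractional single-nucleotide-neighbour partition
   (neighbours that are stops leave the denominator), averaged over the
   two endpoint sequences.
3. **Jukes–Cantor correction.** `dN = -3/4 · ln(1 - 4/3 · pN)`. A
   proportion at or beyond 3/4 cannot be corrected; such entries are kept
   with `dN = NA` and `saturated = TRUE` rather than dropped silently.

A full maximum-likelihood codon model would estimate the same quantity;
at the shallow divergences this system occupies (a few percent per
branch), counting and ML agree closely, and every downstream statistic
uses ranks or ratios that are robust to the estimator choice. The package
therefore keeps the transparent estimator and verifies it three ways in
the test suite: site classes against exhaustive neighbour enumeration for
all 61 codons, reconstruction cost against brute-force Sankoff on random
columns, and two-taxon additivity against the independent pairwise NG86
implementation (exact, at matched site partitions).

Columns containing a gap in any row are excluded everywhere (complete
deletion) — the conservative standard for counting methods.

## Comparative statistics

* **Standardization.** `ratio = dN(X) / dN(Y)` per gene; a zero in either
  branch makes the gene impossible to standardize and it is omitted (the
  omission is recorded, and reported counts always separate omitted
  genes). The ratio is scale-equivariant by construction.
* **Outlier screen.** Iterative two-sided Grubbs test at α = 0.005
  (default), critical value from the t distribution:
  `G = (n-1)/sqrt(n) · sqrt(t² / (n-2+t²))`, `t = t(α/2n, n-2)`. Both
  slow and fast outliers are screened (two-sided), since either tail can
  distort rank statistics. The screen's false-flag rate on clean normal
  samples is checked in the tests (≤ 1 %).
* **Pathway relaxation.** Wilcoxon rank-sum, pathway genes vs all
  non-pathway genes (never overlapping): exact enumeration when both
  groups have ≤ 12 untied values, otherwise midranks with tie-corrected
  variance and continuity correction. Both the one-sided ("pathway
  greater") and two-sided p-values are reported with the direction
  flagged, since either convention may be wanted.
* **Paired lineage test.** ΔdN = dN(SB1) − dN(SB2) per ortholog with
  finite rates on both branches. Zero differences are dropped for the
  signed-rank test (exact for ≤ 25 untied differences, tie-corrected
  normal approximation otherwise), but the reported mean ΔdN includes
  them. The headline p-value uses all non-zero differences; a companion
  value excluding Grubbs-flagged differences is also reported, because
  outlier exclusion is a display convention, not part of the test.

## Pseudogene detection

Disrupted genes are found by aligning reference proteins (the sister
genome's intact orthologs, falling back to a free-living relative when
both copies are damaged) against genomic windows with a frameshift-aware
local dynamic program: residues align to codons in any forward frame of
either strand; codon advances of 2 or 4 nucleotides model 1-nt
indels (penalty 12); residue-vs-stop-codon matches cost 8; substitution
scores are BLOSUM62 with affine gaps (11 open, 1 extend, first gap
position 12 as in BLAST). Windows are the annotated loci ± 1 kb plus all
intergenic stretches, split above 3.5 kb with 300 nt overlap. An exact
8-mer peptide prescreen over the six-frame translation skips windows that
cannot plausibly match; it can be disabled (`prescreen = FALSE`), and the
strand-symmetry test exercises the scan both ways.

Classification: **ABSENT** if no window reaches 40 % of the reference
self-score (`min_score_frac`); otherwise **PSEUDOGENE** if the best
alignment crosses an internal stop, switches frame, or covers < 50 % of
the reference (`truncation_frac`); otherwise **INTACT**. Both thresholds
are exposed. The two rules interact: a truncation that removes much more
than half the gene also drops below the score floor and is reported
ABSENT — past that point a remnant genuinely is indistinguishable from a
deleted gene by sequence alone. The shipped lesion profile places its
truncations at 48 % of gene length, inside the band where the remnant is
recognizable but below the coverage threshold, and documents this
detectability limit.

## The synthetic-data generator

The simulator is a GY94-style continuous-time Markov chain on the 61
sense codons: single-nucleotide codon changes at rate proportional to the
target codon's frequency, × κ for transitions, × the branch's ω for
non-synonymous changes; multi-nucleotide instantaneous changes have rate
zero and stops are unreachable. The generator is normalized per branch so
that branch lengths are expected substitutions per codon *at that
branch's ω*. Two consequences worth knowing:

* dN is sublinear in ω (the non-synonymous share of a fixed total flux),
  so an ω ratio of 1.25 between two branches yields a dN ratio nearer
  1.14. All recovery checks compare against expectations integrated from
  the generator matrix itself, not against ω naively.
* Expected non-synonymous divergence on any path is available in closed
  form from the generator (the tests' oracle), which is why this model
  was chosen over more elaborate ones.

Defaults: κ = 2, ω = 0.2 on every branch, branch lengths 0.05, uniform
codon frequencies, genes of 300 codons — divergences of a few percent per
branch, the regime of a recently split pair of endosymbiont genomes, and
gene lengths near a typical bacterial CDS. The root sequence is drawn
from the codon frequencies. Each gene is a deterministic function of
`(seed, gene_index)` via a private substream, so single genes can be
regenerated in isolation; the batch interface (`simulateOrthologSet`)
draws all genes from one seeded stream for replicate studies. The genome
fabricator wraps the simulated SB1/SB2 leaf sequences into annotated
genomes — ATG start and TAA stop added, genes on random strands separated
by uniform-random 50–500 nt spacers — injects the requested lesions, and
logs every lesion in a truth table. Lesioned genes stay in the genome
sequence but leave the annotation and the intact protein sets: they are
exactly what the scanner must rediscover.

What the generator does **not** emulate: within-alignment indels (gene
alignments are gap-free), among-site rate heterogeneity, codon-usage or
GC bias (uniform frequencies give ~50 % GC, far above a real
endosymbiont's), rearrangements, paralogy, and any lesion-frequency
spectrum beyond what the user specifies. Green tests on fabricated data
therefore certify the machinery — counting, reconstruction, pairing,
scanning, statistics — under a clean generative model, not robustness to
every idiosyncrasy of real assemblies.

## Ortholog pairing and codon alignment

Orthologs are paired by reciprocal best hit on global protein alignment
score (BLOSUM62, affine 11/1): a pair forms only when each member is the
other's unique top partner; equal top scores exclude the gene. Genes
under 30 residues are not considered (scores too unstable). Outgroup taxa
attach by RBH against the SB1 set (star extension); a tuple is complete
when every taxon contributes a member, and only complete tuples enter
tree-based rate estimation. Protein alignments for complete tuples are
built deterministically by pairwise global alignment of every sequence
against the SB1 sequence, merged on its coordinates ("once a gap, always
a gap") — adequate for near-gap-free data, where the load-bearing
contract is codon back-threading: every amino-acid column expands to its
source codon, a terminal stop is allowed and stripped, and any
CDS/protein mismatch is an error rather than a warning.

## Problem sizes and numerical choices

The validation suite runs at the following scales, chosen to mirror the
study design while staying desk-sized: the paired-lineage check uses
1,450 genes × 300 codons for each of five seeds; type-I calibration uses
400 replicates of 300 genes × 150 codons (shorter genes make more zero
differences, which the signed-rank test must drop correctly — a useful
stress); pathway-relaxation power uses 50 replicates of a 10-gene pathway
at 3× ω against a 300-gene background at 300 codons; estimator-recovery
regressions use 500 genes per ω in {0.05, 0.2, 0.5}; scanner validation
fabricates 40-gene genomes at 300 codons carrying the two-pathway lesion
profile. Matrix exponentials for the per-branch transition kernels come
from eigendecomposition (`ape::matexpo`) with negative entries clipped at
zero and rows renormalized; kernels are memoized on the exact parameter
values. All randomness flows from explicit integer seeds; per-gene seeds
are mixed arithmetically (exact in double precision, always < 2³¹).

## Known limitations

* The counting estimator shares NG86's biases: at high divergence or
  extreme codon bias it misestimates site counts, and the Jukes–Cantor
  correction saturates at p = 3/4 (flagged, not fixed).
* Parsimony ancestors understate multiple hits on long branches; the
  package targets shallow trees and flags nothing beyond saturation.
* The star protein aligner is not a general MSA tool; with substantial
  indel structure a dedicated aligner should produce the protein MSA,
  which can then be codon-threaded here.
* The pseudogene scanner's ABSENT/PSEUDOGENE boundary is intrinsically
  threshold-dependent for deep truncations (see above), and scan
  sensitivity for lesions within ~10 codons of gene ends is limited — a
  local alignment can simply shed a damaged terminus.
* Genome-wide pseudogene totals and functional-repertoire (KO) assignment
  require external databases and are out of scope; the package consumes
  pre-assigned identifier lists for repertoire comparison.
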
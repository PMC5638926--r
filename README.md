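# SymbiontErosion

Comparative genome-erosion analysis for reductively evolving bacterial
endosymbionts.

Obligate endosymbionts — such as the nitrogen-fixing, cyanobacterium-derived
"spheroid bodies" living inside rhopalodiacean diatoms — shed genes their
host-bound lifestyle has made dispensable. Two sibling endosymbiont lineages
descending from one free-living ancestor can erode at different speeds: one
may keep a biosynthetic pathway intact while the other has already reduced
the same pathway to pseudogenes. This package provides the statistical
machinery to quantify that asymmetry from two annotated endosymbiont genomes
plus a few free-living relatives, and a fully controlled synthetic data
generator to validate every step against known ground truth.

## What it computes

For each ortholog family aligned at the codon level on a fixed rooted
species tree (endosymbionts SB1, SB2; free-living relatives OUT1–OUT3):

* **Branch-specific dN.** Ancestral codons are reconstructed by weighted
  parsimony (Sankoff DP over the 61 sense codons, ties broken toward fewer
  non-synonymous changes, then lexicographically). On every branch,
  synonymous and non-synonymous sites and differences are counted in the
  Nei–Gojobori (1986) manner — fractional site classes from the
  single-nucleotide neighbourhood, multi-step codon differences averaged
  over all minimal mutational paths — and converted to rates with the
  Jukes–Cantor correction: `dN = -3/4 · ln(1 - 4/3 · pN)`.
* **Standardized rates.** A gene's dN on the focal endosymbiont branch
  (branch X) divided by its dN on a reference branch (branch Y), removing
  gene-specific rate variation. Genes with `dN = 0` on either branch cannot
  be standardized and are omitted. An iterative two-sided Grubbs test
  (α = 0.005) screens for outlier genes.
* **Pathway relaxation.** Wilcoxon rank-sum test (exact for small groups)
  comparing a pathway's standardized rates against the genome background —
  elevated pathway dN signals relaxed selective constraint even before
  genes visibly break.
* **Paired lineage comparison.** Per-ortholog ΔdN = dN(SB1) − dN(SB2) on
  the two terminal branches from the endosymbionts' common ancestor, tested
  against zero with the Wilcoxon signed-rank test.
* **Pseudogene detection.** A frameshift-aware protein-to-DNA local
  alignment (BLOSUM62, affine gaps 11/1, stop-codon crossings −8, frame
  switches −12, both strands) scans annotated loci and intergenic regions;
  genes are classified INTACT / PSEUDOGENE (internal stop, frameshift, or
  severe truncation) / ABSENT, and arranged into pathway-by-genome status
  matrices.
* **Synthetic truth.** A GY94-style codon simulator (single κ, per-branch
  ω, branch lengths in expected substitutions per codon) evolves ortholog
  alignments on the species tree, and a genome fabricator assembles
  annotated genome pairs with injected lesions (premature stops,
  frameshifts, truncations, deletions) recorded in a truth table.

## Worked example

Simulate 300 ortholog families on the five-taxon tree with the SB2 branch
evolving under ω 1.25× the SB1 branch, estimate branch rates, and run the
comparative statistics:

```r
library(SymbiontErosion)

topo   <- simTopology("two-sb", branch.length = 0.05)
params <- simParams(n_genes = 300, codons_per_gene = 300, kappa = 2,
                    omega = c(.default = 0.2, SB2 = 0.25), seed = 1)
sim    <- simulateOrthologSet(topo, params)
rates  <- estimateBranchRatesFromStates(sim, topo)
rates
#> BranchRateTable: 300 genes x 8 branches (0 saturated entries)

report <- erosionAnalysis(rates, topo, std_branch_y = "OUTANC")
report
#> ErosionReport
#>   standardized rates: 300 genes (2 omitted, 5 outliers)
#>   paired dN difference: n=299, mean delta=-0.0008581, V=18265, p=0.00544

head(deltaRecords(report), 3)
#>    gene_id      dn_sb1      dn_sb2        delta outlier
#> 1 gene0001 0.004539736 0.007566268 -0.003026532   FALSE
#> 2 gene0002 0.003053439 0.010733636 -0.007680196   FALSE
#> 3 gene0003 0.009114036 0.010650616 -0.001536580   FALSE
```

The negative mean ΔdN and the signed-rank p-value say that SB2's genes
accumulate non-synonymous substitutions faster than SB1's — the faster
lineage is the one we simulated with the relaxed (higher-ω) terminal
branch. At the full study scale (1,450 orthologs) the same contrast is
detected at p ≪ 0.001.

`runPipeline(pipelineConfig(...))` chains every stage — fabrication with
lesions, reciprocal-best-hit ortholog pairing, protein alignment and codon
back-threading, branch rates, statistics, and the pseudogene scan — and
`writePipelineArtifacts()` emits all tables. A thin command-line wrapper
lives in `inst/scripts/erosion-pipeline.R` (subcommands `run`, `simulate`,
`summary`, `compare-ids`).

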
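# intronr

Differential intron retention analysis for yeast RNA-Seq.

In intron-poor yeasts, mutants of mRNA-surveillance (NMD: *UPF1*, *UPF2*) and
exon-junction-complex genes (*MAGO*, *Y14*) change how much unspliced intronic
sequence persists in the transcript pool. `intronr` quantifies that signal
from annotated alignments and tests it, for the standard design of one control
strain and several knockouts with a few biological replicates each. It is
aimed at people analyzing such strain panels who want every analysis step —
from the intron annotation to the retention heatmap ordering — as inspectable,
tested R functions rather than a fixed pipeline.

## What it computes

* **Intron features**: introns are the gaps between consecutive exons with a
  minimal size of 50 bp (inclusive), numbered in transcription order, written
  as a dedicated intron-only GFF3 (`parse_annotation()`, `extract_introns()`,
  `write_intron_gff()`).
* **Intersection-strict counting** (`assign_reads()`, `count_reads()`): a
  read belongs to a feature iff every aligned base is covered by it and by no
  other candidate surviving the per-base set intersection; otherwise it is
  `AMBIGUOUS` or `NO_FEATURE`. Gene loci and introns are counted in two
  separate passes.
* **Low-count filter**: drop features with RPK = `count × 1000 / length` ≤ 40
  in at least 10 of 15 libraries (both thresholds configurable).
* **Differential testing** (`de_analysis()`, `dr_test()`): per-feature
  negative-binomial regression with log link, median-of-ratios size factors
  `s_j`, method-of-moments dispersion `α_f = max((v−m)/m², 10⁻⁸)`, Wald
  p-values, Benjamini–Hochberg adjustment; a feature is called at
  |log2FC| ≥ 1.5 and adjusted p < 0.001. The intron test *borrows* the size
  factors of the complete gene-level dataset — the intron sub-matrix is too
  small a slice of the library to normalize itself, and re-estimating factors
  from it would absorb genuine global retention shifts.
* **Downstream sets**: union of DR introns across mutants, restriction to
  introns of non-differentially-expressed host genes, Euclidean/complete
  clustering of the fold-change heatmap, and correspondence-analysis library
  clustering on a five-quantile-discretized count matrix.
* **Synthetic data with ground truth** (`simulation_scenario()`,
  `simulate_annotation()`, `simulate_counts()`, `simulate_reads()`): the
  5-strain × 3-replicate design with known DE genes and DR introns, down to
  SAM-level read streams that reproduce the count matrices exactly.
* **Auxiliaries**: Dollo parsimony mapping of gene losses on a rooted species
  tree with a Fitch cross-check (`dollo_min_losses()`, `fitch_min_changes()`,
  `package_cooccurrence()`, with a curated EJC presence/absence survey in
  `ejc_survey()`), and Pfaffl qPCR quantification
  (`E = 10^(−1/slope)`, `ratio = E_t^ΔCt_t / E_ref^ΔCt_ref`).

## Worked example

A full simulated run — generate the panel, test every mutant against the
control, restrict, cluster:

```r
library(intronr)

cfg <- run_config(scenario = simulation_scenario(seed = 20260929L))
out <- run_pipeline(cfg)
out$summary
#>  comparison genes_up genes_down introns_more_retained introns_less_retained dr_in_non_de_genes
#>        upf1       11          9                    34                     0                 31
#>        upf2        5          4                    14                     0                 14
#>        mago        3          5                     6                     0                  6
#>         y14       29         35                     0                    39                 33
out$summary_totals
#>  introns_dr_any_mutant dr_in_non_de_any
#>                     71               66
```

Reading the table: each row is one mutant-versus-control comparison.
`genes_up`/`genes_down` count genes passing the |log2FC| ≥ 1.5,
adjusted-p < 0.001 cutoffs; the intron columns count differentially retained
introns by direction. The NMD-like mutants (`upf1`, `upf2`) only gain
retention, the EJC-like `y14` only loses it — the directional signature the
generator encodes and the test recovers. `dr_in_non_de_genes` keeps only DR
introns whose host gene is itself unchanged, isolating splicing-level
effects; 71 introns are DR in at least one mutant. Per-comparison tables,
fold changes, and the heatmap/library clusterings are in `out$gene_de`,
`out$dr`, `out$union`, `out$clustering`, and `out$coa`.

The phylogenetic module, on the packaged survey:

```r
srv <- ejc_survey()
package_cooccurrence(srv$traits, c("MAGO", "Y14"), clade = "Saccharomycotina")$count
#> [1] 7
present <- srv$traits$species[srv$traits$MAGO == "+" & srv$traits$Y14 == "+"]
dollo_min_losses(srv$tree, present)$n_losses
#> [1] 2
```

Seven budding-yeast species carry both EJC core genes, and the minimal
losses-only history places exactly two independent losses: one in the
Saccharomycetaceae ancestor, one before the CTG-clade/Pichiaceae divergence.

See `vignettes/intron-retention-methods.Rmd` for the statistical model,
parameter defaults, and the generator's assumptions and limitations.

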
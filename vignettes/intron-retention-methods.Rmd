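---
title: "Differential intron retention: models, defaults, and design choices"
author: "intronr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential intron retention: models, defaults, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In yeasts that retain spliceosomal introns, mutants of mRNA-surveillance and
exon-junction-complex (EJC) genes change how much unspliced intronic sequence
survives in the transcript pool. Bulk RNA-Seq can quantify this directly: reads
that align inside an annotated intron measure retention of that intron, and a
count-based differential test between a mutant and a control strain identifies
*differentially retained* (DR) introns. `intronr` implements that analysis
end to end for the standard design of one control and several knockout strains
with a few biological replicates each, plus two auxiliary computations used in
the same kind of study: parsimony mapping of gene losses on a species tree, and
Pfaffl relative quantification of validation qPCR.

# Counting model

## Feature sets and intersection-strict assignment

Two feature sets are counted in two separate passes:

* **gene pass** — the complete locus span of every coding gene;
* **intron pass** — a dedicated intron-only feature set, written as its own
  GFF3 file (`extract_introns()`, `write_intron_gff()`), introns being the
  gaps between consecutive exons with a minimal size of 50 bp (inclusive).

Assignment is *intersection-strict*: for every aligned base of a read, form
the set of features covering that base, and intersect the sets across all
bases of all aligned blocks. A singleton assigns the read; an empty
intersection (any uncovered base, or no common feature) is `NO_FEATURE`; a
larger one is `AMBIGUOUS`. Equivalently — and this is how `assign_reads()`
computes it — a read belongs to a feature exactly when the feature's interval
union contains every block.

The two passes are kept separate because a combined gene-plus-intron set
destroys the intron signal: an intron lies inside its host locus, so every
intron-interior read sees both features at every base and is ambiguous. Note
the contract's corollary for reads straddling an exon/intron boundary: against
locus-span genes plus introns they resolve to the gene alone (the exon-side
bases exclude the intron); against exon-defined genes plus introns the
intersection is empty. Either way such reads never support an intron, which is
the honest behavior at a boundary.

Strandedness is off by default (non-strand-specific library preparation);
only primary alignments are counted.

## The RPK filter

Weakly covered features are removed before testing: a feature is dropped when
its RPK (`count × 1000 / length_bp`, computed from **raw** counts — the filter
precedes normalization) is ≤ 40 in at least `ceiling(2n/3)` of the `n`
libraries (10 of 15 in the five-strain, three-replicate design). Both
thresholds are `filter_spec()` parameters. The ≤ at the boundary is
deliberate: RPK exactly 40 counts as low.

# Statistical model

## Size factors

Libraries are made comparable with median-of-ratios size factors: for each
feature positive in all libraries, the reference is its geometric-mean count;
a library's factor is the median ratio of its counts to the reference,
rescaled so the factors have geometric mean 1. If no feature is positive
everywhere, total counts are used (with a warning).

## Borrowed normalization for the intron matrix

Intron-assigned reads are a small slice of the total, and a mutant can shift
retention globally. Re-estimating size factors *from the intron matrix* would
absorb such a genuine global shift into the normalization and erase it from
the fold changes. `dr_test()` therefore requires size factors estimated on the
complete gene-level dataset of the same libraries and never re-estimates them.
This is the single analytic difference between the gene-level and intron-level
tests; the filter, dispersion, test, and thresholds are identical. A
total-count alternative is selectable (`normalization = "total"`).

## Dispersion and the Wald test

Per-feature dispersion is method-of-moments on normalized counts:
`alpha = max((v - m) / m^2, 1e-8)` with `m` the pooled mean and `v` the
pooled within-group variance. Each mutant-versus-control comparison is then
fit independently as a log-link negative-binomial regression on the two-group
indicator with `log` size factors as offset and `alpha` held fixed, by
iteratively reweighted least squares (up to 50 iterations, coefficient
tolerance 1e-8, linear predictor clamped to ±30 to keep degenerate fits
finite). The reported `log2fc` is the group coefficient over `log 2`; the
p-value is the two-sided Wald test under the normal approximation, and
Benjamini–Hochberg adjustment is applied across features.

Deliberately *not* included: dispersion-trend or fold-change shrinkage,
multi-group designs, outlier replacement, pseudocounts. Features all-zero in
both groups return the null result (`log2fc = 0`, `p = 1`); fits that do not
converge (e.g. one group all zero, where the NB maximum sits at minus
infinity) are flagged and also report `p = 1` — a conservative convention
worth knowing about when baseline coverage is very low.

A feature is `up` when `log2fc ≥ 1.5` and `padj < 0.001`, `down`
symmetrically; the fold-change boundary is inclusive and both cutoffs are
arguments (1 is the common relaxed fold-change alternative). DR introns in a
mutant are the `up`/`down` introns of that comparison, `up` meaning more
retained.

## Downstream sets and displays

`union_dr()` collects introns significant in at least one mutant, keeping the
full fold-change matrix for display. `restrict_to_nonde()` keeps a DR intron
only when its host gene is `ns` in the same comparison — a retention change
inside a gene that is itself differentially expressed may simply track the
gene. Host genes removed by the gene-level filter are excluded too: their
non-differential status cannot be certified. `cluster_fold_changes()` orders
the heatmap with Euclidean distance and complete linkage on rows and columns
(rows pre-sorted by id, so the ordering is deterministic under input
permutation); `coa_library_clustering()` reproduces the library display:
counts discretized into five levels at the 20/40/60/80% quantiles of the
nonzero entries (zeros form their own lowest level, a choice recorded in the
output), correspondence analysis as the SVD of standardized Pearson residuals
of the discretized table, Euclidean distances over all retained axes, average
linkage. The orientation is features × libraries with libraries as columns.
Colors and rendering are cosmetic; the tested surface is orderings and merge
heights.

# The synthetic-data generator

`simulation_scenario()` encodes the study conditions the analysis is designed
for: five strains (one control, four mutants) × three biological replicates,
per-library depth multipliers uniform on [1, 1.6] (the ~1.6-fold spread seen
between real libraries, with depths scaled down to roughly 65–105k reads per
library so a full run takes seconds), log-normal baseline expression,
negative-binomial counts at dispersion 0.05, and intron retention expressed
as a fraction rho ∈ [0.05, 0.2] of host-gene read density. Intron-bearing
hosts draw expression from `lognormal(log 40 + 1.8, 0.5)` rather than the
genome-wide `lognormal(log 40, 1)`: yeast intron-containing genes skew
strongly toward highly and uniformly expressed genes, and this keeps intron
coverage in the regime where the RPK-40 filter passes the tested universe.
Mutant effects are per-strain: a fraction of genes shifted by a log-normal
log2 effect with random sign, a fraction of introns with retention multiplied
(8 by default) upward (NMD-mutant-like) or downward (EJC-mutant-like), and
optionally a global retention multiplier on every intron — the scenario that
distinguishes borrowed from subset normalization.

`simulate_reads()` places one single-block read uniformly inside its feature
for every counted unit, so counting the stream against the same feature set
reproduces the count matrix exactly — the count-level truth stays exact, and
the read level is exercised without a sequence simulator. A
`boundary_fraction` instead straddles feature starts to probe the ambiguity
contract. Spliced (multi-block) reads appear only in counting tests.

What the generator does **not** emulate: sequence content and mapping error,
positional coverage bias, physical coupling between retention and host-gene
read loss (an 8× multiplier on a baseline fraction near 0.2 can push intron
read density above the host's, beyond the physical bound of a fully
unspliced pool), isoform structure beyond one intron per gene, and
correlation between replicates. Passing recovery tests on these simulations
demonstrates that the machinery is correct under its own model, not that real
libraries satisfy the model.

# Parsimony and qPCR modules

Gene-loss mapping uses the Dollo model — a single origin at the root, losses
only, the natural model for gene-family loss: `dollo_min_losses()` counts the
edges leading to maximal all-absent subtrees, which is the minimal losses-only
reconstruction (verified in the tests against exhaustive enumeration over all
small topologies). The unrestricted Fitch count is kept as a cross-check and
never exceeds the Dollo count. A character absent from every tip is reported
as one loss at the root, with a message. The packaged presence/absence survey
(`ejc_survey()`) is a curated encoding of a published comparative survey of
EJC components across 32 Ascomycota and Basidiomycota species; the data file
header states which calls are species-level and which summarize clade-level
statements.

qPCR: efficiency `E = 10^(-1/slope)` from the standard curve;
`ratio = E_t^dCt_t / E_ref^dCt_ref` with `dCt = Ct(control) − Ct(sample)`
(the classic `2^-ddCt` when both efficiencies are 2); technical replicates
are averaged before `dCt`; biological replicates yield per-replicate ratios
compared across groups with a two-sided pooled-variance t test. Two equal
constant groups give `p = 1` by convention.

# Numerical and design choices

* **Coordinates** are 1-based closed everywhere, the GFF3 and
  GenomicRanges/IRanges convention; readers and writers never translate.
* **Multi-transcript genes** collapse to the union of exons (with a warning)
  before intron derivation; overlapping exons within one transcript are a
  hard error, as is an exon with an unknown parent.
* **Intron numbering** follows transcription order: intron 1 is most 5', so
  on the minus strand it has the highest coordinates.
* **Ties in clustering** are broken by sorting rows by feature id before
  `hclust`.
* **Wald calibration**: with the dispersion supplied at its true value the
  test holds its nominal size in the acceptance checks; with the
  method-of-moments estimate from 3+3 replicates it runs anti-conservative,
  the known cost of ignoring dispersion-estimation error, which shrinkage
  methods exist to fix and this package deliberately does not implement.
* **Problem sizes** used by the test suite and acceptance script — 500-gene
  default scenarios, a 200-intron universe with 50 true DR introns at 8×,
  2,000 null features for calibration, all rooted topologies on ≤ 5 tips plus
  100 random 6-tip cases for the parsimony oracle — were chosen once as the
  smallest sizes at which the measured properties are stable.

# Known limitations

* The retention model treats intron read density relative to the host gene
  and tolerates values above 1 under strong multipliers (see above).
* The NB test reports `p = 1` for non-convergent fits, so a mutant that
  silences an intron *completely* from a low baseline may be missed; with the
  recommended coverage this is rare.
* Percent-spliced-in (junction-based) metrics, dispersion/fold-change
  shrinkage, and multi-factor designs are out of scope.
* The COA display is a visualization aid; no inferential claims attach to
  the dendrogram.
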
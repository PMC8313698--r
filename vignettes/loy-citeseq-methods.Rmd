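---
title: "Methods: LOY detection and CD99 differential abundance in CITE-seq data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LOY detection and CD99 differential abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Mosaic loss of chromosome Y (LOY) is the most common somatic mutation in the
blood of aging men: a fraction of circulating leukocytes simply lack the Y
chromosome. The `CD99` gene sits in pseudoautosomal region 1 (PAR1), present
on both X and Y; a cell that loses Y keeps its X-linked copy, so the expected
consequence of LOY is a dosage reduction of CD99 rather than its absence.
CITE-seq measures, in the same droplet, the mRNA of each cell (UMI counts)
and a panel of cell-surface proteins via antibody-derived tags (ADT). This
package implements the complete inference chain needed to ask whether LOY
cells carry less CD99 mRNA and surface protein than karyotypically normal
cells of the same leukocyte type, with appropriate confounder adjustment,
plus a generator of synthetic CITE-seq data so every stage is testable
without access to raw patient sequencing data.

## The LOY call

A cell is called LOY when it expresses autosomal genes but has **zero raw
counts** over the genes of the male-specific region of chromosome Y (MSY).
Two deliberate choices:

* The call operates on raw counts, never normalized values: presence of a
  transcript is a count-level statement.
* PAR genes — CD99 above all — are excluded from the MSY sum by explicit
  region filtering. Their retained X-linked copy would otherwise make every
  LOY cell look normal. The annotation module enforces this structurally:
  the `msy` and `par` symbol sets are disjoint by construction and a
  property test keeps them that way.

Cells with neither MSY nor autosomal counts are `UNDETERMINED` and excluded;
after QC they cannot occur (a kept cell has thousands of UMIs). Any nonzero
autosomal count satisfies the "expresses autosomal genes" clause; no further
threshold is imposed.

This rule cannot distinguish true Y loss from a cell whose MSY transcripts
all escaped sampling. The caller itself is deterministic and exact given the
counts; the detection-limit question lives in the generator as an explicit
`msy_dropout` knob (see below), so the caller's logic and the sampling
physics can be tested separately.

## Quality control

Three per-cell criteria on the RNA assay, with literal boundary semantics:

| criterion | rule | rationale |
|---|---|---|
| expressed genes | keep `n_genes <= 2000` | droplets with unusually many genes are likely doublets |
| total UMI | keep `n_umi >= 2500` | dead/low-quality cells |
| mitochondrial % | keep `1.5 <= pct_mito <= 5.0` (closed) | stressed or lysed cells |

`pct_mito` uses the `MT-` symbol prefix convention and is defined as 0 for
an all-zero cell (such a cell fails the UMI criterion regardless, and this
avoids 0/0). Rejected cells are labelled with the first failing criterion in
the fixed order genes, umi, mito. ADT counts of rejected cells are discarded
before protein normalization: cells are filtered first, then both assays are
normalized on kept cells only.

## Normalization

* **RNA**: `ln(1 + count * 10000 / total)` per cell (scale factor 10,000).
  Zeros stay zero, sparsity is preserved.
* **ADT**: centered log-ratio, `ln(1 + x) - mean_panel ln(1 + x)`, computed
  **per cell across the protein panel** by default. The panel is the
  composition being measured, which is why the per-cell margin is the
  default; the per-protein-across-cells convention found elsewhere in the
  ecosystem is available via `margin = "feature"`.
* **Display**: per-cell-type min-max scaling to [0, 1] exists purely for
  violin/box summaries (`make_figures()`); it never feeds any statistic.

Natural logarithms are used everywhere, so `percent = 100 * (exp(logFC) - 1)`
throughout (e.g. a logFC of −0.31 is a 27% decrease).

## Cell typing

Each targeted type has one diagnostic ADT marker (CD19 → B, CD14 →
classical monocyte, CD16 → non-classical monocyte, CD56 → NK, CD8 → CD8 T,
CD4 → CD4 T). A cell gets the type of its top CLR marker when that marker is
positive and beats the runner-up by a margin (default 0.5 CLR units),
otherwise `OTHER`; a CD14/CD16 double-high cell is a monocyte either way and
is resolved by the larger value rather than discarded by the margin rule.
Exact ties are broken alphabetically so assignments are invariant to panel
order. Direct marker typing replaces a PCA/graph-clustering stage on
purpose: the downstream inference needs labels, not clusters, and the
protein panel is itself the validated label source. `OTHER` cells are
excluded from per-type tests but enter the pooled model as their own
category.

## Statistical models

All per-type tests adjust for donor, library-prep batch, sequencing batch,
total UMI and mitochondrial percentage. With batches nested in donors the
design is rank-deficient by construction; aliased columns are dropped
deterministically in column order with a logged warning, so the fitted
models are always identifiable.

* **Protein (ADT)**: a likelihood-ratio test comparing logistic models of
  LOY-status on (covariates + analyte) versus (covariates), 1 df. Direction
  is the sign of the analyte coefficient; effect magnitude is reported as
  the average CLR difference (`avg_logfc`). Regressing group on analyte
  avoids distributional assumptions on CLR values. Under complete or
  quasi-complete separation the test falls back to a Firth-penalized fit
  (Jeffreys-prior score adjustment) and a penalized LRT, flagged with a
  warning.
* **RNA**: a two-part hurdle test for zero-inflated expression. Part one is
  a logistic model of detection (`value > 0`) on group + covariates; part
  two a Gaussian model of the positive log-normalized values on group +
  covariates. The group likelihood-ratio statistics add, with one df per
  estimable part (a part with no variation, or too few positive cells,
  contributes 0 df). A constant or all-zero analyte gives p = 1 with a
  warning. No minimum-expression or fold-change prefilters are applied —
  both are deliberately zero so every cell informs the model.
* **Effect size**: `avg_logfc` is `ln(mean(expm1(x))+1)` group difference
  for RNA (group means on the de-logged scale, re-logged with pseudocount
  1) and the plain CLR mean difference for ADT; `pct_change =
  100*(exp(avg_logfc)-1)` is an emitted-row invariant.
* **Multiplicity**: all p-values of a run — every cell type, analyte and
  assay — form one Benjamini–Hochberg family. Per-type tests with fewer
  than 20 cells in either group are reported as `NA` rather than fitted
  (small-group LRTs are unstable); `NA` rows do not count toward the family
  size.
* **Pooled model**: LOY-status ~ analyte + donor + both batches + UMI +
  mitochondrial % + cell type across all determined cells, reported as the
  Wald z and two-sided p of the analyte coefficient.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes, with
defaults encoding the study conditions: 4 donors, 2 sequencing batches (the
first two donors' libraries partly sequenced in a pilot run at lower
depth-scale), 5,000 singlets by default, six leukocyte types at realistic
PBMC proportions plus 5% `OTHER`, per-type LOY fractions of 5.6% (B), 15.2%
(CD14 monocytes), 15.0% (CD16 monocytes), 20.9% (NK), 8.6% (CD8 T) and 2.4%
(CD4 T), negative-binomial RNA and ADT counts (size 10), log-normal depth,
a Beta-distributed mitochondrial fraction inside the QC window with a 7%
outlier tail outside it, 1% doublets (same-donor count sums), and per-type
CD99 effect sizes in LOY cells taken from the study's effect table for both
assays.

Design choices worth spelling out:

* **Effects are parameterized on the estimator scale.** The configured
  `adt_effects` are the CLR-scale mean differences the analysis should
  recover. Because per-cell CLR over `p` proteins closes the composition, a
  count-mean multiplier `exp(l)` on one protein realizes only
  `(1 - 1/p) * l` on the CLR scale; the generator therefore injects
  `exp(l * p/(p-1))` on the CD99 ADT mean so the realized CLR effect is
  `l`. Likewise the RNA multiplier compensates the log1p pseudocount of the
  de-logged-means estimator: `m = ((M+1) e^l - 1)/M` with `M` the expected
  normalized CD99 mean. Property tests assert the realized effects on the
  estimator scale.
* **MSY detectability is a knob, not an accident.** Normal cells draw their
  MSY block conditioned on a positive total (a truly normal cell does
  transcribe Y genes; if the NB draw is all-zero one transcript is added to
  a weight-sampled MSY gene), and `msy_dropout` then thins each MSY gene
  per cell. At `msy_dropout = 0` the caller is provably exact; as dropout
  rises or depth falls, false-LOY calls appear monotonically — both tested.
  Expected MSY mass is calibrated to ~7 counts per normal cell at median
  depth.
* **Null integrity**: the six lineage-marker ADTs are generated identically
  in LOY and normal cells of a type, so they are true negatives for the
  differential tests.
* **What it does not emulate**: ambient RNA, UMI collisions, cross-donor
  transcriptional heterogeneity beyond depth/batch scaling, realistic
  full-transcriptome gene counts (a background panel of 2,400 genes keeps
  the >2000-expressed-genes doublet criterion live), RNA-level marker
  structure rich enough for transcriptome clustering, or empirical ADT
  background distributions. Passing tests therefore demonstrate
  correctness of the inference chain under the assumed data-generating
  process, not robustness to everything real data can do.

## Problem sizes and numerical choices

The test suite runs the replicate-heavy checks on a reduced 300-gene
background panel (the quantities checked — test calibration, caller
exactness, CLR-scale effect recovery — do not depend on background panel
size): type-I error is measured over 500 replicates of 2,000 cells under a
global-null configuration, effect recovery over 100 seeds of 5,000 cells,
and caller exactness on 10,000 cells at zero dropout with doublets disabled
(a doublet merging a LOY and a normal cell is genuinely MSY-positive, so
truth labels are only meaningful for singlets). Single-run realism checks
(QC rejection fraction, doublet enrichment under the gene criterion) use the
full default panel.

Other numerical decisions: CLR zero-sum is asserted at 1e-9; Wilson score
intervals (without continuity correction) accompany LOY frequencies;
rank-deficiency resolution prefers earlier design columns; exact ties in
typing resolve alphabetically; `qr`-based rank checks guard every LRT
against silently testing an aliased term.

## Limitations

* The LOY call is binary and deterministic; a probabilistic caller modeling
  depth-dependent MSY detection would be a natural extension.
* The hurdle continuous part assumes Gaussian errors on positive
  log-normalized values and fits no shrinkage across genes.
* Protein typing cannot separate types the panel does not mark; `OTHER`
  absorbs them.
* Dataset-level numbers from any particular study (total cell counts,
  pooled z-statistics, adjusted p-values) depend on the real data and are
  not reproduced by synthetic runs; what the package reproduces are the
  transformations, the calibration properties, and the qualitative effect
  pattern.
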
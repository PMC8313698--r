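# loycite

Detection of mosaic loss of chromosome Y (LOY) in single leukocytes and
quantification of LOY-associated changes in CD99 mRNA and cell-surface
protein abundance from CITE-seq data.

## The problem

A fraction of the blood leukocytes of aging men lack the Y chromosome (LOY),
the most common somatic mutation in hematopoietic lineages and a marker of
disease risk. The `CD99` gene lies in pseudoautosomal region 1 of both X and
Y: a cell that loses Y keeps its X copy, so LOY should halve the gene dose
and reduce — not abolish — CD99. CITE-seq reads out, per droplet, both the
transcriptome (UMI counts) and a panel of surface proteins via
antibody-derived tags (ADT: here CD99 plus the lineage markers CD19, CD14,
CD16, CD56, CD8, CD4), making it possible to ask whether LOY cells carry
less CD99 mRNA *and* less CD99 surface protein than normal cells of the same
leukocyte type.

`loycite` implements the full inference chain:

1. **I/O** — 10x-dialect MatrixMarket triples for RNA and ADT, sample
   sheets, multi-sample pooling (`read_10x()`, `merge_samples()`).
2. **QC** — keep cells with ≤ 2000 expressed genes, ≥ 2500 UMIs and
   1.5–5% mitochondrial content (`compute_qc()`, `apply_qc()`).
3. **Normalization** — RNA `ln(1 + 10^4 · count/total)`; ADT per-cell
   centered log-ratio over the protein panel (`log_normalize()`,
   `clr_normalize()`).
4. **LOY calling** — a cell expressing autosomal genes but with zero raw
   counts over the male-specific region of chromosome Y (MSY) is LOY;
   pseudoautosomal genes (CD99!) are excluded from the MSY sum
   (`call_loy()`, `loy_frequencies()`).
5. **Typing** — each cell gets the type of its top CLR lineage marker,
   subject to a positivity and margin rule (`assign_types()`).
6. **Differential abundance** — per cell type: a confounder-adjusted
   logistic likelihood-ratio test for proteins and a two-part hurdle test
   (detection + positive values) for zero-inflated RNA, effect sizes as
   average natural-log fold changes with `percent = 100·(e^logFC − 1)`, one
   joint Benjamini–Hochberg family; plus a pooled logistic model across all
   cells (`run_differential()`, `pooled_overall_test()`).
7. **Synthetic data** — a seeded negative-binomial CITE-seq generator with
   per-type LOY fractions, injected CD99 effects, batch/depth/mitochondrial
   confounders, MSY dropout as an explicit knob, doublets and ground-truth
   labels (`simulate_citeseq()`, `write_fixture()`).

## Worked example

Simulate a default experiment (5,000 singlets, 4 donors, study-shaped LOY
fractions and CD99 effects) and run the whole chain:

```r
library(loycite)
sim <- simulate_citeseq(simulation_config(seed = 1))
res <- analyze_cells(sim$rna, sim$adt, sim$sheet)
#> LOY calls: 380 LOY, 3877 NORMAL, 0 UNDETERMINED (4257 cells)

freq <- res$frequencies
freq[order(-freq$pct_loy), ]
#>  cell_type n_cells n_loy pct_loy ci_lo ci_hi
#>         NK     423    93   21.99 18.30 26.17
#>  CD16_mono     248    45   18.15 13.85 23.42
#>  CD14_mono     580    81   13.97 11.38 17.02
#>      CD8_T     881    80    9.08  7.36 11.16
#>      OTHER     212    17    8.02  5.07 12.47
#>          B     487    34    6.98  5.04  9.60
#>      CD4_T    1426    30    2.10  1.48  2.99
```

4,257 of 5,050 droplets pass QC; per-type LOY frequencies track the
configured study values (20.9% NK … 2.4% CD4 T) within sampling noise. The
CD99 protein rows of the differential table:

```r
tab <- res$differential
tab[tab$analyte == "CD99" & tab$assay == "ADT", ]
#>  cell_type analyte assay avg_logfc pct_change   p_raw   p_adj n_loy n_normal
#>          B    CD99   ADT   -0.3092     -26.60 2.1e-08 5.0e-07    34      453
#>  CD14_mono    CD99   ADT   -0.0765      -7.37 4.4e-02 1.1e-01    81      499
#>  CD16_mono    CD99   ADT   -0.0082      -0.82 7.6e-01 9.2e-01    45      203
#>         NK    CD99   ADT   -0.0311      -3.06 4.5e-01 6.8e-01    93      330
#>      CD8_T    CD99   ADT   -0.1347     -12.60 3.5e-04 2.7e-03    80      801
#>      CD4_T    CD99   ADT   -0.1421     -13.25 1.9e-02 7.6e-02    30     1396
```

The B-cell row recovers the injected effect: avg_logfc −0.31, i.e. a 27%
reduction of surface CD99 on LOY B cells (`100·(1 − e^−0.31)`), strongly
BH-significant, while the six autosomal lineage-marker rows (not shown) stay
null. The pooled models across all cells give the overall picture:

```r
res$pooled
#>  analyte assay coefficient     z        p
#>     CD99   RNA      -0.385 -3.54 4.07e-04
#>     CD99   ADT      -0.966 -5.55 2.91e-08
```

— a significant overall CD99 reduction in LOY cells in both assays, with
donor, both batches, UMI count, mitochondrial percentage and cell type as
covariates. `make_figures(res)` reduces the run to the 0–1-scaled per-type
violin/box summary numbers; `run_pipeline()` is the same chain over on-disk
inputs, writing tidy TSVs and a JSON manifest.

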
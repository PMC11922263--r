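# tcrtrace

Paired single-cell transcriptome + TCR-repertoire analysis of
islet-infiltrating T cells, packaged as a tested, reusable R pipeline.

In autoimmune diabetes, T-cell clones that circulate in peripheral blood
can also be found inside pancreatic islets.  Because every T cell inherits
its clone's T-cell receptor, pairing scRNA-seq with scTCR-seq lets you
(1) partition T cells into compartments (CD4, CD8, double-negative DN,
double-positive DP, gamma-delta) by expression gating, (2) group cells
into clonotypes by their CDR3 amino-acid sequences, (3) call a blood cell
*infiltrating* when it shares an alpha or beta CDR3 with an islet cell,
(4) trace each clone's fate across maturation states, and (5) ask whether
infiltration status is predictable from expression alone.  `tcrtrace`
implements all of this for 10x-style inputs (Matrix Market count triplets
plus `filtered_contig_annotations.csv` contig tables), and ships a
synthetic cohort generator with planted ground truth so the entire chain
is verifiable without external data.

## The core definitions

* **Normalization** — `value = ln(1 + 10^4 · count / cell_total)` after
  cell/gene quality filters (CD3⁺, 200–5,000 detected features,
  mitochondrial ceiling, housekeeping detection; genes in ≥ 3 cells).
* **Embedding** — PCA of scaled expression with per-gene weights on
  immune markers (the 400 most variable genes join the feature set),
  kNN graph on PCs 1–10, Louvain clustering at resolution 1.5.
* **Gating** — per-marker threshold at the midpoint between the medians
  of the zero and positive populations (fallback 0.5); γδ first on
  *Trgv2*, then CD4/CD8 positivity gives CD4 / CD8 / DP / DN.
* **Clonotype** — the pair of sorted CDR3-aa sets
  (α-set, β-set); cells need ≥ 1 α and ≥ 1 β chain; multi-chain cells
  merge only on full set equality.
* **Infiltration (matching)** — cells in different tissues sharing any
  identical α **or** β CDR3 string; symmetric by construction.
* **Transitions** — per clone with > 3 cells, the likelihood of each
  unordered state pair among 100 uniformly drawn member-cell pairs,
  averaged over clones (with an exact enumeration oracle).
* **Classifier** — L1-logistic regression (`lambda = 1/(n·C)`),
  stratified 5-fold CV, ROC/AUC and precision-recall on held-out
  predictions, gene-batch curves, importance = mean |coefficient|.

## Worked example

```r
library(tcrtrace)

co <- generate_cohort(sim_config(seed = 1))   # 4 samples x 500 cells
qc <- filter_cells(co$counts)
qc$report
#> QC: 1866/2000 cells retained, 500/500 genes retained
#>   removed by cd3:         127
#>   removed by features:    0
#>   removed by mito:        7
#>   removed by housekeeping: 0

norm <- normalize_cp10k_log(qc$counts)
comp <- classify_compartment(norm)
table(comp$compartment)
#> CD4 CD8  DN  DP  GD
#> 487 526 703  76  74

ct <- assign_clonotypes(co$chains)
expansion_summary(ct, co$meta)
#>   n_clonotypes n_cells n_singletons n_ge3 n_gt10 max_size n_in_ge2_samples
#> 1          963    1730          690   117     14       59               50

mt <- match_tissues(ct, setNames(co$meta$tissue, co$meta$cell_id))
length(mt$matched_clonotypes)   # 50  (the planted cross-tissue clones)
sum(mt$cell_flags$infiltrating) # 147 cells flagged infiltrating
```

The gated DN fraction (703/1866 ≈ 0.38) tracks the planted 0.33 within
the tolerance the marker effect sizes allow; the 50 matching clonotypes
are exactly the clones planted in both tissues, verified against an
all-pairs brute-force chain comparison in the tests.

The same chain runs from the shell:

```sh
Rscript inst/cli/tcrtrace.R all --outdir out --seed 1
```

which writes per-stage TSVs (`qc/`, `embed/`, `gate/`, `clonotype/`,
`match/`, `transitions/`, `classify/`) and a `run_summary.json`; the run
is byte-reproducible for a fixed config and seed.

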
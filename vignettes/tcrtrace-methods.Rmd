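---
title: "Methods: paired transcriptome and TCR repertoire analysis with tcrtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired transcriptome and TCR repertoire analysis with tcrtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrtrace)
```

# The problem

In autoimmune (type 1) diabetes, T cells infiltrate the pancreatic islets
and destroy insulin-producing beta cells.  Because each T cell carries a
clonally inherited T-cell receptor (TCR), pairing single-cell RNA-seq with
single-cell TCR-seq makes it possible to ask which circulating clones are
the same clones found inside the islets ("infiltrating" or "matching"
clones), what transcriptional states those clones occupy, and whether
infiltration status can be predicted from expression alone.  `tcrtrace`
implements that analysis as a reusable pipeline: quality control,
normalization, marker-weighted embedding and clustering, expression gating
into T-cell compartments, CDR3-based clonotype assignment, blood–islet
clone matching, clone-fate and transition analysis, and an L1-logistic
infiltration classifier — together with a synthetic cohort generator that
plants ground truth so every stage can be validated quantitatively.

# The synthetic cohort generator

`generate_cohort()` emulates a pooled multi-library cohort: each sample
has a tissue (blood or islet) and a disease label (diabetic or
non-diabetic); each cell has a compartment (CD4, CD8, double-negative DN,
double-positive DP, or gamma-delta GD) and a maturation state (naive,
effector, memory, SLEC, pre-exhausted, exhausted).

**Count model.**  Counts are negative binomial (gamma–Poisson) with a
single global dispersion (`dispersion`, default 2) and independent dropout
(`dropout_rate`, default 0.05), which together produce the zero-inflated
marker counts that complicate real single-cell gating.  Background genes
share one mean (`baseline_mean`, default 1.5, chosen so a 500-gene cell
detects roughly 300 features and passes a 200-feature floor the way a
real cell with ~2,000 detected genes would).

**Marker model.**  Panel genes are modelled as on/off: a marker's mean is
`marker_base * 2^log2_fold` in its target compartment or state and
`off_factor * marker_base` elsewhere, with `off_factor = 0` by default.
Structural off-expression is the biological situation for lineage markers
— *Cd4* is not transcribed in CD8 cells — and it is what makes
threshold gating a well-posed problem.  A flat multiplicative bump over a
nonzero background was considered and rejected: on log-normalized data the
median-midpoint gate reduces to a detection gate (any positive count lands
above the midpoint threshold), so two populations that differ only
two-fold over a common background are not separable by any threshold and
the planted compartment fractions could not be recovered.  With the
on/off model, the fold effect still matters — it sets the expressed mean
and therefore the probability that an "on" cell drops to zero — so
recovery genuinely improves with effect size, which the tests assert.
Defaults (`marker_base = 6`, two-fold panel effects) were fixed once from
this design analysis.

**Clone model.**  Clone sizes follow a discrete power law
(P(s) ∝ s^-2.5, truncated at the per-sample cell count), reproducing the
long-tailed expansion profile in which most clonotypes are singletons and
few exceed ten cells.  A configurable number of clones
(`shared_clone_count`, default 50) is planted with at least one paired
cell in each tissue, inside a single disease group (clones do not cross
mice).  Every cell of a clone carries identical alpha and beta CDR3
amino-acid strings, drawn with canonical `C...F` framing and guaranteed
globally unique, so clone identity and CDR3 identity coincide exactly.
Cells failing `paired_chain_rate` receive a single alpha or beta chain
under a private singleton clone id, exercising the downstream exclusion
rule; GD cells receive gamma/delta chains only.

**What it does not model.**  Transcriptome-wide co-expression, batch and
library effects, doublets, ambient RNA, or any association between
infiltration status and expression: the planted clone structure is
independent of the count model, so the end-to-end classifier AUC on
synthetic cohorts is ~0.5 by construction.  Passing tests therefore
demonstrate correctness of the machinery, not that real infiltrating cells
are predictable; conversely the planted-signal simulations show the
classifier recovers informative genes when a signal exists.

# Quality control and normalization

Cells must pass, in order: CD3 positivity (`Cd3e > 0` counts by default —
the positivity gene is configurable since some datasets may favour other
CD3 chains), a detected-feature window (200–5,000), a mitochondrial
fraction ceiling, and detection of at least one housekeeping gene
(*Actb*, *B2m*, *Gapdh* by default).  Attrition is attributed to the first
failing filter so the per-filter counts sum to the total removed.  Genes
detected in fewer than 3 retained cells are then dropped.  The
mitochondrial ceiling defaults to 0.10, a common murine choice; it is a
parameter, not a claim.  Normalization is counts-per-10,000 with `log1p`
(`value = ln(1 + 1e4 * count / cell_total)`), preserving sparsity; scaling
centers each gene to mean 0, variance 1 (denominator n−1), clips at ±10,
and maps constant genes to zero.

# Embedding and clustering

The feature set is the union of the immune-marker panel and the 400 most
variable genes (ties broken by gene order, so selection is deterministic).
Weighted PCA multiplies each scaled feature row by its weight before the
SVD; unit weights reduce exactly to ordinary PCA, and a weight of zero
excludes a gene.  Component signs are fixed by making the
largest-magnitude loading positive, so scores are reproducible rather than
sign-ambiguous.

Only lineage-discriminating markers (*Cd4*, *Cd8a*, *Cd8b1*, *Trgv2*, and
the state markers that switch between maturation states) are up-weighted
(default weight 5).  Up-weighting markers expressed uniformly across the
populations of interest — *Cd3e* or housekeeping genes — would amplify
their sampling noise by the same factor as any signal and degrade
separation; this is why the default weight set is narrower than the full
gating panel.

Cells are connected to their 20 Euclidean nearest neighbors in the top 10
PCs (ties broken by cell index; the directed relation is symmetrized by
union) and clustered by Louvain modularity at resolution 1.5.  Labels are
0-based consecutive integers ordered by decreasing cluster size.
Community detection is delegated to `igraph::cluster_louvain()`; the
contract the pipeline relies on — modularity objective, resolution, seed
determinism, size-ordered labels — is asserted by tests.  A 2-D UMAP
would carry no analytical weight in this pipeline and is not computed;
all downstream logic consumes PCs, clusters and gates.

# Expression gating

For each marker the threshold is the midpoint between the median of the
zero-expression population and the median of the positive population,
falling back to a fixed 0.5 when positives are fewer than 1% of cells (or
in `fixed` mode, 0.5 always).  Compartments are called in a fixed order:
gamma-delta first (*Trgv2* above threshold, exclusive), then CD4/CD8
positivity partitions the rest into CD4, CD8, DP and DN.  CD8 positivity
is an OR over *Cd8a*/*Cd8b1* by default — the permissive reading given the
strong co-expression of the two chains — with AND available.

Th-like subsets are called only on cells lacking CD8 expression, by
marker combinations (Treg: *Foxp3*+*Il10*; Th17: *Il17a*; Th22:
*Il22*+*Tnf*; Th1: *Ifng*+*Tnf*; Tfh: *Il4*+*Il10*; Th2: *Il4* without
*Il10*; Th9: *Il10* without *Ifng*/*Tnf*).  The combinations are not
mutually exclusive, so a fixed precedence (Treg, Th17, Th22, Th1, Tfh,
Th2, Th9) resolves multi-rule cells deterministically; cells matching no
rule are `NA`.  SLEC-like cells are *Klrg1*+ *Gzma*+ *Il7r*−; exhaustion
is called when at least 2 of 5 inhibitory receptors (*Pdcd1*, *Tigit*,
*Ctla4*, *Havcr2*, *Lag3*) are above threshold — a configurable
operationalization of what is usually a hand annotation.

# Clonotypes, matching, transitions

Only cells with at least one productive alpha and one beta chain enter the
clonal analysis.  The clonotype key is the pair of sorted CDR3 amino-acid
sets (alpha set, beta set); cells with multiple chains per locus merge
only on full set equality.  Matching between tissues is deliberately
looser than clonotype identity: two cells match if they share *any* single
alpha or beta CDR3 string, and a blood cell is islet-matching
(infiltrating) iff it matches at least one islet cell, symmetrically.
V/J-gene agreement is not required, matching the chain-sequence definition
of infiltration; epitope annotation against a VDJdb-style table uses
exact, uppercase-canonicalized, chain-aware string equality.

Clone fate: a clone with members in SLEC-like states and none in exhausted
states is `SLEC_only`, the converse `Texh_only`, both `mixed`, neither
`other`.  In the pipeline the transition-graph nodes are expression
clusters, and the SLEC/exhausted state sets are auto-annotated by majority
vote of the per-cell gate flags within each cluster — replacing manual
cluster annotation with a reproducible rule.

Transition likelihoods are estimated per clone with more than 3 cells by
drawing 100 unordered pairs of distinct member cells (uniform over the
C(n,2) pairs; with replacement across draws) and recording the fraction of
draws showing each unordered state pair; edge weights average these
per-clone likelihoods over eligible clones.  `exact_transitions()`
computes the same quantity by full enumeration and serves as the oracle
the bootstrap must match in expectation — per-clone likelihoods sum to 1,
and the estimator is unbiased.

# The infiltration classifier

An L1-penalized logistic regression predicts the per-cell infiltration
flag from log-normalized expression within a configurable subset (default:
gated CD8 cells in blood).  `reg_strength` behaves like the inverse
regularization C of liblinear-style solvers; the fitted penalty is
`lambda = 1/(n_train * reg_strength)` and "lasso" refers to the L1 penalty
name.  Evaluation is stratified five-fold cross-validation with all
curves computed on held-out predictions only.  Because the overall AUC of
a cross-validated model can be pooled or averaged, both conventions are
reported (`auc`, `auc_mean_fold`), and precision-recall/average-precision
is reported alongside ROC because infiltrating cells are a minority class.
Gene batches (contiguous chunks of the variance-ranked gene list, default
100 genes) yield one discrimination curve per batch; feature importance is
the mean absolute coefficient across folds normalized to the top gene.

# Numerical choices and problem sizes

Deterministic tie-breaks appear wherever order matters: variable-gene ties
by gene order, kNN distance ties by cell index, cluster labels by size
then community id, importance ties by gene name.  All randomness flows
from explicit seeds (generator, Louvain, fold assignment, bootstrap), and
the full CLI chain is byte-reproducible for a fixed configuration and
seed.  The test and validation cohorts use 800–2,000 cells and 500 genes
with 50 planted shared clones — sizes at which the brute-force all-pairs
matching oracle and enumeration oracles are exact and fast while the
statistical checks (fraction recovery within binomial error, ARI ≥ 0.8 on
well-separated compartments, unbiased bootstrap, ≥15/20 planted genes
recovered) retain power.

# Limitations

Real cohorts deposit no per-state ground truth, so generator defaults are
chosen for testability, not fidelity to any particular animal.  The
pipeline replaces model-based library integration with the simpler stated
log-normalization and carries the sample label as a covariate option; it
does not attempt pseudotime, module detection, enrichment analysis, or
fuzzy CDR3 matching.
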
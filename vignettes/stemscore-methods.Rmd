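---
title: "Methods: chromatin stemness scoring for glioma scATAC-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin stemness scoring for glioma scATAC-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Glioblastoma tumors harbor a minority population of stem-like cells that
drives recurrence and therapy resistance. Existing stemness indices
(mRNAsi, mDNAsi, entropy-based scores) quantify stemness from
transcriptomes or methylomes; `stemscore` instead scores stemness from
chromatin accessibility alone, so that glioma single-cell ATAC-seq
experiments can be interrogated for stem-like cells without matched
scRNA-seq.

The score for cell $c$ is a weighted sum over a panel of marker genes
$G$:

$$\mathrm{ATACss}(c) = \sum_{i \in G} w_i \, x_{ic}, \qquad
\mathrm{ATACss}^*(c) =
\frac{\mathrm{ATACss}(c) - \min_c \mathrm{ATACss}}
     {\max_c \mathrm{ATACss} - \min_c \mathrm{ATACss}},$$

where $x_{ic}$ is the log-transformed, filtered accessibility of gene
$i$ in cell $c$ and $w_i$ combines two per-gene quantities: the gene's
importance in classifying neural stem/progenitor cell states, and the
strength of the functional association between the gene and its
regulatory elements. Cells with $\mathrm{ATACss}^* > 0.5$ are called
high-stemness.

## Pipeline stages and their assumptions

### 1. Consensus marker-gene selection (`run_consensus`, `combine_models`)

Marker genes are learned from a labeled scRNA-seq reference (neural
lineage states: qNSC, aNSC, NPC, astrocytes) with three tree-ensemble
multiclass classifiers:

| learner | engine | preset |
|---|---|---|
| `rf` | randomForest | 500 trees, $\lfloor\sqrt{p}\rfloor$ features per split |
| `gb` | xgboost | 2500 trees, learning rate 0.001, depth 5, min 5 obs/leaf |
| `xgb` | xgboost | 2500 rounds, depth 15, learning rate 0.01, 50% column subsample |

Each learner is run `reps = 100` times. Every repetition draws a fresh
stratified 70/30 split (class proportions preserved; per-class training
count `round(0.7 * class size)`), fits on the training cells, and
records the `top_k = 100` genes by the learner's native impurity/gain
importance. A gene is *selected* by a learner if it appears in at least
`min_votes = 50` of the repetitions; the final consensus panel is the
intersection of the learners' selected sets (union available when the
intersection is empty). Held-out accuracy is recorded per repetition
but plays no role in selection — selection is purely vote-based.

Design notes:

* The per-repetition list length is not derivable from first
  principles; 100 (one fifth of the default gene panel) is the
  default, exposed as a flag.
* "Importance" is the learners' native impurity/gain importance (the
  engines' default), not permutation importance.
* For the `xgb` preset the learning rate (`eta`) is 0.01, exposed as
  an override like every other preset entry.
* Gradient boosting runs on the xgboost engine with the classical GBM
  hyperparameters (depth 5, minimum terminal-node size 5, learning rate
  0.001, 2500 trees); row subsampling is left at 1 so fits are
  deterministic given the seed.
* Repetition $r$ seeds both its split and its learner with
  `seed + r`, so any repetition can be replayed in isolation.
* Per-learner importances live on different scales (Gini impurity vs
  normalized gain); before combining, each learner's mean importance is
  min-max rescaled to $[0,1]$ over its gene table, and a consensus
  gene's combined importance is the mean of the rescaled values
  (`--importance-from` selects a single learner instead).

### 2. Region-to-peak mapping and aggregation (`map_regions_to_peaks`, `aggregate_gene_counts`)

Promoter and enhancer regions of the panel genes (an annotation-table
input with per-element gene-association scores, GeneHancer-style) are
linked to ATAC peaks by a strand-agnostic midpoint test: region $r$
maps to peak $p$ iff they share a chromosome and
$p_{\mathrm{start}} \le \lfloor (r_{\mathrm{start}} +
r_{\mathrm{end}})/2 \rfloor < p_{\mathrm{end}}$ (all coordinates
0-based half-open; 1-based inclusive inputs are converted on read via a
required convention flag rather than guessed). All peaks containing the
midpoint are recorded when peaks overlap. Overlap search uses
`GenomicRanges::findOverlaps()`; its output is checked against a
brute-force all-pairs scan in the test suite.

Gene-level accessibility is the per-cell sum of counts over the
distinct peaks mapped to the gene. A peak reachable through two regions
of the same gene is counted once — double-counting the same reads
through both a promoter and an enhancer hit would weight genes by their
annotation redundancy rather than their accessibility.

The per-gene association power is the mean association score over the
gene's mapped (region, peak) records.

### 3. Filtering and transform (`zscore_filter`, `log_transform`)

Within each gene row, cells are standardized across the sample (mean
$\mu$, sd $\sigma$ with denominator $n-1$) and entries with
$z < -1$ (i.e. below $\mu - \sigma$) are zeroed, so lowly accessible
cells contribute exactly zero to the score. Standardization is
per-gene-across-cells because the filter's purpose is to silence low
accessibility *of a gene*; a per-cell-across-genes variant exists
behind `filter_axis = "cell"` but is not the default. Constant rows
($\sigma = 0$) pass through unchanged; a cutoff of $-\infty$ disables
the filter. Counts are then transformed as $\log_2(x + 1)$. Filtering
precedes the log transform. No per-cell sequencing-depth normalization
is applied anywhere — a deliberate simplification and a known
limitation (deeply sequenced cells score systematically higher; users
comparing across samples should normalize externally or rely on the
per-sample min-max rescaling).

### 4. Weights and the score (`compute_weights`, `raw_scores`)

Each factor (combined importance; association power) is reduced to one
number per gene, and the gene weight is their product after a
normalization that makes the two scales commensurable. Two
normalizations are implemented:

* `scale`: z-standardization of both factors (the `scale()`
  convention). This is the classical formulation, and it is the default
  of `compute_weights()`. Its drawback is structural: centered factors
  are negative for below-average genes, and the expected *sum* of the
  products equals $(n-1)\,\mathrm{cor}(\text{importance},
  \text{association})$ — when the two factors are uncorrelated, the
  total weight mass, and with it the *direction* of the score, has an
  arbitrary sign. On synthetic panels with independent factors the
  score direction flips from seed to seed.
* `minmax`: both factors rescaled to $[0,1]$. Order within each factor
  is preserved, all weights are non-negative, and more-important,
  more-strongly-associated genes always push the score up.

Because a stemness score must have a defined direction, the *pipeline*
(`run_all`, the `score` subcommand) defaults to `minmax`, while
`compute_weights()` retains `scale` as its default for users who want
the classical behaviour; the pipeline logs the count of negative final
weights whenever `scale` is chosen. Genes selected by consensus but
lacking mapped peaks are dropped from $G$ with a warning (both weight
factors are undefined without peaks); standardization is computed over
the scored gene set only.

Min-max normalization maps raw scores to $[0,1]$ per sample (so scores
are comparable within, not across, samples); a degenerate all-equal
score vector maps to all zeros with a warning. Classification at the
0.5 cutoff is strict: exactly 0.5 is "low", so "high" always means
*strictly* elevated.

### 5. Cellular-state labeling (`label_neftel_states`)

For each of the six glioblastoma cellular states (NPC-like 1/2,
OPC-like, AC-like, MES-like 1/2), the promoter regions of the state's
signature genes are mapped and aggregated exactly as above (no z-score
filter here — labeling uses plain logged accessibility), cells are
clustered hierarchically (Ward linkage on Euclidean distances, the
standard heatmap convention; both configurable) and the cluster with
the highest mean accessibility is flagged as the state's cells, ties
to the smaller cluster id. `k` is a required user parameter — in
practice it is chosen per sample by inspecting heatmaps (3–5 is
typical), and `suggest_k()` offers a silhouette-based starting point
without ever choosing silently. A cell flagged by several states takes
the state with the larger per-cell mean signature accessibility;
whether enhancers should join the promoters in signature mapping is
ambiguous in the source protocol, so promoters-only is the default
with `elements = c("promoter", "enhancer")` available.

### 6. GSC functional states (`assign_gsc_state`)

Glioma stem-cell functional states (constructive / reactive /
invasive, defined by bulk-ATAC discriminating regions; invasive carries
the worst prognosis) are assigned only to cells at or above the 0.5
stemness cutoff. No canonical rule exists for turning region-level
state definitions into per-cell calls; the package's rule is: a
peak belongs to a state if the peak's midpoint falls in any of the
state's regions; the per-state signal of a cell is the summed counts
over those peaks divided by the state's region count (so states with
many regions are not favored); the cell takes the argmax state, and
exact ties leave it unassigned. `signal = "total_sum"` and
`"per_base_mean"` (length-normalized) are the flag-selectable
alternatives.

## The synthetic-data generator

Every stage is testable without external data through
`simulation_spec()` and its generators. The generator emulates:

* a labeled scRNA-seq matrix (negative-binomial counts, default
  dispersion 2, baseline mean 5) of 4 states × 100 cells and 500
  genes, in which 20 informative genes have their mean multiplied by
  `fold_effect = 8` in exactly one state;
* a promoter/enhancer annotation (1 promoter + 0–3 enhancers per gene;
  gamma(2, scale 5) association scores, emulating the right skew of
  database association scores);
* a scATAC bundle (default 5000 peaks × 1000 cells, baseline mean 0.5,
  the sparse-count regime of real scATAC data) in which one peak is
  built around every gene region's midpoint, the remaining peaks are
  decoys containing no midpoint, and a planted 20% of cells ("stem")
  carry the fold-8 shift at informative-gene peaks — operationalizing
  the premise that stemness manifests as accessibility at
  state-predictive genes;
* signature lists (MES-like 2 = the informative genes) and GSC regions
  (constructive = informative-gene peaks, reactive/invasive = decoys).

Baseline means are deliberately *shared* across genes and peaks: with
homogeneous baselines, noise genes are exchangeable, so a label
permutation measures pure chance selection. (Tree-ensemble impurity
importances are biased toward high-variance features; with
heterogeneous baselines a label-free control would re-select the same
high-mean genes run after run and no longer be a null.) The cost is
realism: real data have heavy-tailed mean-variance structure, depth
variation, batch effects, doublets and fragment-length artifacts, none
of which are emulated.

On null controls for the voting protocol, one subtlety matters:
shuffling the labels *once* and running the ordinary protocol is not a
null for the *vote counts*. Each gene then retains a fixed chance
association with the fixed permuted labels, and because repetitions
share most of their training cells, they keep voting for the same
chance genes — on the default simulation roughly a tenth of all genes
still clears the 50%-vote threshold. The proper null re-shuffles the
labels inside every repetition
(`run_consensus(..., permute_labels = TRUE)`), making votes
independent across repetitions; the expected selection fraction at
`min_votes = n_reps / 2` is then essentially zero, and that is the
control the test suite asserts at the 2% bound. Passing recovery tests therefore demonstrates
the pipeline's internal correctness and its behaviour under its own
assumptions — not performance on real tumors.

## Numerical choices

* Coordinates: internal 0-based half-open everywhere; midpoint is
  floor((start+end)/2); containment is `start <= m < end`.
* sd uses denominator $n-1$ throughout (the `scale()` convention).
* Ranking ties in importance break by gene id in C-locale order;
  cluster-mean ties flag the smaller cluster id; GSC signal ties leave
  the cell unassigned.
* Degenerate inputs: constant gene rows pass the z-filter unchanged;
  constant raw-score vectors normalize to all zeros with a warning;
  zero-variance weight factors are a hard error (standardization
  undefined); an empty consensus is a warning at combination time and
  an error at scoring time.
* All learner fits are single-threaded; results are independent of
  machine parallelism. Each pipeline stage derives its seed from the
  single top-level seed (`seed * 101 + offset`, folded into 32-bit
  range), recorded in the run manifest.

## Problem sizes used in the test suite

The packaged tests run the full protocol at reduced repetition counts
so the suite completes on a laptop: consensus recovery uses 20
repetitions with a 10-vote threshold (the 100/50 defaults scale both
numbers together; the vote fraction, not the absolute count, carries
the signal), and the end-to-end score check reuses one reduced
selection run across ten independently simulated scATAC datasets of
1000 cells each. Oracle-equivalence checks (mapping, aggregation,
scoring, GSC assignment) run on hundreds of small random instances
against brute-force reimplementations.

## Known limitations

* No depth normalization (see above); no TF-IDF or other scATAC
  normalizations — scores are comparable within one sample.
* The consensus protocol's learners are fixed to the three named
  ensembles; no tuning is performed.
* State labeling assigns whole clusters, so its resolution is bounded
  by the clustering; `k` is a user decision.
* Real-data accession-based results require the original deposits;
  nothing in this package downloads data.
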
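---
title: "Dynamic multilayer modularity of brain functional networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic multilayer modularity of brain functional networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynmodnet)
```

## The problem

Resting-state fMRI gives, per subject, one BOLD time series per brain
region (node). Static functional connectivity summarizes a whole scan in
a single correlation matrix and discards how the network's modular
organization reorganizes over minutes. `dynmodnet` studies that
reorganization: it slices the scan into overlapping windows, treats the
ordered windowed connectivity matrices as the layers of a temporal
multilayer network, finds time-resolved modules, and quantifies how
loyally node pairs stay together (connection stability) and how
individual nodes change module membership — together with others
(cohesive switching) or alone (disjoint switching). The motivating
application is cirrhosis: separating patients with minimal hepatic
encephalopathy (MHE) from cirrhotic patients without encephalopathy
(noHE), where elevated solo switching of higher-cognitive-network nodes
is the candidate biomarker.

## Pipeline and model

### Sliding-window connectivity

For a node × volume series, windows of `length` volumes advance by
`step` volumes; trailing volumes that cannot fill a window are dropped,
so a 190-volume series with a 45-TR window at step 1 yields
`floor((190 - 45)/1) + 1 = 146` layers. Within each window, pairwise
Pearson correlations are Fisher z-transformed, with |r| clipped at
`1 - 1e-7` first: synthetic and duplicated signals do reach r = 1, and
atanh must stay finite. A node that is constant inside a window is a
hard error, not a silent NA — it signals degenerate input. Windows are
rectangular (no tapering).

### Multilayer modularity

With intra-layer weights $A_{ijs}$ (layer $s$), strengths
$k_{is} = \sum_j A_{ijs}$, per-layer totals $2m_s$, resolution
$\gamma$ and inter-layer coupling $\omega$, the quality of an
assignment $M_{is}$ of node copies to modules is

$$Q(\gamma,\omega) = \frac{1}{2\mu} \sum_{ijsr}
  \left[\left(A_{ijs} - \gamma \frac{k_{is}k_{js}}{2m_s}\right)\delta(s,r)
  + \delta(i,j)\,\omega\,[\,|s-r|=1\,]\right] \delta(M_{is}, M_{jr}),$$

with $2\mu = \sum_s 2m_s + 2\omega N (T-1)$. Three conventions needed
fixing where the temporal-modularity literature leaves room:

* **Coupling topology.** $\omega$ is *ordinal*: it rewards a node for
  keeping its module between adjacent layers only. All-pairs coupling
  would make $Q$ grow quadratically in the layer count and is not what
  the standard generalized-Louvain toolboxes implement.
* **Negative weights.** Negative Fisher-z entries are zeroed before
  optimization; the Newman–Girvan null is ill-behaved on signed
  matrices, and zeroing is the dominant practice for this family of
  analyses.
* **Normalization.** $2\mu$ includes the coupling weight, matching the
  common toolbox convention, so $q$ values are comparable across
  $\omega$.

Optimization is a generalized Louvain heuristic over the dense
supra-modularity matrix (intra-layer blocks plus $\omega$ on same-node
adjacent-layer entries), written in C++: greedy sweeps in a seeded
random order move each node-layer copy to the neighbouring module with
the largest positive gain (> 1e-10; ties keep the current module,
otherwise take the lowest module id), then modules are contracted and
the procedure recurses. Randomness comes from a self-contained
splitmix64 generator, so a seed reproduces the same partition on any
platform. The dense representation caps practical problem size at a few
thousand node-layer copies; larger runs should increase the window step
(the 264-node atlas at 146 step-1 layers exceeds the cap by design —
network-level questions at that scale are better asked with
non-overlapping windows).

Because the heuristic returns local optima, every subject is
re-optimized `n_runs` times (100 in the motivating analysis; 20 in this
package's bundled experiments, which profiling showed is where ensemble
averages of the metrics stabilize at the 40-node scale) and all metrics
are ensemble averages. On 200 random multilayer graphs small enough for
exhaustive search (≤ 8 node-layer copies), the ensemble optimum matched
the true maximum of $Q$ on 100% of instances (the test suite requires
≥ 95%).

### Reconfiguration metrics

From each run's labels (nodes × layers):

* **Connection stability** (allegiance): fraction of layers in which a
  node pair shares a module; diagonal fixed at 1.
* **Flexibility**: fraction of the $T-1$ transitions at which a node
  changes module.
* **Disjoint vs cohesive switches**: a switch is cohesive when at least
  one other node makes the same source→destination move at the same
  transition, disjoint otherwise. Partners leaving the same source for
  *different* destinations do not make a move cohesive — the rule
  requires matching source *and* destination. **Disjointness** is the
  disjoint-switch count over $T-1$; **cohesion strength** sums the
  number of partners per cohesive move, again over $T-1$, making it
  commensurate with flexibility (raw counts are also kept). Per run and
  node, `flexibility * (T-1) = disjoint + cohesive counts` — an identity
  the tests assert on every fixture.

Module ids are arbitrary per run; no cross-run label alignment is
attempted because every metric is relabeling-invariant. Network-level
values average member nodes (nodal metrics) or within-network pairs
(stability); a single-node network has no within pairs and yields a
logged missing value.

### Group analysis

MHE labeling follows the psychometric-norm convention: NCT-A and DST
are regressed on age and education in healthy controls, and a patient
is labeled MHE when either test deviates from its prediction by more
than 2 residual SDs *in the impaired direction* (NCT-A above, DST
below). The one-sidedness is deliberate: performing unusually well is
not encephalopathy.

Group differences use the Kruskal–Wallis omnibus test per unit
(network or node) with Benjamini–Hochberg FDR across the units of one
family, and pairwise two-sided Mann–Whitney post hocs gated on the
omnibus p < 0.05. Correlations with cognitive scores are partial
correlations — Pearson on OLS residuals against age, sex, education and
mean framewise displacement (the scalar motion summary; the 6-regressor
alternative adds little at these n), with p from the t transform on
$n - c - 2$ degrees of freedom.

Motion QC uses the 50-mm-sphere framewise displacement convention (the
0.2 mm exclusion threshold in common use presumes it); thresholds are
strict inequalities, so a subject at exactly 0.2 mm is kept.

### Discrimination

Node disjointness feeds an SVM separating MHE from noHE under
leave-one-out cross-validation. Each fold ranks features by the
two-class F-score

$$F(i) = \frac{(\bar x_i^{(+)}-\bar x_i)^2 + (\bar x_i^{(-)}-\bar x_i)^2}
  {\frac{1}{n_+-1}\sum_k (x^{(+)}_{k,i}-\bar x^{(+)}_i)^2 +
   \frac{1}{n_--1}\sum_k (x^{(-)}_{k,i}-\bar x^{(-)}_i)^2}$$

*on the training fold only*, takes the top k, z-scores them with
training-fold statistics, and fits an RBF-kernel SVM (C = 1, kernel
width 1/k — the usual library default; the data give no basis for
tuning, and a linear kernel is available for comparison). A leakage
test asserts that corrupting the held-out subject never changes that
fold's selection. Consensus features are the k most frequently selected
across folds. ROC/AUC comes from a threshold sweep of the per-fold
decision scores (trapezoid area; equal to the Mann–Whitney pair-count
with ties at half, which the tests verify against an independent
implementation). Significance uses label permutations with the full
per-fold selection rerun each time and the add-one estimator
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(n_{perm}+1)$, which never
returns 0. The feature count k can be fixed (23 in the motivating
analysis) or chosen by `select_k()` from the cross-validated accuracy
grid.

## The synthetic cohort generator

No patient fMRI is distributable, so the generator plants known
structure and every downstream claim is tested against that ground
truth. Per epoch, each module has one latent unit-variance Gaussian
driver per volume and node signals are

$$x = \sqrt{r_b}\,g + \sqrt{r_w - r_b}\,d_{module} + \sqrt{1-r_w}\,\varepsilon,$$

giving within-module correlation $r_w$ (default 0.6 — the upper range
of windowed cortical correlations) and between-module $r_b$ (0.1).
Membership follows a switch schedule; the ground-truth classification
of each planted change uses the same source-and-destination rule as the
estimator, so colliding events are counted consistently. Epoch
boundaries align with window strides (default: 12 epochs of 20 volumes,
20-TR non-overlapping windows) so planted changes are recoverable in
principle; this alignment is a fixture convention, not a claim about
real data.

Cohort defaults mirror the motivating study's composition: 41 healthy
controls, 32 noHE, 30 MHE, with group-wise age (≈ 48–51 ± 7 y),
education (≈ 12–13 ± 3 y) and sex ratios drawn to match its
demographics table. Baseline dynamics give every node a 0.04
per-boundary probability of a solo switch and each boundary a 0.5
probability of one 2–4-node cohesive event. The MHE-like group adds
0.25 solo-switch probability on 10 designated nodes spread over the
DMN/FPN/VAN-like networks — a strong, focal effect chosen to emulate a
clinically separable patient group (the motivating analysis reports
~89% discriminability). Cognitive scores are linear in age, education
and the planted disjointness rate $d$ over the designated networks
(DST $= 62 - 0.45\,\text{age} + 0.9\,\text{edu} - 120 d + \epsilon_6$;
NCT-A $= 25 + 0.35\,\text{age} - 0.5\,\text{edu} + 160 d + \epsilon_5$),
signs matching the observed direction (disjointness hurts attention and
visual memory) and intercepts placing healthy controls near the
published norms. Head motion is a slow random walk well inside the QC
thresholds.

What the generator does *not* emulate: hemodynamic autocorrelation and
low-pass structure, scanner noise spectra, motion artefacts coupled to
the signal, inter-subject anatomical variability, and graded (rather
than planted) module structure. Passing the recovery tests therefore
shows the estimator chain is correct and well-calibrated on its own
model, not that real MHE cohorts will separate at the same accuracy.

## Numerical choices

* Fisher-z clip at `1 - 1e-7`; move-acceptance tolerance 1e-10; Louvain
  move phase errors out after 100 sweeps (pathological input).
* Child seeds fan out from the master seed via a fixed counter scheme
  (`derive_seeds`), so subject-level parallelism cannot change results;
  all derived seeds stay below 2^31.
* Kruskal–Wallis uses the tie-corrected H; an all-tied unit takes the
  H = 0, p = 1 path and is never post-hoc tested.
* Zero-variance features in a training fold z-score to 0 (SD clamped to
  1); an infinite F-score (zero within-class variance, unequal means)
  ranks first and warns.
* Partial correlations with constant residuals report missing rather
  than NaN.

## Bundled experiment sizes

The package's tests and the acceptance script run: the 103-subject
default cohort at 40 nodes, 12 non-overlapping 20-TR windows, 20
optimization runs per subject and a 200-permutation null; a 200-instance
exhaustive-search comparison on ≤ 8 node-layer copies; and six 45-subject
null cohorts (240 node-level omnibus tests) for calibration. At these
sizes the full suite completes in minutes on one core. Observed outcomes
at seed 1: node-disjointness profile recovery Spearman ≈ 0.86,
designated-node enrichment p ≈ 1e-9, LOOCV accuracy ≈ 94% against a
permutation-null 95th percentile of ≈ 65%, and a 3.3% null
false-positive rate at the 5% level.

## Known limitations

Dense supra-matrix optimization bounds the node × layer product;
consensus partitions across runs are deliberately out of scope (metrics
are relabeling-invariant ensemble averages); signed modularity, tapered
windows and connectivity-state clustering are not implemented; and the
generator's planted effects are step changes, so it cannot probe
sensitivity to gradual reconfiguration.
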
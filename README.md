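# dynmodnet

Dynamic multilayer modularity analysis of brain functional networks, in
R.

## What it is for

Resting-state fMRI yields one BOLD time series per brain region. Beyond
the static correlation matrix, the *modular organization* of the brain
graph reorganizes on the timescale of a scan, and how individual nodes
change module membership carries clinical information. `dynmodnet`
implements that analysis end to end for researchers studying network
reconfiguration in patient cohorts — the motivating case is separating
cirrhotic patients with minimal hepatic encephalopathy (MHE) from
cirrhotic patients without it (noHE), where elevated *solo* module
switching (disjointness) of default-mode, fronto-parietal and
ventral-attention nodes is the candidate biomarker.

The pipeline:

1. **Sliding-window connectivity** — per window, pairwise Pearson
   correlation with the Fisher z-transform; the ordered windows are the
   layers of a temporal multilayer network.
2. **Multilayer modularity** — generalized Louvain optimization of

   Q(γ,ω) = 1/2μ · Σ<sub>ijsr</sub> [ (A<sub>ijs</sub> −
   γ·k<sub>is</sub>k<sub>js</sub>/2m<sub>s</sub>)·δ(s,r) +
   δ(i,j)·ω·[|s−r|=1] ] · δ(M<sub>is</sub>, M<sub>jr</sub>)

   with ordinal inter-layer coupling ω, run as a seeded ensemble of
   restarts (C++ core).
3. **Reconfiguration metrics** — connection stability (module
   allegiance), flexibility, and the split of each module switch into
   *cohesive* (shared source→destination move with a partner) vs
   *disjoint* (alone), ensemble-averaged, at node and network level.
4. **Group statistics** — 2-SD residual-norm MHE labeling from NCT-A /
   DST scores, Kruskal–Wallis + Benjamini–Hochberg FDR group
   comparisons, covariate-adjusted partial correlations with cognitive
   scores, and motion-based (framewise displacement) subject exclusion.
5. **Discrimination** — F-score feature ranking inside each
   leave-one-out fold, RBF-kernel SVM, ROC/AUC, and label-permutation
   significance.
6. **Synthetic cohorts** — a generator that plants time-varying modular
   structure with known per-node switch counts and group-linked
   cognitive scores, so every stage is testable against ground truth.

## Worked example

```r
library(dynmodnet)

cfg <- run_config(seed = 7, n_runs = 10, n_perm = 99, k = 5,
                  synthetic = list(n_per_group = c(HC = 10, noHE = 12,
                                                   MHE = 12)))
res <- run_pipeline(cfg, verbose = TRUE)
cat(pipeline_report(res), sep = "\n")
```

```
inputs: generated 34 synthetic subjects
metrics: 34 subjects x 10 runs
group stats: 5 families
classification: accuracy 95.83%, permutation p 0.01
# Pipeline summary

Subjects: 34 (HC=10, MHE=12, noHE=12); excluded by QC: 0
Window 20 TR step 20 TR; gamma 1.00 omega 1.00; 10 runs

FDR-significant node-disjointness units (p_fdr < 0.05): node2, node3, node4, node11, node13, node20

## MHE vs noHE discrimination

accuracy 95.83%, sensitivity 100.00%, specificity 91.67%, AUC 0.993, permutation p 0.01
```

The generator planted extra solo-switching on ten designated
higher-cognitive nodes in the MHE group; the FDR-significant nodes above
are drawn from that set, and the classifier separates the patient groups
well above the permutation chance level (p = 0.01 with 99 shuffles is
the smallest value the add-one estimator can return). Network-level
disjointness shows the same picture:

```r
head(res$group_tests$network_disjointness[, 1:6])
```

```
  unit         H           p       p_fdr  median_HC median_MHE
1  DMN 12.414694 0.002014575 0.007008988 0.02454545 0.05045455
2  FPN  6.815011 0.033123729 0.042675908 0.03693182 0.04318182
3  VAN 11.753705 0.002803595 0.007008988 0.02727273 0.07575758
4  VIS  6.539553 0.038014922 0.042675908 0.03750000 0.02613636
5  SSM  6.308241 0.042675908 0.042675908 0.02045455 0.02556818
```

The MHE-like group's median disjointness is elevated in the DMN-, FPN-
and VAN-like networks where the effect was planted.

Real data enter through the same door: a tab-separated subject manifest
plus node × volume series files (`load_subjects`), an atlas table
(`load_atlas`; the bundled 264-node, 14-network functional atlas is
`power264_atlas()`), and optional SPM-style realignment parameter files
for QC (`qc_cohort`). A thin command-line wrapper lives at
`inst/cli/pipeline.R` (`synth`, `run`, `grid`, `report` subcommands).

## Documentation

The methods vignette
(`vignettes/dynamic-modular-networks.Rmd`) documents the model, the
conventions adopted where the temporal-modularity literature leaves
choices open (ordinal coupling, negative-weight zeroing, the μ
normalization, the cohesion rule), the synthetic generator's design and
its limits, and all numerical tolerances.
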
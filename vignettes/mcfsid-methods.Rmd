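---
title: "Monte Carlo feature selection and interdependency discovery for survival omics: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo feature selection and interdependency discovery for survival omics: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcfsid)
```

# The problem

Glioma cohorts assembled from tumour methylation arrays (450k
beta-values), RNA-seq expression, and clinical records pose a
feature-selection problem of extreme shape: a few dozen deceased patients
against hundreds of thousands of candidate features. The scientific
question is which CpG sites and transcripts separate short-term from
long-term survivors — operationalised by dichotomizing days-to-death at a
threshold (400 days by default, where the survival-time histogram shows a
persistent drop) — and whether any features act *jointly* rather than
marginally. `mcfsid` implements the full discovery pipeline around Monte
Carlo Feature Selection with Interdependency Discovery (MCFS-ID):
projection-based decision-tree ensembles for feature ranking, a
permutation cutoff for significance, a directed interdependency graph,
corroborating dependency statistics, classifier validation, Kaplan-Meier
stratification, and probe-centred genomic-region annotation.

# The MCFS-ID model

`mcfs()` draws `s` random subsets ("projections") of `m` features; for
each subset it makes `t` stratified train/test splits (two thirds
training) and grows one binary classification tree per split. Trees are
grown greedily by maximal information gain (Shannon entropy in bits; Gini
available behind `mcfs_config(impurity=)`), with thresholds at midpoints
between consecutive sorted unique values. Each tree is scored on its
held-out part by weighted accuracy `wAcc` — the mean of the two per-class
recalls, robust to the class imbalance typical of survival dichotomies.

The relative importance of feature $g$ aggregates over all $s \cdot t$
trees $\tau$ and all nodes $n_g$ splitting on $g$:

$$\mathrm{RI}(g) \;=\; \sum_{\tau} \mathrm{wAcc}(\tau)^u
  \sum_{n_g \in \tau} \mathrm{IG}(n_g)
  \left(\frac{\mathrm{count}(n_g)}{\mathrm{count}(\mathrm{root}_\tau)}\right)^{v}$$

with $u = v = 1$ by default. The sum is additive over tree collections,
so the engine streams trees through the accumulator without ever holding
them in memory; `run_projections()` + `compute_ri()` expose the same
aggregation over explicit tree objects for inspection and testing, and
the two paths are verified against each other in the test suite.

At full scale the published settings are `s = 50000`, `m = 500`, `t = 5`;
all examples and tests in this package run at desk scale (`s` in the
hundreds to thousands), which the recovery experiments below show is
already sufficient for cohorts of a few hundred samples and ~1000
features.

## Significance cutoff

A ranking alone does not say where "informative" ends. `determine_cutoff()`
permutes the class labels `n_perm` times (20 by default), reruns MCFS on
each permutation with `s` reduced tenfold, and records the maximal RI any
feature attains under the null. Because RI is an unnormalised sum over
trees, a run with fewer projections produces proportionally smaller RI
values; the permutation maxima are therefore rescaled by
$s/s_\mathrm{perm}$ before use (RI is a sum of i.i.d. per-projection
contributions, so its expectation is linear in $s$). The cutoff is the
upper one-sided Student-t confidence bound of the rescaled max-RI sample,
$\bar{x} + t_{0.95,\,n-1}\, \hat\sigma/\sqrt{n}$, and features whose
real-data RI exceeds it are flagged significant. On pure-noise data
(1000 features, 100 samples) this procedure flags on average fewer than a
handful of features, as the acceptance suite checks.

## Interdependency graph

Marginal rankings miss features that act only in concert. The ID graph
exploits the tree structure directly: when a split on feature $a$ sits
above a split on feature $b$ on the same root path, $b$'s usefulness is
conditional on $a$'s — the classic signature of an interaction. For every
internal node $n$ and every ancestor $a$ on its path, the directed edge
$\mathrm{feature}(a) \to \mathrm{feature}(n)$ receives a candidate
contribution

$$\mathrm{wAcc}(\tau)^u \,\mathrm{IG}(n)
  \left(\frac{\mathrm{count}(n)}{\mathrm{count}(\mathrm{root})}\right)^{v}
  \Big/ \; \mathrm{dist}(a, n)$$

and each ordered feature pair is credited once per tree with its largest
contribution (the edge count tallies co-occurring trees). Three design
choices deserve explanation, because the published account fixes only two
monotonicity properties — edge strength increases with co-occurrence and
decreases with path distance — not a formula:

* **Why the RI-style weights.** A bare `IG/dist` accumulation lets deep,
  tiny nodes dominate: a pure split of three samples yields close to one
  bit of gain, and trees grown to purity manufacture thousands of such
  splits on noise. Weighting by tree quality (`wAcc^u`) and node-coverage
  fraction makes those contributions vanish while leaving genuine
  conditional splits — which occur high in the tree, on many samples —
  intact. It is also the same "structure analysis" currency RI uses.
* **Why once per tree.** Summing every ancestor-descendant occurrence
  rewards features that are re-split repeatedly along one deep path
  (interval refinement on continuous noise), quadratically inflating
  lucky noise pairs. Crediting the strongest occurrence per tree reads
  "number of co-occurrences" at tree granularity and keeps the statistic
  additive over tree collections (the streaming contract).
* **Why self-loops are kept but not ranked.** Two distinct nodes on one
  path may split the same feature; the graph records such `g -> g` edges,
  but `top_edges()` excludes them by default because an interdependency
  is a pairwise relation between two distinct features.

The planted-interaction experiment (below) is the hard test of this
statistic: a pure XOR pair is invisible to every marginal method by
construction, and reaches the trees only when both members land in the
same random projection — at `m = 20` of ~500 features roughly one
projection in 700.

## XOR blindness and the epsilon rule

Greedy gain-maximising growth proceeds only when the best split improves
on the parent by more than `epsilon` (1e-9), with ties broken to the
lowest feature index, then the lowest threshold. An exactly balanced XOR
block therefore never splits — its marginal gain is identically zero —
and interactions are reachable only through sampling imbalance and
projection diversity. This is a deliberate design: single-feature
lookahead would cost a factor of `m` per node, and the ID statistic is
precisely the instrument that harvests interaction evidence from the
ensemble instead of from any single tree. The consequence, quantified in
the tests, is that pure-interaction recovery is variance-limited at the
co-sampling rate; the recovery experiment at `s = 5000, m = 20` succeeds
in roughly half to three quarters of seeds, with failures caused by
noise features whose spurious marginal correlation (up to $|r| \approx
0.2$ at $n = 400$) anchors competing edges.

Trees stop splitting nodes below `min_split = 20` samples — the
conventional CART stopping rule (the same default as `rpart`). This
value was calibrated alongside the edge-weight design on planted-truth
simulations: smaller values deepen trees without improving either
marginal recovery or interaction recovery, while inflating the noise edge
mass.

# The synthetic cohort generator

Because the real cohorts cannot be redistributed, every pipeline stage is
exercised on `generate_dataset()`, which emulates the structure of a
TCGA-like glioma decision system with known ground truth:

* **Cohort**: 88 deceased patients by default, survival days 7–4084 with
  a discrete power-law density $\propto d^{-1.5}$, dichotomized at 400
  days. A pure power law with exponent above 1 puts ~90% of its mass
  below 400 days, which contradicts the observed 38 SHORT / 50 LONG
  split of the cohort it emulates; the generator therefore draws the
  class first (SHORT with probability 38/88) and then draws days from
  the power law truncated to the class's side of the threshold. This
  keeps the density's shape on each side, the exact class/day invariant,
  and the realistic class balance.
* **Methylation**: Beta-distributed with precision $\kappa = 50$
  (narrow, realistic beta-value peaks); informative CpGs shift their mean
  by `effect_size` on the logit scale between classes. Values stay in
  $[0,1]$ by construction — link functions, never clipping.
* **Expression**: log-normal (FPKM-like, heavy right tail); informative
  transcripts get a log-scale class shift.
* **Interactions**: each planted XOR pair dichotomizes two latent
  signals at their medians so that class equals the pair's parity with
  10% label noise — marginally silent (|r| < 0.1 with the class),
  jointly predictive (a two-stump parity rule reaches balanced accuracy
  ≈ 0.9, the ceiling imposed by the label noise).
* **Nuisance structure**: optional correlated feature blocks through a
  shared latent factor; age, gender and grade covariates independent of
  the class by default.
* **Determinism**: one global seed spawns a named sub-stream per block,
  so enlarging one block never perturbs another.

What the generator does *not* emulate — probe-chemistry artefacts,
SNP-masked probes, tumour purity mixtures, batch effects — bounds what
green tests mean: they demonstrate the statistical machinery, not
robustness to 450k platform artefacts.

# Downstream statistics

* **Mutual information** uses equal-frequency binning (5 bins by
  default) and the plug-in estimator in bits. Rank-based binning makes
  the estimate invariant under monotone transforms. Published usage is
  ambiguous about whether MI was taken against the binary class or raw
  survival days; both are available, with the binary class as default.
  Permutation p-values use the plus-one convention $(b+1)/(B+1)$,
  Bonferroni-corrected across tested features.
* **Interaction information** $II = I(x;y\mid z) - I(x;y)$ quantifies
  whether a covariate (age, gender) modulates a feature–survival
  dependence: positive = synergy, negative = redundancy. The permutation
  null shuffles $z$ within class, which preserves $I(x;y)$.
* **Kruskal–Wallis with Bonferroni** and **Pearson/Spearman correlation
  matrices** (with age and days-to-death appended) are delegated to
  `stats`; with two groups KW is the squared standardized rank-sum
  statistic, an identity the tests verify exactly.
* **Classifier validation** runs five stock classifiers (rpart tree,
  5-NN, 500-tree random forest, Gaussian naive Bayes, RBF SVM) behind a
  uniform fit/predict contract, reporting balanced accuracy. Feature
  selection happens *outside* cross-validation; when the features were
  selected on the same samples the CV figure is optimistic, and the
  honest figure is the train/test evaluation on an unseen cohort — the
  same caveat the original validation design carries.
* **Survival**: the product-limit estimator and the log-rank test are
  delegated to the `survival` package (`survfit`/`survdiff`, the same
  functions the original analysis used), wrapped in the three-way
  beta-value stratification (High > 0.96, Low < 0.85, Medium the closed
  interval between — the printed Medium definition has an inconsistent
  inequality direction, and the closed interval is the only reading
  consistent with High and Low). The High-vs-Low pair is the default
  log-rank comparison. Censoring is supported even though the target
  cohorts are all-deceased.
* **Regions**: probe positions (1-based, array-manifest convention) are
  converted to 0-based half-open intervals, extended ±25 bp (51 bp
  regions), and intersected with BED annotation tracks through
  `GenomicRanges`; a quadratic all-pairs oracle checks the intersection
  exactly in the tests.

# Numerical and degenerate-input choices

* Split thresholds at midpoints of consecutive distinct values; split
  ties to the lowest feature index then lowest threshold; majority-class
  ties at a leaf resolve to the first class level.
* Rank-based splitting makes every tree *structure* (chosen features,
  gains, node counts) invariant under strictly monotone transforms of the
  data. One ingredient is not rank-based: midpoint thresholds are not
  equivariant, so a held-out sample lying between `midpoint(a, b)` and
  `midpoint(g(a), g(b))` can switch sides and nudge `wAcc`. RI is
  therefore exactly transform-invariant at `u = 0` and structurally
  invariant (same trees, near-identical rankings) at the default `u = 1`.
* Single-class training input yields a flagged degenerate single-leaf
  tree contributing zero RI.
* Constant features: dropped by `drop_zero_variance()`; a constant
  feature has MI 0 and an undefined correlation (flagged `NA` with a
  warning).
* Missing values: features with any missing value are dropped before
  zero-variance filtering (conservative default, matching a pipeline that
  applied no additional processing); per-feature median imputation is
  available behind `na_action = "impute"`. How masked probes were handled
  originally is unrecorded, so the conservative default is ours.
* All randomness flows through R's RNG; every fitting function takes a
  seed, and the pipeline manifest's MD5 checksums are reproducible from
  the configuration alone.

# Problem sizes in the test suite

The acceptance tests run the recovery experiment at
$n = 150, p = 1000$ with $s = 2000$ (ten seeds), the interaction
experiment at $n = 400, p = 504$ with $s = 5000$ (ten seeds), the null
cutoff control at $p = 1000$ over 20 repeats, 1000 log-rank null
simulations, and a 1000×1000 interval-intersection fuzz — sizes chosen so
the full suite completes on a single CPU in well under half an hour while
leaving each experiment enough replicates to be statistically meaningful.

# Known limitations

* Binary decisions only (two survival classes); no multi-class or
  regression trees.
* Bit-compatibility with other MCFS implementations is out of reach
  (different tie-breaking alone changes trees); equivalence is at the
  property level.
* Pure-interaction (XOR) recovery at realistic co-sampling rates is
  variance-limited, as quantified above; interactions with any marginal
  component are recovered far more reliably.
* The permutation cutoff inherits Monte Carlo noise from `n_perm` and
  the reduced permutation `s`; tight significance claims near the cutoff
  deserve a larger `n_perm`.
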
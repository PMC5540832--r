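---
title: "Discriminating clinical subgroups from structural connectomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating clinical subgroups from structural connectomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psyconn)
```

# The analysis problem

In 22q11.2 deletion syndrome, roughly a third of patients develop attenuated
positive psychotic symptoms during adolescence, and identifying structural
brain correlates of that subgroup is a step toward early risk markers. The
analysis this package implements asks whether two matched patient groups —
`psy_pos` (at least one SIPS positive item P1–P5 scored ≥ 3) and `psy_neg`
(all items < 3) — can be discriminated from three kinds of white-matter
features:

1. **Edge features**: the upper triangle of each subject's 83 × 83
   streamline-count matrix (3403 region-pair features);
2. **Graph-theory features**: five global measures (characteristic path
   length $L$, global efficiency $E$, mean clustering $\bar C$, modularity
   $Q$, small-world index $\sigma$) and three local measures per region
   (betweenness centrality, clustering coefficient, strength), computed on
   the weighted and on the binarized connectome — a fixed-order vector of
   $5 + 3 \times 83 = 254$ features;
3. **Diffusion features**: mean FA, AD and RD along 18 reconstructed
   white-matter bundles.

The package starts from tractography *outputs* (count and mean-length
matrices, tract tables); image processing is out of scope.

# Connectome construction

Count matrices are validated (symmetry to a relative tolerance of $10^{-9}$,
nonnegativity, zero diagonal), optionally normalized by dividing each count
by the mean streamline length of that connection (correcting the
long-tract seeding bias of deterministic tractography), and never thresholded:
binarization keeps every strictly positive weight as an edge. Because no
threshold is applied, the binary graph encodes exactly the support of the
count matrix, and `binarize(length_normalize(c, l))` equals `binarize(c)`.

# Graph measures

Distances use unit edge lengths on binary graphs and inverse weights $1/w$
on weighted graphs — the standard convention for streamline-count
connectomes, where a stronger connection is "shorter". The transform is a
genuine modelling choice (a $-\log w$ kernel is also defensible); it is
isolated in one internal function, and the scale-behaviour tests pin down
its consequences ($L \mapsto L/c$ under $w \mapsto cw$).

* **Characteristic path length** is the mean shortest-path distance over
  connected distinct pairs; the disconnected fraction is attached to the
  result as an attribute rather than silently folded in. On an edgeless
  graph $L$ is NaN.
* **Efficiency** is the mean of $1/d$ over all distinct pairs with
  $1/\infty := 0$, which is why it is the better-behaved measure on
  disconnected graphs.
* **Clustering** is the triangle density $2t_i/(k_i(k_i-1))$ on binary
  graphs and the Onnela geometric-mean form on weighted graphs, with
  weights normalized by the graph maximum (the default of the standard
  brain-connectivity toolbox). Nodes of degree < 2 get 0 and stay in the
  mean.
* **Betweenness** sums $\sigma_{st}(v)/\sigma_{st}$ over unordered pairs,
  endpoints excluded, unnormalized.
* **Modularity** $Q$ is maximized by a seeded multi-level (Louvain) search
  with 10 restarts, each followed by a greedy refinement that alternates
  single-node moves (including moves to a fresh singleton) with pairwise
  community merges until neither improves $Q$. On graphs of ≤ 16 nodes each
  restart additionally refines from the singleton partition and from a
  random partition: the multi-level pass can lock in a bad coarse merge on
  tiny graphs, and the extra starts are cheap there. The test suite holds
  the search to the exhaustively enumerated optimum on hundreds of random
  graphs of up to 8 nodes (4140 partitions each).
* **Small-world index** $\sigma = (\bar C/\bar C_{null})/(L/L_{null})$
  against 100 degree-preserving rewired nulls (double edge swaps, $10|E|$
  attempted swaps each); on weighted graphs the original weights are
  shuffled over the rewired edges. $\sigma$ is the one stochastic measure,
  so it is seeded; each subject draws its own deterministic seed from the
  master seed and its cohort position, making per-subject features
  independent of cohort order. If the null ensemble has no triangles at
  all, $\sigma$ is reported as NaN with a warning rather than a fabricated
  value — classifier inputs are required to be finite, and sparse toy
  graphs are the only place this arises in practice.

# The discrimination framework

**Classifier.** Gaussian naive Bayes: each feature is modelled per class as
an independent normal. Priors are the empirical class proportions of the
training fold — in a leave-one-out loop over a 31/31 cohort, every fold has
priors $31/61 = 50.82\%$ and $30/61 = 49.18\%$. Per-class variances are
floored by adding $10^{-9} \times$ the largest feature variance of the full
training matrix, so a within-class-constant feature yields a proper
density; the floor is taken from the full matrix (not the selected subset)
so that models at different feature counts nest exactly. Exact posterior
ties go to the larger-prior class, then to the first class.

**Feature selection.** Features are ranked by the absolute point-biserial
correlation (Pearson correlation with the 0/1-coded label); zero-variance
features score 0; ties break by feature index. The incremental curve
refits the classifier at each count of a grid — edges (10, 10, …, 1600),
graph measures (5, 10, …, 250, 254; the total is appended when it is off
the step lattice), diffusion (1 … 18) — and reports each point's accuracy
with its 95% Wilson score interval.

**Ranking scope.** The default ranks features *inside each training fold*,
which is the leakage-free reading of selection-then-LOOCV; a `global`
option (rank once on everyone) is kept for replicating analyses that
selected features outside the loop, and warns loudly about its optimism.
The leakage contract is enforced by test: corrupting the held-out subject's
features must leave the trained fold model bit-identical.

**Significance.** A grid point is flagged when its 95% Wilson interval
excludes the 50% chance level. Because many classifiers are evaluated along
a curve, per-point flags are descriptive, not selection-corrected — the
feature-curve documentation says so, and the chance-level behaviour of the
whole procedure is itself measured in the test suite on label-permuted and
null-effect data.

**Covariates.** Optional in-loop residualization regresses each feature on
age, sex and scanner (or any manifest columns) *using training rows only*,
then applies the training coefficients to the held-out subject. Unseen
categorical levels in the test subject are a hard error; rank-deficient
designs drop collinear columns with a warning. The headline analysis runs
without covariates, matching the design this replicates; the corrected
rerun is a flag away.

**Inference utilities.** The univariate screen is a two-sided Mann-Whitney
U per feature (exact when both groups ≤ 20 and the feature is tie-free,
tie-corrected normal approximation otherwise — group sizes of 31 always use
the approximation) under Benjamini-Hochberg FDR at $q = 0.05$, applied per
feature family. The matched-pair bootstrap removes one random pair per
trial and reruns the configured curve on the remaining 30/30, reporting how
often the best accuracy stays above chance and stays significant (100
trials by default; the per-trial best grid point is used, with the
alternative fixed-feature-set reading available by passing a single-point
grid).

# The synthetic cohort generator

No patient data are distributable, so the generator produces cohorts with
the statistical structure the analysis assumes, and the pipeline is
validated on what it can actually claim: calibration under the null and
recovery of known planted effects.

* **Template**: a stochastic-block-model graph (4 near-equal communities;
  within-community edge probability 0.45, between 0.08 at 83 regions),
  log-normal streamline counts (median 50, log-sd 1) and uniform 10–150 mm
  mean lengths on present edges. For other parcellation sizes the default
  densities are rescaled by $\sqrt{82/(n-1)}$ (capped at 0.9): coarser
  parcellations yield denser connectomes in real tractography, and the
  square-root compromise keeps node degrees out of the noisy
  low-degree regime at 30 regions without saturating the graph.
* **Subjects**: 31 matched pairs by default; pair members share sex and are
  within one year of age; scanners split roughly 80/20 between two models.
  SIPS P1–P5 scores are drawn consistent with the intended group so the
  labeling rule reproduces the design exactly.
* **Noise**: multiplicative log-normal count noise (sd 0.3) plus
  per-subject *edge dropout* at a rate drawn uniformly in 0.10 ± 0.03.
  The dropout matters: multiplicative noise alone preserves the support,
  which would make every unaffected subject's binary graph identical — a
  degenerate cohort no real tractography produces. Dropout emulates
  false-negative streamlines, and its mild subject-to-subject spread
  emulates scan-quality heterogeneity. The spread is deliberately small:
  a wide spread turns overall density into a dominant factor shared by
  every graph feature, and such a factor drives leave-one-out accuracy on
  *null* data systematically below chance (the held-out subject is
  excluded from its own class mean, and a single shared noise axis turns
  that small exclusion bias into consistent anti-learning). The package's
  calibration tests measure exactly this behaviour.
* **Group effect**: every patient carries the same amount of local
  rewiring; what differs between groups is *where* it concentrates. In
  `psy_pos` subjects each edge incident to a designated region is, with
  probability `topo_effect`, detached and reattached to a random
  non-neighbour; in `psy_neg` subjects the same procedure runs at an
  equal number of regions drawn fresh per subject. Rewiring (rather than
  removal) preserves the node's degree, so strength carries almost no
  signal, while the region's clustering coefficient collapses (its new
  neighbours are not interconnected) and its betweenness shifts — the
  signal lives in the local measures of the designated regions. Matching
  the *amount* of disruption between groups makes the global measures
  exchangeable by construction, reproducing the empirical pattern this
  design emulates, where every global-measure classifier performed at
  chance and only localized betweenness/clustering discriminated; it also
  reflects that the comparison group are patients with the same syndrome,
  not healthy controls. For the 83-region parcellation the default
  affected regions are the right amygdala, left posterior cingulate, left
  parahippocampal and right rostral anterior cingulate; other
  parcellations default to five regions spread across the communities.
* **Diffusion effect**: FA down (−0.03) and RD up (+3 × 10⁻⁵ mm²/s) in the
  bilateral inferior longitudinal fasciculus and cingulum cingulate gyrus,
  on top of per-tract means drawn in physiological ranges; validity bounds
  (FA ∈ [0,1], AD ≥ RD ≥ 0) are enforced after shifting.
* **Covariate nuisance**: age, sex and scanner act multiplicatively on
  counts and additively (scaled) on diffusion values for *all* subjects;
  since the design is matched, they are nuisance variance rather than
  confounds.

What the generator does **not** emulate: anatomical geometry, distance-
dependent connection probabilities, hub structure beyond the block model,
site-by-sequence interactions, or realistic effect sizes — the true effect
sizes of the motivating study are unknowable from its report. Passing
recovery tests therefore shows the *pipeline* recovers what was planted
under these assumptions, not that real cohorts of this size yield similar
accuracies.

# Numerical and scale choices

* Asymmetric inputs beyond $10^{-9}$ relative tolerance are symmetrized by
  averaging with a warning (tractography exporters disagree about rounding);
  within tolerance, silently.
* Matrix round trips are exact: matrices are written with 17 significant
  digits.
* The edge vector is the row-major strict upper triangle with a stored
  index map, so vectorization is invertible.
* Within the LOOCV grid engine, per-fold ranking and residualization happen
  once and the naive-Bayes log-likelihood is accumulated feature by feature
  in rank order, which makes the whole curve exactly equal to — and much
  cheaper than — refitting at every grid point.
* Simulation-based validation runs at reduced problem sizes chosen to keep
  the full suite fast while leaving the estimands unchanged: 30-region
  cohorts of 31 pairs for calibration (20 seeds) and recovery (25 seeds,
  `topo_effect = 0.6`), oracle comparisons on graphs of ≤ 8 nodes where
  exhaustive enumeration is feasible, and 100 rewiring nulls per
  small-world index throughout.

# Known limitations

* The weighted small-world null model (rewire + weight shuffle) is one of
  several defensible constructions; the binary form is the standard one.
* The Wilson significance flag along a feature curve is not corrected for
  selection over grid points; treat curve maxima as descriptive.
* The `global` ranking scope reproduces a leaky design on purpose; its
  accuracies should never be reported as generalization estimates.
* Modularity maximization is NP-hard; beyond oracle-checkable sizes the
  seeded search returns the best of its restarts, which is the field's
  standard practice, not a certified optimum.
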
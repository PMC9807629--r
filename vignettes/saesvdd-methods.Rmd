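---
title: "Methods: one-class detection of rare respondents in binary questionnaires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one-class detection of rare respondents in binary questionnaires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Screening surveys for conditions such as antenatal depression produce data
that is awkward for ordinary classifiers in three ways at once: the positive
class is rare (roughly 7% in the motivating survey of 5666 respondents), the
one-hot encoded answers are high-dimensional and sparse (147 binary option
columns), and the healthy majority is itself heterogeneous — different
subpopulations answer consistently differently. `saesvdd` addresses this as a
*one-class* problem: learn the support of the majority (target) class only,
and flag anything outside it as abnormal.

## Support vector data description

The core primitive is the kernel SVDD hypersphere. For target samples
$x_1,\dots,x_n$ the primal seeks a center $a$ and radius $R$ minimizing
$R^2 + C\sum_i \xi_i$ subject to $\|x_i-a\|^2 \le R^2 + \xi_i$,
$\xi_i \ge 0$. The dual solved by the package is

$$\max_\alpha \; \sum_i \alpha_i\,\phi(x_i,x_i)
  - \sum_{i,j}\alpha_i\alpha_j\,\phi(x_i,x_j)
  \quad\text{s.t.}\quad \sum_i \alpha_i = 1,\; 0 \le \alpha_i \le C,$$

with $\phi$ the kernel. Points with $0<\alpha_i<C$ sit on the sphere
(boundary support vectors), $\alpha_i = C$ points sit outside, and the
penalty $C$ controls how many training points may be discarded as outliers:
the larger $C$, the fewer. A query $z$ is scored by its squared kernel-space
distance to the center,
$\phi(z,z) - 2\sum_i\alpha_i\phi(z,x_i) + \sum_{i,j}\alpha_i\alpha_j\phi(x_i,x_j)$,
and accepted iff this distance does not exceed $R^2$. (Two printed
conventions in the source material conflict here — a box $\alpha_i\le 1$
versus $\alpha_i\le C$, and an acceptance rule "$f(z)\le 0$" for a quantity
that is a squared distance; the package implements the classical forms,
$\alpha_i \le C$ and $\text{dist}^2 \le R^2$.)

The default kernel is the RBF $\exp(-\|x-y\|^2/\sigma^2)$ — note the
$\sigma^2$ (not $2\sigma^2$) denominator, fixed and documented because
conventions vary.

### Numerical choices

* The dual is solved by a purpose-built SMO-style pairwise coordinate
  ascent on the capped simplex (C++): the maximal-violation pair is updated
  analytically until the Karush–Kuhn–Tucker violation falls below `1e-8`.
  A swarm-tuning run performs thousands of medium-$n$ solves, which is why
  the solver is specialized rather than a generic QP; tests cross-check it
  against a brute-force simplex grid (all $n \le 4$ instances) and against
  `kernlab::ipop`. Alternative solvers can be plugged in via the `solver`
  argument of `svdd_solve_dual()`.
* $R^2$ is the mean squared center distance of the boundary support vectors
  (`0 < alpha < C` at tolerance `1e-6`); if none exist (e.g. the degenerate
  $C = 1/n$ solution where every $\alpha$ sits at the bound), the maximum
  over support vectors is used.
* The acceptance test is $\text{dist}^2 \le R^2(1+10^{-9}) + 10^{-7}$. The
  absolute term is deliberate: boundary support vectors scatter around
  $R^2$ by the solver tolerance, and a purely relative slack misclassifies
  half of them on tight spheres.

## Divide and conquer: affinity propagation sub-clusters

A single sphere around a heterogeneous majority class is loose: the space
between subpopulations lies inside it, and rare-class points living there
are accepted. The pipeline therefore partitions the target training set by
affinity propagation (similarity = negative squared Euclidean distance, the
classical choice) and fits one tuned sphere per sub-cluster; a query is
target iff it falls inside *any* sphere (union rule).

AP's `preference` diagonal controls the number of exemplars. It is chosen
by Latin hypercube sampling of `n_candidates = 10` values over
`[min, median]` of the off-diagonal similarities — spanning the
few-clusters to moderate-clusters regime — scoring each candidate partition
by mean silhouette $s(i) = (b(i)-a(i))/\max(a(i),b(i))$ and keeping the
best. Single-cluster candidates are excluded (the silhouette is undefined
for $K=1$); if every candidate collapses, the pipeline degenerates
gracefully to one plain sphere. Singleton clusters score $s(i)=0$ by
convention. Clusters smaller than `min_cluster_size = 3` are merged into
the nearest exemplar's cluster before tuning, since a sphere needs
$C \ge 1/n$ and at least one boundary point.

Message passing uses damping 0.9, up to 1000 iterations, and declares
convergence after 100 iterations with an unchanged exemplar set — all
configurable. Because message passing is quadratic in $n$, inputs beyond
`max_n = 1000` points are clustered on a seeded random subsample and the
remaining points are assigned to the nearest exemplar; the scale at which
this engages is far below the regime where AP's memory itself becomes a
problem, so the package makes no attempt at sparse or streaming variants.

## Swarm-tuned parameters and the fitness question

Each sub-cluster's $(C,\sigma)$ is tuned by a canonical inertia-weight PSO
(defaults $w=0.729$, $c_1=c_2=1.49445$, 20 particles, 30 iterations) with
one refinement: when the global best stagnates for 5 iterations, it is
re-perturbed with probability 0.2 by Gaussian noise scaled to the search
box. This optimizer is an explicit, documented stand-in for a
published-elsewhere adaptive-mutation PSO whose internals are not
reproduced here; the optimizer interface (`pso_optimize`) is swappable.

Two design points deserve emphasis because the source material is silent on
both:

* **Where do negatives come from?** The classifier trains on target samples
  only, yet the tuning fitness is an F-score. The package scores each
  5-fold split by validating on the held-out targets (positives) plus
  *synthetic outliers* drawn uniformly from the cluster's bounding box
  expanded by 10% per side, one outlier per held-out target by default —
  the classical artificial-outlier device for one-class model selection. In
  the high-dimensional spaces this package targets, box-uniform points are
  overwhelmingly far from the data cloud, so they act as "easy negatives"
  that mainly punish engulfing spheres; in low dimensions (2–3-D toys) they
  overlap the cluster and cap the achievable fitness, which the test suite
  accounts for by passing explicit far negatives
  (`outlier_config(negatives=)`) where a separable score is asserted.
* **On what scale is the penalty searched?** The box constraint only acts
  through $C\,n$ (the dual fixes $\sum\alpha=1$), so an absolute $C$ tuned
  on CV folds of size $m$ means something different on the full cluster of
  size $n_k$. The search is therefore parameterized as
  $\nu = 1/(Cn) \in (0,1]$ on a log scale — $\nu=1$ is the fully-relaxed
  centroid-like sphere, small $\nu$ the hard-margin sphere — and the tuned
  $\nu$ transfers unchanged from folds to the final refit. Kernel width is
  searched over $\log_{10}\sigma\in[-2,2]$. Clusters larger than
  `fitness_max_n = 400` points are tuned on a seeded subsample of that size
  (the final sphere always uses the full cluster), keeping the
  swarm-times-folds cost of the quadratic solver bounded.

## The stacked autoencoder front end

Sparse 147-dimensional 0/1 vectors are a hostile geometry for
distance-based methods: pairwise distances concentrate and cluster
structure is buried. The pipeline therefore first embeds the data with a
stacked autoencoder (default architecture 147 → 110 → 90 → 30), trained
greedily: each symmetric autoencoder (sigmoid activation, untied encode and
decode weights) learns to reconstruct its own input — the frozen code of
the previous layer — by mini-batch SGD on squared reconstruction error,
front to back, with no end-to-end fine-tuning (there are no labels to
fine-tune against). The multi-sphere classifier is then fitted on the
30-dimensional codes, and prediction encodes queries internally.

The default step size is 0.3 with 60 epochs and batch 32. This is worth a
note: with sigmoid units on sparse binary inputs, timid steps (0.01) leave
the first autoencoder essentially at its initialization, producing
near-constant codes in which no downstream structure survives. On the
package's synthetic benchmark the step-0.3 encoder raises the code-space
silhouette of the true clusters to ~0.90, versus ~0.22 in the raw space —
the dimensionality reduction is what makes the sub-cluster geometry
visible. Weight tying and denoising/sparsity penalties are deliberately not
defaulted on; hooks exist in the configuration.

## Option importance: improved TF-IDF and information gain

To explain *which* questionnaire options separate the classes, each option
$t$ is scored by

$$\text{imp}(t) = \frac{p_t}{N_p}\,\log_{10}\frac{N}{1+n_t},$$

where $p_t$ and $n_t$ count abnormal and normal respondents selecting $t$,
$N_p$ is the abnormal total and $N$ the grand total — selection frequency
among cases, discounted by prevalence among controls — together with the
information gain of the selected/not-selected split,
$\text{Gain} = \text{Ent}(D) - \sum_v \frac{|D^v|}{|D|}\text{Ent}(D^v)$,
under the convention $0\log 0 = 0$.

Both default to base-10 logarithms. The printed reference values this
implementation was validated against (all ten importance scores and the
information-gain column of the published top-ten table, `N = 5666`,
`N_p = 407`, shipped in `inst/extdata/`) reproduce to 4 decimals only in
base 10, even though entropy is conventionally written in base 2; the base
is configurable, and since changing it rescales every score by a constant,
rankings are base-invariant. `rank_options()` sorts descending, breaking
ties by column order, and also reports corpus averages over all options.

## The synthetic generator: what it emulates and what it does not

No machine-readable respondent-level survey accompanies the published
counts, so the package ships a generator whose defaults emulate the
documented conditions: 5259 target / 407 abnormal respondents, 147 binary
options, target heterogeneity as a mixture of Bernoulli-profile clusters,
and designated risk options selected at 0.35 by the abnormal class versus
0.12 by targets — mirroring the top published risk factor (138/407 ≈ 0.34
vs 646/5259 ≈ 0.12). Auto-generated cluster profiles raise a disjoint
random set of 25 "signature" options per cluster from the background rate
0.10 to 0.75, the way a subpopulation consistently picks particular
answers; abnormal rows follow the background profile with risk options
elevated. All randomness derives from one seed through labeled sub-seeds
(`derive_seed`), so each stage is independently reproducible.

The generator makes no attempt at realistic item correlations beyond the
mixture, at ordinal answer structure, or at label noise in the screening
instrument. Tests passing on this generator therefore demonstrate that the
pipeline recovers planted cluster structure and planted risk enrichment
under the documented imbalance and dimensionality — not that it matches
any particular clinical survey's operating characteristics.

## Benchmark configuration used by the tests

The end-to-end claim checked by the test suite and the acceptance script —
that the autoencoder + multi-sphere pipeline dominates a tuned plain
single sphere, with test F-score at least 0.80 — runs on 2000 targets in 3
clusters plus 150 abnormal at 147 features, split 80/20 (all abnormals to
test), averaged over 5 seeded replicates, with the default swarm budget.
These sizes were chosen as the smallest at which the planted structure is
stable across seeds; at this scale one replicate (autoencoder training, AP
preference search, per-cluster swarm tuning, baseline tuning, evaluation)
completes in about a minute on one core. Risk-option recovery is scored
over 20 replicates with a top-16 criterion (twice the planted risk-set
size).

## Known limitations

* Sphere tuning optimizes an F-score against synthetic negatives; if real
  negatives are available they are almost certainly more informative
  (`outlier_config(negatives=)` accepts them).
* The silhouette-maximal preference never selects $K=1$, so homogeneous
  target data is partitioned anyway; the union of the resulting spheres is
  still a sound (if more fragmented) description.
* Greedy layer-wise SGD with a fixed step is deliberately simple; the
  encoder is replaceable, and no claim is made that it is optimal.
* Training-set sizes beyond ~10⁴ would want a sub-quadratic clustering
  stage; the present subsample-and-assign device is adequate at survey
  scale.
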
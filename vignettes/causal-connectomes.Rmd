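---
title: "Causal connectomes by greedy adjacency search and non-Gaussian orientation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal connectomes by greedy adjacency search and non-Gaussian orientation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gango)
```

## The model

`gango` treats a parcellated resting-state recording as `n` exchangeable
samples of a linear structural equation model
`x = Bx + e`, where `B` is strictly lower-triangular in some (unknown)
node ordering — i.e. the causal structure is a DAG — and the noise
components `e_i` are mutually independent and *skewed*. Two consequences
of this model drive the two pipeline stages:

* The conditional-independence structure (hence the adjacency skeleton) is
  identified by the Gaussian likelihood alone, so a BIC-scored search over
  Markov equivalence classes recovers adjacencies consistently.
* Gaussian likelihoods cannot distinguish `x → y` from `y → x` within an
  equivalence class, but *non-Gaussian* noise breaks that symmetry: for an
  adjacent pair, higher-order statistics of the standardized pair identify
  the direction.

The pipeline is therefore: greedy equivalence search → discard
orientations (symmetrize) → re-orient every adjacency with a pairwise
skew statistic. Orientations from the search stage are deliberately
thrown away: score-based searches estimate adjacencies much more
accurately than orientations, while the pairwise stage orients every edge
and does so from information the score never uses.

### Adjacency stage

The search state is a completed partially directed graph (pattern). The
local score of node `v` with parent set `P` is

    score(v | P) = -n * ln(sigma2_hat(v | P)) - c * |P| * ln(n)

with `sigma2_hat` the least-squares residual variance (computed from the
covariance of z-scored columns) and `c` the *penalty discount* (`penalty`
argument, default 1 = classic BIC; larger values give sparser graphs).
Constants independent of `P` are dropped. The forward phase repeatedly
applies the best-scoring valid Insert(X, Y, T) operator while the best
improvement is strictly positive; the backward phase does the same with
Delete(X, Y, H). Operator validity uses the standard clique and
semi-directed-path conditions for search over equivalence classes, and
after every applied operator the graph is re-completed: a consistent DAG
extension is computed, its v-structures oriented, and orientations closed
under the Meek rules (R1–R3, which are complete when all orientation
information comes from v-structures).

Numerical and determinism choices:

* Ties between equal-scoring operators are broken lexicographically by
  (source index, target index, subset); together with the fixed
  enumeration order this makes the search fully deterministic, enabling
  exact regression tests.
* "Stops improving" is a strict `> 0` test on the score change.
* Residual variances are floored at machine epsilon before the log;
  collinear parent sets raise an error (they indicate duplicated or
  degenerate parcels, which should be fixed upstream).
* Columns are z-scored before the covariance is formed, matching the
  standard per-run z-scoring of resting-state data; the BIC comparison is
  scale-invariant, so this only fixes the additive constant.
* No maximum-degree cap is imposed.

The test suite validates the search against an *exhaustive* oracle: on
every 3-node structure (25 DAGs) and on random 4-node problems, the
greedy result is compared with the pattern of the equivalence class that
maximizes the total BIC over all enumerated DAGs. Agreement is essentially
perfect at `n = 2000`, which is the strongest property this design can
ask for: the greedy search attains the global optimum of its score.

A consequence worth stating plainly: at `c = 1` the score *admits* weak
false adjacencies by construction. Adding a parent is accepted when the
likelihood-ratio statistic exceeds `ln n` — a per-pair type-I rate of
about `P(chi2_1 > ln n)`, i.e. ~0.6% at `n = 2000`. Over the ~190 pairs
of a 20-node problem this yields roughly one spurious adjacency per graph
*even for the globally BIC-optimal graph*, and heavy-tailed (exponential)
noise inflates it slightly. The acceptance study measures adjacency
precision ~0.85–0.87 and recall ~0.99 at p = 20, density 5%, n = 2000;
raising `penalty` trades recall for precision, but 1 is kept as the
default because the classic BIC is the method's stated operating point.

### Orientation stage

For each adjacency `{i, j}` the statistic

    R = rho_hat * ( mean(g(x) * y) - mean(x * g(y)) ),   g(u) = ln cosh(max(u, 0))

is computed on the standardized pair, after sign-flipping any series
whose sample skewness is negative (the statistic is derived under
positive skewness; both skewness signs carry the same information).
`R > 0` orients `i → j`. The `ln cosh` contrast saturates for large
arguments, so single extreme samples cannot flip a decision — the
"outlier-robust" property. The sign convention is pinned by a simulation
oracle in the test suite: on pairs generated as `y = 0.8x + e` with
exponential noise at `n = 2400`, the statistic picks the generating
direction in >99% of replicates, while under Gaussian noise accuracy
collapses to chance (~50%) — the documented negative control that
motivates the gate. An exactly zero statistic (a measure-zero event) is
resolved deterministically as lower index → higher index, with a warning.

Each pair is standardized internally, so orientation does not depend on
whether the caller pre-scaled the data.

### The non-Gaussianity gate

Per subject, the absolute sample skewness (moment form, `m3 / m2^{3/2}`)
of each of the `p` parcels is compared against that of `p` freshly drawn
Gaussian surrogate series of the same length, with a one-tailed Wilcoxon
rank-sum test (observed > surrogate) at `alpha = 0.05`. The moment
estimator is used rather than the adjusted form because the rank test
compares equal-length series, so the shared bias factor cancels. Parcels
with zero variance are excluded with a warning (their skewness is
undefined); surrogates are drawn from a per-subject sub-seed of the
master seed. `gango()` refuses to orient when the gate fails unless
`force = TRUE` — orienting by skewness on non-skewed data produces
arbitrary directions.

## Graph analytics

* **Centralities**: indegree, outdegree, total degree, and unnormalized
  directed betweenness (raw shortest-path counts, endpoints excluded).
  Betweenness is unnormalized because all comparisons are within a fixed
  node count, and raw counts are directly checkable against path
  enumeration (the tests do exactly that on all small digraphs).
* **Participation coefficient** `P_i = 1 - Σ_s (κ_is / K_i)²`, computable
  on incoming, outgoing, or all connections; `P_i = 0` for isolated
  nodes by definition.
* **Global efficiency**: mean inverse directed shortest-path length over
  ordered pairs, zero for unreachable pairs. Undirected comparison graphs
  use unordered semantics.
* **Hub nulls**: random directed graphs with the observed node count and
  an edge count drawn per graph from `Normal(m_mean, m_sd)` (rounded,
  clipped), pooled into one nodal reference distribution per metric; a
  node is a hub when it exceeds the pooled 95th percentile. Pooling
  (rather than per-graph percentiles) is the documented choice: the
  comparison is against "the surrogate distribution", singular. One
  calibration subtlety matters for testing: hub flags are strongly
  correlated *within* a graph (a dense edge-count draw lifts every
  node's centrality), so calibration must be judged on per-graph flag
  rates with a cluster-robust interval; a pooled binomial band around 5%
  would reject even a perfectly calibrated generator.
* **Heavy-tail test**: rank-sum comparison of per-graph skewness of a
  centrality's nodal distribution, observed vs surrogate.
* **Correlation comparison graphs**: Pearson matrix thresholded to retain
  the largest *positive* values, either a fixed 15% of unordered pairs or
  an exact count for density-matching a causal graph; ties broken
  deterministically by value then index.

## Group statistics

All group tests are nonparametric and paired within subject:

* **Inter-module connectivity**: per module pair, the shared edge count is
  tested (Wilcoxon signed-rank) against the equal-spread null
  `total out-of-module count / (N_M - 1)`, BH-FDR corrected over all
  ordered pairs; significant pairs must also clear a paired Cohen's d
  (mean difference / SD of differences, the paired analogue matching the
  signed-rank design) of at least 0.2. Direction is established by testing
  the proportion of edges running a → b against 0.5 (signed-rank, BH-FDR).
* **Sender/receiver**: per module, subject-wise mean indegree vs
  outdegree, signed-rank, BH-FDR over modules; undefined tests (modules
  with no edges anywhere) are reported balanced with a degenerate flag.
* **Across-module centrality**: Friedman test on subject x module mean
  centralities, with Nemenyi all-pairs post-hocs on mean ranks
  (`q = |ΔR̄| / sqrt(k(k+1)/12n)` referred to the Studentized range);
  the mean-rank form is the documented choice.
* Wilcoxon tests use the exact distribution for tie-free samples of at
  most 25 differences and the normal approximation with continuity
  correction otherwise (R's exact path does not handle ties); zero
  differences are discarded, the classic treatment.

## Virtual lesions

`lesion_curve()` deletes nodes cumulatively and records percent change in
global efficiency relative to the intact graph (curves start at 0%).
`targeted_attack()` runs one schedule per module — `n_reps = 10` random
intra-module orders, averaged — plus one random-attack schedule drawing
from the whole graph, with length equal to the largest module so curves
share a plot range (the random-schedule length is not pinned down by any
external convention; this is our choice). Slopes are mean first
differences per *node deleted* (unit steps, not fraction-of-module steps;
configurable downstream if module-size normalization is wanted). Deleting
a disconnected node *increases* efficiency — it removes zeros from the
pairwise average — which is why weakly integrated modules show positive
lesion slopes.

## The synthetic-data generator

The generator exists so that every stage is testable end to end without
any neuroimaging data. It emulates:

* ~2400 samples per subject (two z-scored 1200-sample runs concatenated),
* a sparse linear acyclic causal structure (default density 2.25% of
  unordered pairs — the regime the pipeline targets),
* skewed marginals via standardized exponential noise (analytic skewness
  2, giving closed-form checks) or gamma noise; Gaussian noise as the
  negative control,
* edge weights uniform on ±[0.3, 0.8] — strong enough for detection at
  n = 2400, weak enough to avoid near-deterministic coupling,
* a module partition with near-equal module sizes (12 modules by
  default).

Samples are i.i.d.: the score and the orientation statistic both treat
rows as exchangeable, so temporal autocorrelation is deliberately absent
(an AR(1) coloring flag exists for sensitivity experiments but defaults
off). The generator makes no attempt at hemodynamics, spatial smoothing,
or realistic fMRI noise spectra — so passing tests demonstrate
correctness of the *statistical machinery under its own assumptions*, not
robustness to the full generative complexity of BOLD data. On real
recordings the i.i.d. and linearity assumptions are approximations, which
is precisely why the skewness gate is a hard precondition of the
orientation stage.

## Validation study sizes

The test suite and `scripts/acceptance.R` run: the exhaustive 3-node
oracle over all 25 structures (20 and 8 seeds respectively, n = 2000);
adjacency recovery at p = 20, density 5%, n = 2000 (20 and 10 seeds);
orientation accuracy over 1000/500 pairs at n = 2400; gate type-I
calibration over 1000/400 replicates (run at a compact p = 60, n = 300 —
the rank-sum null is size-invariant — with power checked at the full
p = 360, n = 2400); hub-null calibration at p = 100 with 200 surrogates;
and group-statistics calibration on 12-module cohorts of 20 subjects at
p = 60 with m = 600 edges, chosen so per-pair inter-module counts (~8)
are comparable to those of empirical connectomes (~1452 edges over 12
networks), the regime where count-based signed-rank tests are
well-behaved.

## Known limitations

* Two-cycles and feedback loops are outside the model class: every
  adjacency receives exactly one direction.
* The adjacency stage inherits the classic-BIC operating point: about one
  weak spurious adjacency per ~200 node pairs at n = 2000 (see above);
  use `penalty > 1` when precision matters more than recall.
* Orientation accuracy degrades to chance as noise approaches
  Gaussianity; the gate catches this per subject, but a passing gate does
  not guarantee that *every* parcel pair is strongly skewed.
* Group tests assume subjects are exchangeable and use large-sample
  approximations for tied data.
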
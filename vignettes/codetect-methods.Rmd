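---
title: "Probability-based co-detection networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probability-based co-detection networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codetect)
```

## The problem

Microbial co-occurrence networks built from correlation coefficients are
notoriously sensitive to how many samples went into them: edge counts keep
growing with sample size, compositionality distorts the coefficients, and
two cohorts of different size are not comparable. `codetect` implements an
alternative that uses only the *detection pattern* of each genus — in which
samples it is present at all — together with the machinery needed to compare
it against correlation-based networks and to extract a core network.

## The co-detection model

For a data set $S$ with $n_s$ samples, let $p_i$ be the prevalence of genus
$i$ (the fraction of samples where it is detected; abundance is ignored).
Genera with prevalence below 10% are removed first. Under independence, the
expected number of samples detecting both members of a pair $(i, j)$ is

$$\mathrm{Exp}_{ij} = n_s \, p_i \, p_j,$$

and the deviation from the observed co-detection count $\mathrm{Obs}_{ij}$ is
$\mathrm{Dev}_{ij} = \mathrm{Exp}_{ij} - \mathrm{Obs}_{ij}$. Across all
$\binom{G}{2}$ retained pairs we take the mean $\mathrm{MDev}$ and sample
standard deviation $\mathrm{SDDev}$ of the deviations. Deviations within one
standard deviation of the mean are treated as noise (shared technical
factors — sequencing region, sample preparation — push many pairs mildly
off independence in the same direction). The signed edges are

* **positive** (co-detected more than expected):
  $\mathrm{Dev}_{ij} \le \mathrm{MDev} - k \cdot \mathrm{SDDev}$,
* **negative** (avoidance):
  $\mathrm{Dev}_{ij} \ge \mathrm{MDev} + k \cdot \mathrm{SDDev}$,

with $k = 1$ by default. Note the sign convention: a *negative* deviation
means *excess* co-detection, hence a positive connection. The deviation
itself is stored as the edge `intensity`; `weight = |intensity|` orders
edges during shearing.

Because only the detection pattern enters, the model is invariant to any
rescaling of abundances that preserves which entries are zero — there is no
compositional closure problem to undo.

### Parameter choices

| parameter | default | meaning |
|---|---|---|
| `min_prev` | 0.10 | prevalence filter; genera at exactly 10% are retained (the rule removes those *below* the threshold) |
| `detection_threshold` | 0 | a genus is detected when abundance is strictly greater than this |
| `k_sd` | 1 | half-width of the noise band in SD units |

`SDDev` uses the sample ($n-1$) standard deviation — the default of
mainstream statistics environments — computed over all retained pairs of
the data set, not per genus. Boundary deviations (exactly $k$ SD from the
mean) become edges, following the non-strict inequalities of the rule. When
$k \cdot \mathrm{SDDev} = 0$ the two thresholds coincide; we then require a
strict inequality so that no pair can be labelled both positive and
negative, and an all-equal deviation set yields no edges. Isolated genera
remain nodes (the stability benchmark counts them); `drop_isolates()`
removes them for display.

## Comparator networks

Three standard builders are included for benchmarking, all sharing the
prevalence filter and the `p < 0.05` retention rule, without multiple-testing
correction by default (a Benjamini–Hochberg flag exists but is off to match
the benchmark convention):

* **Pearson on clr**: abundances are centred-log-ratio transformed per
  sample first. Zeros are replaced by a pseudocount of 1 for count tables,
  or by half the smallest non-zero value (with re-closure) for relative
  abundances; both policies are exposed.
* **Spearman** on per-sample relative abundances, average ranks for ties.
* **SparCC**: basis correlations estimated from log-ratio variances
  $t_{ij} = \mathrm{var}\,\log(x_i/x_j)$ on Dirichlet-resampled fractions
  (+1 prior), basis variances solved from the sparsity-approximated linear
  system, strongly correlated pairs (|rho| > 0.1) iteratively excluded for
  up to 10 rounds, and the entrywise median taken over 20 inner resamples.
  Pseudo p-values permute every genus row independently and use the add-one
  convention $p = (1 + \#\{|\rho_b| \ge |\rho_{obs}|\})/(1 + B)$ with
  $B = 100$ bootstraps, so $p$ lives in $(0, 1]$ and the smallest attainable
  value is $1/101$. Negative basis-variance solutions (possible under the
  sparsity approximation) are floored at machine epsilon before the
  correlation is formed; a singular system after exclusions falls back to
  the no-exclusion estimate with a warning.

Correlation p-values use the two-sided t approximation. Pairs involving a
constant row are skipped with a warning rather than failing the build.

## Network attributes

Per-node centralities are unweighted — edge weights order shearing removals
but never enter path lengths:

* closeness: inverse mean shortest distance within the node's connected
  component (isolates score 0);
* betweenness: shortest-path transit counts over unordered pairs;
* eigenvector: Perron scores of the adjacency.

Each is *centralized* into a network-level score
$\sum_v (\max_u c_u - c_v)$ — zero on vertex-transitive graphs, large on
star-like ones. The printed formulas are raw sums; no theoretical-maximum
normalisation is applied (a normalised variant would only rescale the
trade-off curves the shearing stop rule consumes).

Eigenvector centrality on disconnected graphs needs a convention, and
ARPACK-style solvers are ambiguous exactly where shearing spends most of
its time: late trajectories fragment into several components whose spectral
radii tie (every isolated edge has $\lambda = 1$), and the dominant
eigenvector of the whole adjacency is then not unique. We therefore compute
a dense symmetric eigendecomposition per component, scale each component's
Perron vector to unit maximum within the component, and multiply by
$\lambda_c / \lambda_{\max}$. The globally dominant component peaks at
exactly 1, weaker components score proportionally less, isolated nodes score
0, and the result is deterministic on every input — which the shearing
trajectory requires.

The three attributes tracked by the stability benchmark are the node count
(isolates included), links per node (average degree $2E/N$; $E/N$ is
available behind a flag), and the P/N ratio (positive over negative edge
count). A network with no negative edges has an *undefined* P/N ratio,
recorded as `NA` and excluded pairwise from downstream t-tests — not
infinity, which would poison means.

## Network shearing

Shearing prunes a network to its core by repeatedly testing two candidate
removals — the least-weight edge and the biggest-weight edge, sign ignored —
and committing whichever leaves the *higher* centralized eigenvector score,
until a single edge remains. The procedure's decision step is stated in the
source description as comparing "the centrality in step 2" with "3"; read
literally that compares a centralization against the constant 3, which is
dimensionally implausible (the score scales with network order). We read it
as comparing the two candidate centralizations and keep the literal
constant-3 variant behind `literal_three = TRUE` for auditability.

Determinism is guaranteed by total tie-breaks: among equal-weight edges the
lexicographically first (by genus pair) is the candidate, and when the two
candidate scores tie (within `1e-12`, relative) the least-weight removal is
committed. Steps are 1-based: after step $t$ exactly $t$ edges have been
removed, and a trajectory from $E$ edges has $E - 1$ records.

The stopping step trades betweenness against closeness centralization along
the trajectory. No formal rule is given in the source description, so the
rule is pluggable and recorded in every output: the default
`normalized-product` min–max normalises both curves to $[0, 1]$ and takes
the step maximising their product (earliest on ties); `max-min` maximises
the smaller normalised value; `knee` returns the step before the largest
one-step drop in normalised closeness. A constant trade-off curve returns
step 1 with a warning. The network replayed up to the stop step is the core
network.

## Sample-size stability

The benchmark subsamples a pool without replacement at sizes
10, 30, 50, 80, 100, 200, 300, 500, 700, 800, 1,000, 1,200 (20 replicates
per size; sizes exceeding the pool are skipped with a warning, since real
cohorts can be smaller than the grid), rebuilds the network on every
subsample — the prevalence filter is re-applied *within* the subsample —
and records the three attributes. A replicate on which the builder fails is
recorded as an `NA` triple rather than aborting.

The *minimum stable sample size* for an attribute is the smallest grid size
whose values show no significant difference (two-sided pooled-variance
Student's t-test, $\alpha = 0.05$) from those at **every** larger size —
the stricter reading of "no further change when the sample size increases",
rather than only adjacent-size comparisons. The largest size is never a
candidate (its stability would be vacuous), so a strictly drifting
attribute returns `NA`, meaning "not stabilised by 1,200". When methods are
ranked by stability, `NA` is treated as worse than any finite size, and
ties count as "no later than". Welch's t-test is available behind a flag;
no multiple-testing correction is applied across the grid. A Shapiro–Wilk
normality screen is computed per (size, attribute) and reported alongside,
but never gates the t-tests — it is diagnostic output only.

## Synthetic data

Two generators cover the two statistical regimes the methods assume; both
are pure functions of their parameters and a seed.

* `simulate_presence()`: independent Bernoulli($p_i$) detections, plus
  disjoint planted pairs drawn per sample from the 2×2 joint table with
  $P(\text{both}) = p_i p_j + \delta$ and marginals preserved. Infeasible
  offsets (outside the Fréchet bounds) are rejected with an informative
  error. Pairs are restricted to disjoint genus sets so the ground truth is
  unambiguous.
* `simulate_compositional()`: per sample, basis log-abundances from a
  multivariate normal (mean, per-genus log-SD, correlation), exponentiated,
  closed to proportions, and multinomially sampled at a fixed depth of
  20,000 reads by default — a typical post-filter amplicon depth. The
  correlation matrix alone does not determine a covariance, so the basis
  log-SD is an explicit parameter (default 1, a realistic log-scale spread
  for genus abundances). Depth is fixed per sample by default.

`simulate_planted_pool()` combines the two for benchmarking: marginal
prevalences uniform in [0.3, 0.7], five planted co-detection pairs
($\delta = +0.15$) and five avoidance pairs ($\delta = -0.15$) among 50
genera. Prevalences of planted pairs are redrawn within the range until the
offset is feasible with a 0.01 margin inside the Fréchet bounds. With
`abundances = TRUE` the detection pattern is filled with log-normal values
(log-mean 3, log-SD 1) so correlation methods can run on the same pool;
the detection structure is identical either way.

### What the generators do and do not emulate

The presence generator reproduces exactly the independence null the
co-detection model tests against, plus localised dependencies of known
sign — so recovery tests measure the model's discriminative behaviour
directly. It does *not* emulate pervasive weak correlation structure,
age-dependent composition shifts, batch effects across studies, or depth
variation, all present in real surveys. Two consequences matter when
reading test results:

* With a fixed offset $\delta$, a planted pair's deviation grows like
  $\delta \, n$ while the null spread grows like $\sqrt{n}$, so the planted
  pairs increasingly dominate `SDDev` as $n$ grows. Precision of planted-pair
  recovery is therefore strongly sample-size dependent — near-perfect
  recall at all tested sizes, but high precision only once the band has
  been pushed several null SDs out (thousands of samples under the default
  pool). This is a property of the benchmark construction, not evidence
  about false-discovery behaviour on real data, where dependence is weaker
  and pervasive.
* The same mechanism makes the model's links-per-node *drift* with
  subsample size on planted pools (the band keeps moving relative to the
  null as $n$ grows), which can invert stability rankings relative to what
  the method shows on real survey data. Stability conclusions from these
  pools characterise the benchmark regime, not the method's field
  behaviour.

## Problem sizes in the test suite

The bundled tests run the full workflows at reduced but representative
scale, chosen so the whole suite exercises every code path on a laptop:
oracle equivalence on 100 random presence matrices (up to 20 genera × 300
samples), planted-pair recovery at $n$ = 100–1,000 over 20 seeds, SparCC
recovery at 22 genera × 500 samples × depth 20,000 over 20 seeds, shearing
contracts on 20 random weighted graphs, and the stability benchmark on
3,000-sample pools with 5 repetitions (script) or 10 (tests). The
acceptance script (`scripts/acceptance.R`) recomputes the headline
quantities from scratch at these sizes.

## Known limitations

* The co-detection model defines no per-edge p-value; the $k$-SD band is a
  global gate, and its calibration with pervasive dependence is untested
  here.
* SparCC parity is with the published algorithm's defaults, not bit-exact
  with any particular distribution of the tool.
* The shearing stop rule is a heuristic family; different rules can select
  very different cores on flat trade-off curves.
* Species/strain-level analysis, raw-read processing, rarefaction, and
  confounder analyses are out of scope; inputs are genus-level tables.
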
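---
title: "Feature alignment by generalized Wasserstein distance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature alignment by generalized Wasserstein distance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwalign)
```

## The problem

Liquid chromatography separates analytes in time before mass spectrometry
measures them, but the retention time (RT) at which an analyte elutes varies
from run to run — by seconds for stable systems, by minutes for long
nanoflow gradients. Before any label-free quantification can compare signals
across replicates, corresponding features (the connected regions of signal a
feature detector attributes to one analyte) must be put in correspondence:
RT alignment.

Most aligners warp the RT axis with a monotone function. Monotone warping
cannot, by construction, fix an *elution-order swap* — two analytes whose
relative order differs between runs — and swaps are not rare: independent
per-feature drift of realistic magnitude inverts a few percent of all
feature pairs. `gwalign` instead matches features directly, using the full
two-dimensional shape of each feature, so nothing constrains the
correspondence to be monotone.

## The dissimilarity measure

A detected feature is a finite set of peaks over the (RT, m/z) plane with
nonnegative intensities. After normalization each feature becomes a
unit-mass discrete measure, and two features $\mu$, $\nu$ are compared by an
unbalanced optimal-transport cost

$$
W(\mu, \nu) \;=\; \min_{T \ge 0,\; T_\mu \le \mu,\; T_\nu \le \nu}
\; \sum_{x, y} T(x, y)\, d(x, y)
\;+\; \lambda\,\bigl(\lVert\mu\rVert - \lVert T_\mu\rVert\bigr)
\;+\; \lambda\,\bigl(\lVert\nu\rVert - \lVert T_\nu\rVert\bigr),
$$

where $T(x,y)$ is the mass moved from support point $x$ of $\mu$ to $y$ of
$\nu$, $T_\mu, T_\nu$ are the plan's marginals, and
$d(x,y) = |\Delta \mathrm{rt}| + |\Delta m/z|$ is the Manhattan ground
distance in scaled coordinates. The marginal penalty is the total-variation
divergence: any unit of mass may stay behind at cost $\lambda$ per side.
Three consequences shape everything downstream:

* the distance between unit measures saturates at $2\lambda$ (destroy one,
  create the other), so $\lambda$ is the radius beyond which differences no
  longer matter — noise peaks and unmatched isotopologues cost at most their
  mass times $\lambda$;
* for two single-point features the distance is exactly
  $\min(d, 2\lambda)$;
* the cost of a rigid RT shift is the shift itself (per unit mass), so for
  well-behaved pairs the distance reads as "drift plus shape difference".

### Why the two-dimensional shape matters

A subtle and, in our view, instructive point: a difference in *elution
width alone* does not disambiguate a swap. In one dimension, transporting a
wide profile onto a narrow one that is far away costs exactly the centroid
shift whenever the quantile map moves all mass in one direction — the
reshaping rides along the shift for free. The information that actually
breaks swap ties lives in the dimension *orthogonal* to the drift: the
isotopic-envelope shape over m/z. Two analytes with distinct envelopes keep
a positive crossed-pairing penalty no matter how the RT axis drifts. This
is why the package's swap fixture (`make_swap_scenario()`) gives its two
features distinct, symmetric envelope weights: symmetric so that their m/z
centroids coincide and any point-reduction of the features is provably
ambiguous (equal crossed sums), distinct so that transport is not.

### Solvers

Two solvers compute $W$:

* `exact_gwd()` — the reference. The problem is a balanced transportation
  problem after a virtual trash point is appended to each side ($\lambda$
  from everything, 0 between trash points); it is solved exactly as a
  minimum-cost flow by successive shortest paths with Dijkstra and node
  potentials (compiled code). Intended for modest supports; cost is
  quadratic in support size and augmentation count.
* `sinkhorn_gwd()` — the workhorse. Entropic regularization of strength
  $\varepsilon$ turns the problem into diagonal scaling; the
  total-variation penalty makes each scaling step a clamp of the dual
  potential at $\lambda$. All iterations run in the log domain, so small
  $\varepsilon$ is numerically safe. Convergence is declared when the
  largest change of either plan marginal between successive
  iterations falls below `tol`; because the row update enforces its
  marginal identically, the violation is measured *after* the subsequent
  column update — the gap between the row marginal and its proximal target
  is exactly the joint-fixed-point residual. The reported cost is the
  transport part evaluated on the resulting plan, with the entropy term
  excluded and no further debiasing.

Defaults: $\varepsilon = \lambda/100$, `tol` $= 10^{-6}$ (mass units),
`max_iter` $= 5000$. On random measures with up to 10 support points this
keeps the regularized cost within 2 % of the exact optimum (the test suite
sweeps 200 such pairs against the exact solver); error decreases
monotonically as $\varepsilon$ shrinks. Supports above `max_support`
(default 500 points) are first reduced by intensity-weighted binning on a
(RT, m/z) grid, since memory is quadratic in support size.

## Preprocessing

RT spans hundreds to thousands of seconds while m/z features span a few Da,
so RT is divided by a factor
$k \cdot \overline{\text{RT span}} / \overline{\text{m/z span}}$ (spans are
per-feature max − min over peaks; $k$ = `rt_scale_k`, default 1). After
scaling, the Manhattan metric weighs the two axes comparably. Features with
zero span in a dimension are excluded from that average (a single-peak
feature would zero the denominator) but are still scaled and alignable; if
every feature has zero m/z span the factor cannot be estimated and an
explicit one must be supplied. Centroids are intensity-weighted means —
robust to asymmetric envelopes, and commuting exactly with the scaling.

Features are normalized to unit mass. Preserving relative total
intensities between features was the open alternative; unit mass was chosen
because the $\lambda$-penalty is then commensurable across features — an
abundant and a faint feature pay the same price per *fraction* of unmatched
signal, which is what a dissimilarity between analytes should measure.

## Matching

With more than two chromatograms, scaled centroids of all features are
first clustered into consensus candidates: a seeded k-means stage with
$k = \lceil \text{features}/\text{chromatograms} \rceil \times$
`overcluster` (default 2), then an average-linkage agglomerative merge of
the k-means centers cut at `cluster_cut`. Overclustering followed by
merging is deliberate: k-means fixes the granularity cheaply, the merge
repairs its splits. When the requested $k$ reaches the number of distinct
positions the stage degenerates gracefully to "every position its own
cluster". The k-means stage is the pipeline's only randomized step; its
seed is part of the configuration, making runs reproducible end to end.

`cluster_cut` defaults to $\lambda/4$. The cut must cover the centroid
scatter of one analyte across runs (drift-sized) yet stay below typical
inter-analyte spacing; a cut on the order of $\lambda$ or larger fuses
neighbouring analytes into one candidate, and since each candidate can
accept at most one feature per chromatogram per matching iteration, every
fused analyte beyond the first is silently trashed. A quarter of the trash
radius proved a serviceable middle ground at realistic feature densities;
both constants are exposed in `run_config()`.

Each chromatogram then serves once, in input order, as the target side
$L$ of a flow network against the pooled features $R$ of all others:
source $\to L_i$ (capacity 1); $L_i \to R_j$ (capacity 1, cost = GWD) for
every cached candidate pair; $R_j \to C_k$, its cluster (capacity 1);
$C_k \to$ sink (capacity 1) — one feature per chromatogram per candidate;
and $L_i \to Tr \to$ sink, the trash path that lets any feature stay
unmatched at cost $c$. We wire the trash with per-feature edges of cost
$c$ and a $Tr\to$ sink capacity of $n$ rather than giving the trash
source/sink edges capacities $\max\{0, s-n\}$ / $\max\{0, n-s\}$: the
latter extinguishes the opt-out exactly when clusters outnumber features,
while the opt-out must be available to *every* feature whose best match
costs more than $c$. The minimum-cost maximum flow (value $n$, always
feasible) is computed by the same successive-shortest-path solver; unit
flows $L_i \to R_j \to C_k$ decode into (feature, cluster) matches.
Consensus features collect, per cluster, everything matched to it across
iterations; singletons are dropped unless `keep_singletons`.

With exactly two chromatograms the cluster layer is unnecessary and
matching degenerates to an optimal partial assignment with opt-out
(`match_two()`); the test suite checks it against exhaustive enumeration on
all instances up to 5×5.

Numerical choices: network costs are made integral by multiplying by
`int_scale` ($10^4$, i.e. four decimals of GWD survive) and rounding — the
flow solver's optimality argument wants integral costs; remaining ties are
broken by node index, which makes results deterministic for a fixed input
order but is a documented source of (bounded) order sensitivity. The trash
cost defaults to $c = 1.9\lambda$, just under the $2\lambda$ saturation: a
feature is trashed only when no candidate is meaningfully better than "no
match". The candidate window of the pairwise cache defaults to $2\lambda$
in centroid distance for the same reason — a farther pair cannot beat the
trash option, so its cache entry is simply absent.

## Evaluation

`alignment_precision_recall()` formalizes the per-ground-truth-set
precision/recall used by alignment benchmarks: for each ground-truth set
$G$ the best-intersecting tool consensus $t^\*$ is found (ties: larger
intersection, then smaller $|t^\*|$, then lexicographic id);
$R(G) = |t^\* \cap G|/|G|$, $P(G) = |t^\* \cap G|/|t^\*|$, averaged
arithmetically; `f_score()` is their harmonic mean. The definitions imply
(and the suite asserts on randomized cases) that splitting a tool
consensus cannot raise recall and merging two cannot raise precision.
`identification_recall()` scores, over a chromatogram subset, the fraction
of identification labels repeating in ≥ 2 runs whose annotated features
land in a single consensus. `swap_fraction()` counts order inversions
between two runs over all pairs of true correspondences (ties are not
swaps), and `swap_resolution_rate()` reports the fraction of swapped pairs
whose both correspondences the aligner recovered.

## The synthetic generator

`generate_chromatogram()` emulates what an upstream feature detector hands
to an aligner: per feature, peaks on an m/z grid spaced $1/z$ (geometric
envelope, decay 0.7 over 4 isotopologues by default) times a Gaussian
elution profile ($\sigma = 8$ s, sampled every 2 s over $\pm 2\sigma$),
with monoisotopic m/z uniform in 300–1500 Da, apex uniform in 100–1900 s,
charge 1–3, and log-normal abundance. These defaults sketch a typical
nanoflow proteomics run at desk scale. `simulate_drift()` shifts each
feature rigidly and independently by uniform draws within $(\pm 150$ s,
$\pm 0.3$ Da$)$ — the drift regime in which a few percent of all feature
pairs swap order.

What the generator does *not* emulate — chemically accurate isotope
abundances, peak tailing, co-eluting interference, detector noise,
split/merged detections — bounds what passing tests show: they validate
the matching machinery under clean features with known truth, not
performance on real chromatograms, where feature-detection quality
dominates.

Problem sizes used by the validation suite and the acceptance script were
chosen to exercise every code path at desk scale: 200 features for the
two-run drift experiment (about a thousand candidate pairs and, at these
densities, roughly 5 % of pairs swapped), 100 features × 3 replicates for
the clustered multi-run path, 200 random measure pairs for the
solver-equivalence sweep, exhaustive enumeration up to 5×5 for matching
optimality.

## Known limitations

* A corresponding pair whose drift approaches $2\lambda$ in scaled
  coordinates is indistinguishable from "no match"; $\lambda$ must be set
  generously above the expected drift, at the price of a wider candidate
  window.
* Dense chromatograms can place a foreign feature closer than the true
  partner; transport then favours the camouflage. More information (e.g.
  MS/MS identity) would be needed, and the evaluation module is built to
  quantify exactly this failure mode.
* The featureXML reader apportions a feature's total intensity uniformly
  over its convex-hull points (hull points carry no intensity of their
  own); per-peak mass-trace intensities, where present, would be the
  richer alternative.
* Input order has a small residual effect through integer-cost ties and
  the iteration order of matching; the suite bounds it (≥ 90 % of
  memberships stable under permutation) rather than eliminating it.
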
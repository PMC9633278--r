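# gwalign — LC-MS retention-time alignment by optimal transport

`gwalign` aligns liquid chromatography–mass spectrometry (LC-MS) runs by
**matching detected features** across chromatograms rather than warping the
retention-time axis. Warping assumes analytes elute in the same order in
every run; real retention-time drift breaks that assumption for a few
percent of all feature pairs (*elution-order swaps*), which monotone
methods cannot repair by construction. `gwalign` is for proteomics and
metabolomics workflows that need feature correspondence — label-free
quantification, biomarker screening across conditions — without a
reference run and without prior identification.

## The method

A detected feature is a set of peaks over the (RT, m/z) plane. After
normalization to unit mass and RT scaling, two features μ, ν are compared
by a **generalized (unbalanced) Wasserstein distance**

W(μ, ν) = min over plans T ≥ 0, T_μ ≤ μ, T_ν ≤ ν of
&nbsp;&nbsp;&nbsp;&nbsp;Σ<sub>x,y</sub> T(x,y)·d(x,y) + λ·(‖μ‖ − ‖T_μ‖) + λ·(‖ν‖ − ‖T_ν‖),

with Manhattan ground distance d and a per-unit penalty λ for mass left
untransported, so the distance saturates at 2λ and noise becomes
ignorable. It is computed exactly (minimum-cost flow; reference solver)
or fast by a log-domain Sinkhorn–Knopp scaling algorithm (entropic
regularization ε, the default workhorse).

Correspondence is then a global optimization: feature centroids are
clustered into consensus candidates (k-means + agglomerative merge), and
each chromatogram in turn is matched against the pool of all others by a
**minimum-cost maximum flow** on a network whose edges carry the pairwise
distances, with a per-feature *trash* option (cost c) that leaves a
feature unmatched when nothing beats "no match". The result is a list of
consensus features — sets of corresponding features, at most one per
chromatogram. Because nothing forces monotonicity, swapped features are
matched by their two-dimensional shape: the isotopic-envelope differences
in m/z stay informative no matter how RT drifts.

The package also ships the evaluation toolkit used by alignment
benchmarks (alignment precision/recall per ground-truth consensus,
F-score, identification recall, swap statistics) and a synthetic
chromatogram/drift generator with known ground truth. See the methods
vignette (`vignettes/alignment-methods.Rmd`) for assumptions, parameter
guidance and design rationale.

## Worked example

Simulate a run of 50 features, apply heavy per-feature drift (±150 s RT,
±0.3 Da m/z — enough to swap ~7 % of feature pairs), align the two runs,
and score the result against the known truth:

```r
library(gwalign)

gen <- generate_chromatogram(generator_params(n_features = 50, seed = 1), "run_a")
dr  <- simulate_drift(gen$features, drift_params(rt_range = 150, mz_range = 0.3,
                                                 seed = 2), "run_b")
sf <- swap_fraction(dr$pairing)
sprintf("swapped pairs: %d of %d (%.1f%%)",
        attr(sf, "n_swapped"), attr(sf, "n_pairs"), 100 * as.numeric(sf))
#> "swapped pairs: 85 of 1225 (6.9%)"

aln <- align(list(gen$features, dr$drifted), run_config())
aln
#> <gw_alignment> 50 consensus features from 2 chromatograms (RT factor 17.297)

srr <- swap_resolution_rate(dr$pairing, aln$consensus, "run_a", "run_b")
sprintf("resolved %.0f%% of swapped pairs", 100 * as.numeric(srr))
#> "resolved 100% of swapped pairs"

gt <- ground_truth(lapply(gen$catalog$feature_id, function(f)
  data.frame(source_id = c("run_a", "run_b"), feature_id = f)))
pr <- alignment_precision_recall(gt, aln$consensus)
sprintf("P = %.2f  R = %.2f  F = %.2f",
        pr$precision, pr$recall, f_score(pr$precision, pr$recall))
#> "P = 1.00  R = 1.00  F = 1.00"
```

Every true pair was recovered, including all 85 swapped ones; precision
and recall of 1.00 mean each ground-truth pair was reproduced exactly,
with no admixture and no losses. The reported RT factor (17.3 s per
m/z-equivalent unit) is the scaling that makes the two axes commensurable;
with it, the default trash distance λ = 10 comfortably covers ±150 s of
drift. A `Sinkhorn reached max_iter` warning, when it appears, flags
candidate pairs whose iteration hit the cap before the 10⁻⁶ marginal
tolerance — their costs are still accurate to well under a percent.

The same pipeline is scriptable from a shell:

```sh
exec/gwalign simulate --out-dir sim --n 50 --seed 1
exec/gwalign align --out consensus.tsv --report report.json sim/run_a.tsv sim/run_b.tsv
exec/gwalign evaluate --consensus consensus.tsv --ground-truth gt.tsv
exec/gwalign gwd sim/run_a.tsv F0001 sim/run_b.tsv F0001
```

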
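---
title: "Quantifying immune-epithelial crosstalk: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying immune-epithelial crosstalk: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimm)
```

`epimm` packages four statistics for studying how immune (IMM) cells and the
epithelium (EPI) intermingle in chronically inflamed nasal tissue — chronic
rhinosinusitis with and without nasal polyps being the motivating disease —
together with seeded simulators that provide ground truth for every stage.
This vignette explains each method, its assumptions, the tunable parameters,
and the design choices made where the procedure was genuinely open.

## The spatial proximity graph and OR*

Cells segmented from a region of interest (ROI) are reduced to points with
type labels. Adjacency is the Delaunay triangulation of the cell centroids,
pruned to edges of Euclidean length at most `max_edge_len` (default 50 μm,
inclusive), so an edge asserts "these two cells are near neighbours and
within 50 μm". The triangulation itself is delegated to `deldir`; pruning,
classification and all statistics are computed here.

With `nA` epithelial and `nB` immune cells, the possible pair counts are
`N_AB = nA·nB`, `N_AA = nA(nA−1)/2`, `N_BB = nB(nB−1)/2`, and for observed
edge counts `e` the interaction odds are `Odds = e / (N − e)`. The geometric
odds ratio

`OR* = Odds_AB / sqrt(Odds_AA · Odds_BB)`

compares across-type contact against the geometric mean of within-type
contact. Values near 1 mean the two compartments interleave as much as they
self-associate; values near 0 mean segregation. Two properties are worth
keeping in mind:

* the denominators are *all possible pairs*, not geometrically realizable
  edges, so OR* is coupled to ROI size (a planar graph has O(n) edges while
  N grows like n²). This is deliberate: the definition uses all possible
  pairs, and the implementation follows it exactly rather than substituting
  realizable edges. Comparisons should therefore be made between ROIs of similar
  cell counts, or against the permutation null, which holds the graph and
  the label counts fixed.
* OR* is symmetric in the two labels, and `classify_edges` ignores edges
  touching any third compartment (e.g. myeloid cells), so a two-label
  analysis is unaffected by the presence of other cell types.

**Degeneracy policy.** Whenever any count is 0 or saturated (or a
denominator is 0 — a one-cell compartment), all three odds switch to the
Haldane-Anscombe form `(e + 0.5)/(N − e + 0.5)` and the result is flagged
`corrected`. Correcting all three, rather than only the offending one,
preserves the label symmetry. The uncorrected values (possibly `0`, `Inf`
or `NaN`) are retained alongside.

**Numerical choices.** The length cutoff is inclusive so integer fixtures
behave identically under exact arithmetic. Exact duplicate coordinates are
jittered by 1 μm × 10⁻⁶ under a seed derived from the ROI id (recorded on
the graph object); ROIs with fewer than three cells or with all cells
collinear fall back to the complete graph pruned at the same cutoff so that
downstream counts stay defined. Graphs are strictly per-ROI; no edges cross
ROI boundaries, and pooling across an individual's ROIs (`pool_edge_counts`)
therefore sums the per-ROI possible-pair denominators rather than
recomputing them from summed cell counts.

**Permutation null.** `permutation_null` permutes the label vector over the
fixed graph, recomputing OR* with the same correction policy, and reports
the add-one empirical p-value `(1 + #{OR*perm ≥ OR*obs}) / (1 + n_perm)`,
which cannot be zero. Each ROI draws from a stream keyed by `(seed, roi_id)`
so results are reproducible and ROIs independent. Note the convention is
one-sided toward *mixing*: a segregated ROI gets p = 1, not p ≈ 0.

## Ligand-receptor weighted co-expression

For each ROI `j` and panel pair `i`, the score is
`P_ij = L_ij · R_ij / OR*_j` — ligand expression in the EPI region times
receptor expression in the matched IMM region, divided by the ROI's
geometric odds ratio — and the ROI summary is the geometric mean
`(∏ P_ij)^(1/n)` over the `n` pairs actually usable in that ROI. The
default panel ships with the package: CCL26–CCR3, CCL20–CCR6, TSLP–IL7R,
IL33–IL1RL1, four axes of epithelial recruitment of immune cells.

Choices and caveats:

* the corrected OR* is always used when correction was triggered, because
  `P` is undefined at OR* = 0;
* a zero ligand or receptor value propagates to a zero score (geometric-mean
  semantics); a `floor` argument adds an ε to every `L` and `R` for callers
  who want strictly positive scores (default 0);
* missing panel genes cause the pair to be skipped with a recorded reason
  and `n` adjusted, rather than failing the ROI;
* dividing by OR* *down-weights* spatially well-mixed ROIs. On simulated
  data where ligand expression is coupled to mixedness
  (`analysis/03_lr_scores.R`) the score actually decreases with mixedness,
  because OR* in the denominator grows faster than the expression signal.
  The formula is implemented exactly as defined; this interpretive tension
  is documented rather than resolved.
* "expression in EPI" means the region-aggregate value for ROI-level
  matrices (the native resolution of mask-based spatial profiling); if
  cell-level matrices are aggregated upstream, the mean over cells of the
  named type within the ROI is the intended summary.

## Signature scoring and marker selection

`module_score` re-implements the binned-control score used throughout
single-cell work: genes are placed into `n_bins` (default 24)
equal-frequency bins by average expression, each signature gene draws
`n_ctrl` (default 100) control genes with replacement from its own bin, and
a unit's score is mean(signature) − mean(pooled controls). The score is
shift-invariant and zero on constant input; bin count, control count and
seed are recorded in the result because the upstream tool exposes them only
implicitly. Sampling order (one block of draws per signature gene, in panel
order, from a single seeded stream) is part of the function's contract and
is what the test-suite oracle replays.

`ssgsea_score` computes the single-sample rank-enrichment statistic: per
unit, genes are ranked (ties averaged) and walked from highest to lowest
expression; the running sum adds the `rank^alpha`-weighted in-set fraction
and subtracts the uniform out-of-set fraction, and the score is the sum
over all positions (`alpha` default 0.25; `alpha = 0` gives the unweighted
Kolmogorov-Smirnov-style sum). Only ranks matter, so any strictly monotone
per-unit transform leaves scores unchanged — which also means it is safe on
arbitrarily normalized region profiles.

`rank_de_test` is the marker-style differential test: genes are
pre-filtered to `|log_fc| > 0.25` (difference of group means of
log-normalized values, natural-log scale) and detection in more than 25% of
units in at least one group, then tested with the two-sided Wilcoxon
rank-sum test; correction (Bonferroni by default, BH optionally) spans the
*tested* genes only, matching how marker selection is done in practice.
This Wilcoxon engine is also used for the continuum DE below — the package
deliberately uses a single DE method rather than shipping a hurdle-model
engine, since the procedures around the DE, not the DE engine, are what it
implements.

`region_score_correlation` pairs two score vectors by ROI (optionally
through an explicit EPI-ROI → IMM-ROI mapping) and reports tie-corrected
Spearman rho, with an exact enumeration p-value below n = 10 and the t
approximation from n = 10 on.

## The basal transition continuum

The continuum summarizes how basal-cell transcriptomes deform across
disease states as a single coordinate:

1. **Gene selection** (`select_continuum_genes`): samples with ≤ 50 basal
   cells are dropped (the inclusion rule is strictly "more than 50"); per
   sample, DE p-values vs the control reference are BH-adjusted, and a gene
   is kept iff `p_adj ≤ 0.05` and `|log2FC| ≥ 0.5` in at least two
   surviving samples. BH is used *here*, while marker selection elsewhere
   defaults to Bonferroni, following the convention standard to each
   procedure.
2. **Fit** (`fit_continuum`): per-sample pseudobulk profiles over the
   selected genes are z-scored per gene, PCA is run on samples, and a loess
   spline (degree 2, tricube weights, span default 0.75) of PC2 on PC1 is
   evaluated on a 200-point grid. The resulting polyline's cumulative arc
   length is the continuum coordinate; samples and external profiles map to
   the arc length of their nearest vertex (ties to the lower arc length),
   with the off-curve distance reported as `residual_distance`.
3. **Projection** (`place_on_continuum`): external profiles (e.g. spatial
   EPI region transcriptomes) are standardized with the *training* means
   and standard deviations, projected through the training loadings, and
   placed on the polyline. Model genes missing from the input are imputed
   at the training mean (z = 0) with the imputed fraction recorded; below
   50% overlap the projection refuses.
4. **Trends** (`fraction_trend`): per immune population, Spearman rho of
   its per-sample fraction against the normalized coordinate, plus a
   loess-smoothed curve on a 50-point grid; constant fractions are defined
   as rho = 0, p = 1.

Open design points, decided as follows. PCA is computed over *samples*
(pseudobulk = per-sample mean of log-normalized basal-cell expression),
not over cells; cell-level PCA is a plausible alternative, but the
continuum is read against per-sample immune fractions, so the sample is
the natural unit. The construction specifies only "a spline through
(PC1, PC2)"; the scalar coordinate along it is this package's choice, and
nearest-vertex arc length is the minimal faithful reading. Its resolution
is one grid step, which is why the self-consistency guarantee is "training
coordinates reproduce within one grid step". Projection of external
profiles has no canonical recipe either; training-standardization plus
training loadings is the documented choice. Finally,
PCA sign ambiguity is pinned by requiring the lexicographically smallest
training sample id to land in the lower half of the coordinate — with a
control-like reference named first (e.g. `S01`), coordinates read
control → disease.

Degenerate inputs: zero-variance genes are dropped with a warning before
standardization; fewer than 4 samples, or a constant PC1, are errors. If
loess cannot fit (very few samples), a quadratic least-squares curve on the
same axis is substituted.

## What the simulators emulate — and what they do not

`simulate_spatial_roi` places two cell types on a square field with a
single mixing parameter λ: each cell comes from its own-type Gaussian
cluster with probability 1 − λ and from the uniform field otherwise. At
λ = 0 cluster centres are at least `4·cluster_sd + 50` μm apart, so
across-type edges are rare (Gaussian tails still allow occasional
contact); at λ = 1 labels are spatially random. Mixing-by-contamination was
chosen over a Gibbs interaction model because it is simple, monotone in λ,
and sufficient to validate OR*: median OR* rises strictly across
λ ∈ {0, 0.25, 0.5, 0.75, 1} in the acceptance suite (50 replicates of
100+100 cells per level).

`simulate_roi_expression` couples region expression to the realized
geometry: ligand (EPI) and receptor (IMM) values follow
`base · exp(κ · mixedness + noise)` with `mixedness = eAB/N_AB` from the
ROI's own graph and log-normal noise (sd 0.1). Because `mixedness` scales
like 1/n (planar graphs have O(n) edges against n² possible pairs), the
coupling is only detectable on small dense ROIs; the packaged analyses use
10+10 cells on a 120 μm field, where the κ = 2 signal spans roughly
0–0.5 on the log scale against noise sd 0.1.

`simulate_continuum_cohort` assigns samples evenly spaced latent positions
t on [0, 1] and shifts two opposing gene modules by ±`effect_size · t` on
the log-mean scale; counts are negative binomial parameterized by
(mean, dispersion) with variance `mu + mu²/dispersion` (dispersion default
10 — moderate single-cell-like overdispersion), per-gene baseline means
drawn log-uniform on 1–20 counts, and a designated immune population's
fraction follows `0.1 + 0.5·t + N(0, 0.02)` truncated to [0, 1]. One
realistic artefact emerges for free: because module shifts change cell
totals, CPM normalization induces compositional fold changes in *non*-module
genes, so the continuum DE legitimately selects more genes than the 30
module members — the recovered coordinate is what matters, not the gene
list.

The simulators deliberately do **not** emulate probe-level noise of the
spatial platform, segmentation error, batch structure, doublets, or
zero-inflation beyond the negative binomial. Passing tests therefore show
that the statistics recover the constructs they define under a clean
generative model, not that they are robust to every artefact of real
tissue data.

## Problem sizes and reproducibility

All randomness flows through explicit integer seeds; per-ROI streams are
derived from `(seed, roi_id)` via a 31-bit string hash so ROIs are
independent and results bit-reproducible. The test and acceptance
workloads were sized for quick desk-scale runs: the permutation-null
calibration uses one 200-cell ROI with 2000 permutations; the mixing sweep
uses 50 replicates per λ level; the continuum recovery uses 20 samples of
200 cells over 100 genes (two 15-gene modules, effect 1.5), where the
recovered coordinate's Spearman correlation with the latent axis and the
negative control (effect 0, which correctly fails gene selection) are both
checked by `tests/testthat/test-acceptance.R` and recomputed by
`scripts/acceptance.R`.

## Known limitations

* OR* depends on ROI size through its all-pairs denominators; compare like
  with like, or use the permutation null.
* The L-R score inherits the inverse OR* weighting discussed above.
* Gene identifiers are matched by exact, case-sensitive string equality;
  no alias resolution is attempted.
* The shipped signature GMT is illustrative only; real analyses must supply
  curated signatures.
* The continuum assumes the dominant axis of pseudobulk variation is the
  disease axis; strong batch or cohort structure would need correcting
  before fitting.
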
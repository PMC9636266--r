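---
title: "How proportional thresholding shapes EEG connectivity graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How proportional thresholding shapes EEG connectivity graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connsweep)
```

## The problem

Graph analyses of EEG functional connectivity almost always begin by
deleting "weak" edges: a proportional threshold keeps the top $(1-q)$
fraction of edge weights and discards the rest. The level $q$ is an
analyst's choice with no agreed default, yet every global network measure
computed afterwards — path length, clustering, participation,
small-worldness — depends on it. `connsweep` makes that dependence an
object of study. It estimates spectral phase-synchronization networks from
multichannel oscillatory recordings, sweeps the full threshold grid
$q = 0.01, 0.02, \dots, 0.99$, computes the global measures and their
statistics at every level, contrasts the thresholded graphs with a
data-driven alternative (orthogonal minimum spanning trees), and quantifies
how much a study's conclusion — including the presence, size and sign of a
group difference — depends on where the knife falls.

Because resting-state EEG cohorts are rarely redistributable, the package
ships a synthetic-cohort generator with planted, analytically known
coupling structure. Every pipeline claim is validated against that
generator and against independent oracles (exhaustive enumeration, direct
summation, closed forms).

## Synchronization measures

All five measures are functionals of epoch-wise Hann-windowed
cross-spectra $S_{xy}(f) = X_x(f)\overline{X_y(f)}$, averaged over the
bins whose centre frequency lies in the analysis band (default alpha,
8–13 Hz; frequency resolution is `sfreq / epoch_length`):

* **wPLI** $= |E[\mathrm{Im}\,S_{xy}]| \,/\, E[|\mathrm{Im}\,S_{xy}|]$ — a
  zero denominator (identical or purely zero-lag signals) is defined as 0.
* **ImCoh** $= \mathrm{Im}\!\left(E[S_{xy}] / \sqrt{E[S_{xx}]E[S_{yy}]}\right)$.
* **Coherence** $= |E[S_{xy}]| / \sqrt{E[S_{xx}]E[S_{yy}]}$.
* **ciPLV** $= \mathrm{Im}(\mathrm{PLV}) / \sqrt{1-\mathrm{Re}(\mathrm{PLV})^2}$
  with $\mathrm{PLV} = E[e^{i\Delta\phi}]$; $|\mathrm{Re}| = 1$ is defined
  as 0.
* **PPC** $= \frac{2}{n(n-1)}\sum_{j<k}\cos(\Delta\phi_j - \Delta\phi_k)$,
  the unbiased analogue of the squared PLV.

Analytic limits anchor the implementation: a noiseless constant-lag pair
gives wPLI = ciPLV = PPC = coherence = 1 and $|\mathrm{ImCoh}| =
\sin(\text{lag})$ at the carrier bin; a zero-lag mixture drives wPLI,
ImCoh and ciPLV to 0 while coherence persists. These are asserted to
1e-6 in the test suite.

Two numerical details matter. First, R's complex multiplication uses fused
multiply-adds, so $\mathrm{Im}(X\overline{X})$ is ~1e-14 rather than
exactly 0 for identical signals; the wPLI and ciPLV degenerate-case guards
therefore test against a *relative* tolerance (1e-12 of the cross-spectral
magnitude), not exact zero. Second, ImCoh's analytic limit is approached
only up to negative-frequency spectral leakage; 4-s epochs (1024 samples at
256 Hz) put that leakage below 1e-6 for an alpha carrier.

**Rectification.** ImCoh and ciPLV are signed and PPC can be negative, but
quantile thresholding and spanning trees need an unsigned strength
ordering. The defaults are $|\mathrm{ImCoh}|$, $|\mathrm{ciPLV}|$, and PPC
clipped at 0; a `rectify` switch (`abs` / `clip` / `raw`) exposes the
alternatives, since reports in this literature rarely state which
convention was used.

## Thresholding rules

`quantile_threshold()` takes the $q$-quantile of the *off-diagonal
upper-triangle* weights (the structurally zero diagonal would distort the
distribution), using linear interpolation between order statistics
(`stats::quantile` type 7; a nearest-order-statistic mode is available).
Edges **strictly below** the threshold are deleted — ties at the threshold
survive, so an all-equal matrix is never pruned. Isolated nodes are then
removed and recorded; if the survivor is disconnected, only the biggest
component is kept (size ties are broken toward the component containing
the lexicographically smallest label, for determinism). Thresholds are
per-matrix: proportional thresholding is subject-wise by construction.

Two density columns are reported per graph: `density_pre` (edges surviving
the threshold, before node pruning) and `density` (edges of the final
retained graph), both over the original $\binom{N}{2}$ so values are
comparable across subjects. For all-distinct weights `density_pre`
$\approx 1-q$; with an interpolated quantile the kept count can differ
from $\mathrm{round}((1-q)E)$ by one edge at some $(q, E)$, so the law is
asserted to one-edge rounding.

## Global graph measures

* **Characteristic path length** is the *median* hop count over all node
  pairs (the robust convention for sparse pruned graphs); the classical
  mean is available via `agg = "mean"`.
* **Clustering coefficient** is the mean binary local clustering, with
  degree-<2 nodes contributing 0; a weighted (Barrat) variant sits behind
  a flag.
* **Participation coefficient** is $1 - \sum_m (k_{im}/k_i)^2$ averaged
  over nodes, against a modularity-maximizing partition from greedy
  agglomeration (`detect_communities()`; ties in peak modularity are broken
  toward the coarsest partition so a complete graph is one module). The
  community-detection method is a documented stand-in: studies using the
  participation coefficient rarely report how modules were obtained.
* **Small-world index** is the sigma form
  $(C/\langle C_{rand}\rangle)/(L/\langle L_{rand}\rangle)$ with
  degree-preserving double-edge-swap references (disconnected rewires are
  resampled, with a retry budget); 20 references by default, 10 inside
  full-grid sweeps — at 99 levels × 20 subjects the null ensemble is the
  dominant cost and 10 references already give the index a Monte-Carlo SE
  well below the effects under study. Reference seeds are derived per
  (subject, level) from the sweep's master seed.

All metrics are computed on the retained (post-pruning) graph. Metric
preconditions that fail at extreme thresholds (e.g. a 3-node survivor for
the small-world index) yield `NA` with a summarised warning rather than
aborting the sweep.

## OMST extraction

The data-driven alternative repeatedly extracts maximum-synchronization
spanning trees (Kruskal on distances $1/w$; $1-w$ behind a flag;
lexicographic tie-breaks), zeroing each tree's edges so successive trees
are edge-disjoint. After $m$ rounds the union network has wiring cost
$\mathrm{cost}(m)$ (captured weight over total weight) and global
efficiency $GE(m)$ (weighted, normalized by the full graph's efficiency so
it lies in $[0,1]$ — the normalization makes $J = GE - \mathrm{cost}$
dimensionless; the original formulation leaves this detail unspecified).
The selected network maximizes $J$; extraction continues 3 rounds past the
running maximum (J is not guaranteed unimodal; bounded lookahead keeps the
procedure deterministic) or until the residual disconnects.
`match_density_threshold()` then builds the proportional-threshold graph
whose pre-pruning density is nearest the OMST union's, enabling a paired,
density-matched comparison.

## Statistics

The statistical layer mirrors the analyses such a threshold study reports:
pooled OLS of each metric on graph density (slope, adjusted $R^2$,
coefficient p-values); subject-wise Spearman correlations between all
threshold pairs (midranks; undefined under constant vectors, recorded as
missing; significance displayed at p < 0.05); and permutation t-tests with
pooled-SD Cohen's d. The permutation engine enumerates all splits exactly
when there are at most 20 000 (sign-flips for the paired test), and
otherwise uses seeded Monte-Carlo with the add-one correction. Welch's t
is the test statistic, since group sizes are rarely balanced.
`group_effect_profile()` runs the two-sample test at every threshold and
flags contiguous significant runs and sign changes of d between runs — the
configuration in which the threshold choice flips a conclusion. No
multiple-testing correction is applied across thresholds by default (the
profile is descriptive, of the kind the underlying analyses report);
`p.adjust` can be applied to the returned p-value column when inference
over the profile is intended.

One convention deserves a note: in reports of this kind the regression
column labelled as a "density" coefficient is typically the *threshold
level*, so its signs are mirror images of slopes on graph density. On the
density scale used here, path length falls with density while clustering,
participation and the small-world index rise with it — equivalently, CPL
increases and the other three decrease as thresholding gets more
aggressive.

## The synthetic cohort: what it emulates, and what it does not

`generate_recording()` builds each channel as a unit sinusoid of a phase
trajectory whose instantaneous frequency wanders inside the carrier band
(an AR(1) perturbation with 100 ms correlation time, clipped to the band)
plus white measurement noise. A coupled pair $(i, j, \text{lag}, s)$ sets
the follower's phase to the driver's plus the lag plus $(1-s)\,\eta(t)$,
where $\eta$ is an independent Ornstein–Uhlenbeck phase jitter (100 ms
correlation, stationary SD 3 rad). The model was chosen for its known
limits: at $s = 1$ the lag is exact at every sample, at $s = 0$ the
relative phase decorrelates within an epoch, and the OU jitter's fast
mixing means near-zero-lag pairs are genuinely suppressed by the
phase-lag measures — the volume-conduction behaviour those measures exist
for. Epoching is fixed-length and non-overlapping with the trailing
partial epoch discarded (2 s by default; the epoch length is a free
parameter since connectivity papers rarely report it).

The canonical layout, `chain_topology()`, couples consecutive channels
with a ~π/2 phase advance per step — a travelling oscillation sweeping the
array, as alpha waves do. Jitter accumulates along the chain and the lag
wraps, so measured synchronization falls off with sensor distance in the
non-monotone way phase-lag measures display on real arrays, and the
strong-edge skeleton is triangle-poor and lattice-like. Under these
conditions a 20-subject, 32-channel wPLI sweep reproduces the qualitative
threshold phenomenology: CPL rises as density falls, clustering,
participation and SWI fall with it, and the isolated-node count grows with
the threshold. Group effects are planted either as a mean
coupling-strength shift for group B (`group_effect$delta`; detectable
because it changes the separation between structured and noise edges, not
just the scale — proportional thresholding is scale-invariant) or as extra
coupled pairs.

What the generator does **not** emulate: 1/f background spectra,
artifacts, volume-conduction mixing matrices, realistic 2-D sensor
geometry, or source-space leakage. Passing tests therefore show that the
pipeline's machinery behaves as specified on data with known structure —
not that any particular empirical EEG result will replicate.

## Problem sizes and reproducibility

Validation runs use deliberately modest sizes chosen as the smallest that
make each property decidable: analytic limits on 2-channel, 32 s
recordings; calibration on 600 null and 200 alternative replicates;
sweep phenomenology on 20 subjects × 32 channels × 60 s with 10 random
references per small-world index; group profiles on 16-channel cohorts
with 999 permutations per level. Every stochastic step is seeded: cohorts
derive per-subject seeds from a master seed, sweeps derive per-graph SWI
seeds, and the permutation engine is seeded per threshold, so identical
configuration gives byte-identical outputs (`run_full_pipeline()` writes
the resolved configuration, package version and master seed alongside its
CSVs).

## Known limitations

* The sigma small-world index is unstable on very small or clustering-free
  survivor graphs (it returns the path-length ratio when both the graph
  and its references have zero clustering); a lattice-referenced index is
  a possible extension.
* Spearman p-values use the asymptotic t approximation with midranks, not
  exact tie-corrected enumeration.
* The group-effect profile treats thresholds marginally; threshold-cluster
  inference (AUC over significant clusters against a permutation null) is
  out of scope.
* Directed and time-resolved connectivity are out of scope by design.
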
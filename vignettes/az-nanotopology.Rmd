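---
title: "Active-zone nanotopology from SMLM localization tables: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active-zone nanotopology from SMLM localization tables: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aznano)
```

# The analysis problem

Direct stochastic optical reconstruction microscopy (dSTORM) of the
presynaptic scaffold protein Bruchpilot (Brp) at the *Drosophila* larval
neuromuscular junction produces *localization tables*: one row per fitted
single-fluorophore emission, with planar coordinates (nm), the camera frame
index and the fitted brightness in camera A/D counts. From these point
clouds, the pipeline quantifies presynaptic active zones (AZs) and the
nanoscale Brp subclusters (SCs) within them, per dye condition (AF647,
CF568, CF583R):

1. **Filtering** — per-dye minimum A/D count (3000 for AF647, 1000 for
   CF568/CF583R) and optional polygonal ROI cropping to boutons (at most 6
   per image).
2. **Localization precision (NeNA)** — nearest-neighbour distances between
   consecutive frames, fitted with a Rayleigh same-molecule term plus
   empirical correction terms.
3. **AZ segmentation** — HDBSCAN on (x, y) with minimum cluster size 100 and
   minimum samples 25, plus a robustness sweep over the published parameter
   grids.
4. **Morphometry** — 2D alpha-shape areas, with alpha selected per dye as
   the first value of the grid $\alpha = x^2\,\mathrm{nm}^2$,
   $x = 5, 10, \dots, 200$, at which the median AZ area grows by less than
   5% per step; AZs with area $\le 0.03$ or $\ge 0.3\ \mu m^2$ are excluded.
5. **Nanocluster analysis** — per-AZ Ripley's
   $K(r) = A \sum_{i \ne j} \mathbf{1}(d_{ij} \le r)/(n(n-1))$ without edge
   correction, $H(r) = \sqrt{K/\pi} - r$, averaged over AZs; the radius of
   the mean-H maximum estimates the SC radius. A second-level HDBSCAN is
   calibrated per dye so that the median equivalent-circle SC radius
   $\sqrt{\mathrm{area}/\pi}$ (SC areas at $\alpha = 300\ \mathrm{nm}^2$)
   matches that maximum.
6. **Statistics** — median (25th–75th percentile) reporting, Shapiro–Wilk
   normality, Kruskal–Wallis omnibus (one-way ANOVA on ranks) and Dunn's
   pairwise z comparisons.

# HDBSCAN implementation

No HDBSCAN implementation is available in this package's R dependency
stack, so the package ships its own, written against the published
algorithm: core distances from the k-th nearest neighbour, a minimum
spanning tree of the complete mutual-reachability graph (Prim, exact), the
condensed cluster tree at the requested minimum cluster size, and
excess-of-mass cluster selection with the root excluded (so structureless
data yields no clusters). Three conventions are worth stating:

* **Core distance** counts the point itself: with `min_samples` $= k$, the
  core distance is the distance to the $k$-th nearest neighbour including
  self. This is scikit-learn's convention, against which the implementation
  was verified point-for-point on fixtures (identical partitions).
* **Selection** uses excess-of-mass (the common library default), recorded
  in the output as `selection_method`.
* **Determinism and order sensitivity.** For a fixed input the output is
  fully deterministic (ties in the MST are resolved by index). Under
  permutation of record order, points whose mutual-reachability distances
  tie exactly — typically sparse border points — can swap assignment; this
  is inherent to HDBSCAN on non-generic inputs and shared by the reference
  implementations. The permutation-invariance test therefore uses a
  tie-free instance.

# The synthetic scene generator

The imaging data the pipeline was designed around are not redistributable,
so the package carries a generator that emulates their statistical
structure with known ground truth. Per image it draws:

* `n_az` AZ centres, uniform in a 20 × 20 µm field with at least 1 µm
  pairwise separation (AZs at type Ib boutons are well separated at this
  scale) and a 0.5 µm edge margin;
* per AZ, a Poisson(`sc_per_az`) number of SC centres uniform on the AZ
  footprint disc (default radius 170 nm), each SC filled with molecules
  uniform in a disc of the preset's SC radius (25/34/26 nm);
* a **diffuse molecule population** (default 50% of an AZ's molecules)
  uniform on the AZ footprint, with `sc_id = NA` in the ground truth;
* blinking: per molecule a geometric number of blink events (mean 3), each
  a run of consecutive frames of geometric length (mean 2), uniform start
  over 15,000 frames; every burst frame yields one localization at the
  molecule position plus isotropic Gaussian noise (sd = the dye's
  localization precision per axis);
* intensities log-normal with the dye's median A/D count and shape 0.45
  (so a visible fraction falls below the inclusion threshold and the
  filtering stage has something to do);
* uniform background, 5 localizations/µm² over the whole movie.

Molecule counts are scaled so the expected localization count per AZ
matches the dye preset (1085/1481/547).

Two geometry choices deserve their rationale. The footprint radius default
of 170 nm puts simulated alpha-shape AZ areas near 0.1 µm², inside the
0.03–0.3 µm² analysis window — a smaller footprint (e.g. 120 nm) yields
areas *below* the window's lower bound, so the pipeline's own exclusion
filter would discard most simulated AZs, contradicting the intended
AZ-sized footprints of 0.03–0.3 µm². The diffuse fraction of 0.5 produces
a ~3:1 SC-to-interstitial density contrast: real Brp AZs show subclusters
embedded in a continuous scaffold signal, and without that interstitial
population an AZ is not density-contiguous, so level-1 HDBSCAN at
(100, 25) fragments it. With both in place, simulated scenes reproduce the
published workflow's qualitative behaviour: ~30/30 AZs recovered at
(100, 25) stably across the neighbouring sweep grid, alpha selected in the
900–2500 nm² range, and AZ areas with medians near 0.09 µm².

What the generator does **not** emulate: camera noise and PSF fitting
(localizations are taken as given), dye photophysics beyond the
geometric burst model, astigmatic 3D, chromatic registration, sample drift,
and any specific SC spatial arrangement (ring versus filled is exposed via
`sc_inner_radius_nm` but the default is a filled disc — the true
arrangement is not settled by the data this emulates). Tests passing on
simulated scenes therefore validate the *computational* pipeline, not
biological claims.

# NeNA model and numerics

The consecutive-frame nearest-neighbour distance density is fitted by
least squares (Levenberg–Marquardt, `minpack.lm`) to

$$ f(d) = A\,\frac{d}{2\sigma^2} e^{-d^2/4\sigma^2}
   + B\,\frac{1}{\sqrt{2\pi}\omega} e^{-(d - d_c)^2/2\omega^2} + C\,d, $$

a Rayleigh same-molecule term (two localizations of one molecule, each
with per-axis precision $\sigma$) plus a Gaussian bump and a linearly
rising term for mismatched neighbours. Numerical choices: histogram bin
width 1 nm on [0, 200] nm, normalized to unit area; $\sigma_0$ =
(histogram mode)/$\sqrt2$; correction amplitudes start *near* zero
($B = 0.01$, $C = 10^{-6}$) because at exactly zero the Gaussian term's
$d_c$ and $\omega$ gradient columns vanish and the Jacobian is singular;
box constraints keep all parameters non-negative. The optimizer is used
directly (`nls.lm`) rather than through an `nls` model object, because on
clean data the correction terms legitimately collapse to zero, which makes
the final Jacobian singular — a failure of the model-object construction,
not of the fit. Precision is estimated per image and compared across
images; samples are never pooled across images.

# Ripley's H without edge correction

$K$ is normalized by $n(n-1)$ (ordered pairs; an $n^2$ variant is exposed
via `normalization`). The reference area fed to $K$ is the AZ's alpha-shape
area at the selected morphometry alpha, which keeps $H$ comparable across
AZ sizes. The radius grid is 0–150 nm in 1 nm steps (maxima of interest
all lie below 40 nm). AZs with fewer than 2 localizations after filtering
are dropped from the average and counted (`h_curves_dropped`).

For Poisson-null calibration the estimator supports *border-method*
(minus-sampling) counting via the `focal` argument: neighbours are counted
from focal points at least $\max(r)$ from the window edge to all points.
The naive single-set estimator is biased for sparse Poisson patterns both
by edge truncation and by the concavity of $\sqrt{K}$ at small expected
pair counts; the border method with dense patterns removes the former and
makes the latter negligible, and the mean H over 100 such patterns is flat
at zero within two Monte-Carlo standard errors across the full radius
grid.

# Alpha-shape conventions

Alpha compares the *squared circumradius* of each Delaunay triangle
against $\alpha$ (units nm², matching the $\alpha = x^2$ nm² grid), with
$\le$ keeping the triangle; area is the sum of kept-triangle areas, so it
is monotone non-decreasing in alpha by construction, and
$\alpha \to \infty$ recovers the convex hull. Degenerate point sets
(< 3 distinct points, collinear) get area 0 and are excluded downstream by
the area window. The percent-increase denominator in the selection rule is
the previous step's median over all AZs of a dye (pooled across images); a
step whose previous median is zero is not a computable increase — a jump
from zero counts as infinite and a zero-to-zero step is skipped — so the
rule cannot select an alpha at which the shapes are still empty. The
selection threshold (5%) and the area window (0.03, 0.3) µm² (exclusive:
the boundary values themselves are excluded) are exposed as parameters.

# SC calibration

`calibrate_sc_params()` grid-searches (min cluster size, min samples)
pairs, scoring each by the median equivalent-circle radius of the SCs it
yields over all AZs, and returns the pair minimizing the absolute
deviation from the target radius (the mean-H maximum), ties toward smaller
values. The equivalent-circle definition $r = \sqrt{\mathrm{area}/\pi}$ is
adopted because the published SC area/radius pairs satisfy it exactly
($\pi \cdot 34^2 = 3632$). The default pipeline search grid (mcs
4–60 step 4; ms {2, 3, 5, 8, 12, 18, 25}) spans the published per-dye
settings ((22, 5), (44, 11), (15, 3)) at a resolution that keeps the
search affordable; per AZ and min-samples value the mutual-reachability
MST is computed once and reused across cluster sizes.

# Statistics

Kruskal–Wallis (`stats::kruskal.test`) is the omnibus; Dunn's pairwise
comparisons use the standard z statistic on pooled mean ranks with tie
correction. The multiple-testing adjustment is configurable (`"none"` —
Dunn's plain comparisons — or `"bonferroni"`) and defaults to none, since
commercial packages label differently-adjusted variants with the same
name; the choice is recorded in the result. Quantiles are linear
interpolation (R type 7), recorded in the output. Groups of identical
values are reported as non-testable rather than raising errors.

# Problem sizes in the tests

The test-suite and acceptance checks run simulated scenes of 8–30 AZs and
one to three images per condition, with the full 15,000-frame, 20 × 20 µm
scene geometry; these sizes give 15,000–50,000 localizations per image,
which is the scale of a real acquisition, while keeping a complete run of
every stage in the order of minutes on one CPU. The Kruskal–Wallis
calibration uses 1000 null replicates of 3 × 30 values.

# Known limitations

* The generator's AZ geometry (filled footprint disc + diffuse fraction)
  is a stand-in, not a biological claim; H-maxima recovered from it sit
  slightly below the nominal SC radius at AF647-like precision, as
  expected for a finite-radius disc blurred and averaged over AZs.
* Alpha shapes use exact Delaunay triangulation of de-duplicated points;
  point sets lying exactly on a line have area 0 by convention.
* The rapidSTORM reader handles the whitespace header-comment dialect, not
  the full XML header; ImageJ binary `.roi` files are not parsed (ROIs are
  consumed as vertex CSVs).
* Localization uncertainty is isotropic Gaussian with one sd per dye;
  per-localization precision columns, if present, ride along as extras but
  are not used.
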
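---
title: "Quantifying lateral-vein arrangement along the midvein: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lateral-vein arrangement along the midvein: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veinr)
```

## The question and the statistic

Leaves along a stem follow a species-specific phyllotaxis: *alternate*
(one leaf per node) or *opposite* (two facing leaves per node). Do the
lateral secondary veins along a leaf's midvein follow an analogous
species-specific rule? `veinr` quantifies this from digitized
coordinates of the points where lateral veins bifurcate from the
midvein.

For a lateral vein, let $d_{\mathrm{opposite}}$ be the distance to the
next vein origin on the opposite side of the midvein (apical of, or
exactly opposite to, the focal origin) and $d_{\mathrm{same}}$ the
distance to the next origin on the same side (strictly apical). The
spacing ratio is

$$ r = \frac{d_{\mathrm{opposite}}}{d_{\mathrm{same}}}. $$

Its value separates the arrangement archetypes:

* $r \approx 0.5$ — the vein originates halfway between the two
  opposite-side origins: *alternate-like*;
* $r \approx 0$ or $r \approx 1$ — the vein originates (nearly) level
  with an opposite-side origin: *opposite-like*; pooled over a leaf,
  such an arrangement gives a **bimodal** $r$ distribution with modes
  at 0 and 1, whereas an alternate-like one is **unimodal** at 0.5;
* $r > 1$ — two successive veins on the *same* side: the *irregular*
  pattern. $r = 1$ exactly is not counted as irregular, and no upper
  cap is applied to $r$ (very close same-side origins legitimately
  produce very large ratios).

The most apical origin on each side lacks a neighbour, so its ratio is
undefined and excluded rather than imputed; a leaf with $n$ origins
therefore yields at most $n - 2$ defined ratios.

## Geometry

The midvein is a polyline from lamina base to tip. Each origin is
orthogonally projected onto its nearest segment; the arc length to the
projection foot is the axial position $s$, and the sign of the cross
product of the local tangent with the offset vector gives the side
label. Origins lying exactly on the axis carry no side information and
are excluded with a warning. Coordinates are in image pixels with y
increasing downward, but every quantity used is a ratio of distances,
so the results are invariant under translation, rotation, uniform
scaling and mirror reflection of the image (property-tested).

Two distance metrics are offered, because digitization records only
coordinates and either reading is defensible: `euclidean`
(straight-line distance between bifurcation points, the default — the
most literal reading of the distances drawn on a leaf image) and
`axial` (difference of arc-length positions). Real midveins are nearly
straight and origins sit on the midvein, so the two nearly coincide;
with lateral offsets up to 2% of an internode the ratios agree within
0.05 (tested). The archetype benchmarks in `scripts/acceptance.R` use
the axial metric, under which the noiseless constructions are exact
($r = 0.5$, or $r \in \{\delta, 1-\delta\}$) rather than exact up to
the small lateral-offset correction.

## Departure from unimodality: the dip test

Each species' pooled $r$ values are scored with Hartigan's dip
statistic — the largest vertical distance between the empirical CDF
and the closest unimodal CDF — computed in C by the greatest-convex-
minorant / least-concave-majorant algorithm over shrinking candidate
modal intervals. The statistic lies in $[1/(2n), 1/4]$ and is invariant
under monotone affine transforms. The test suite verifies it to
$10^{-9}$ against an independent brute-force oracle that minimises the
sup-distance over piecewise-linear unimodal CDFs by linear programming
(quadratic-programming feasibility checks plus bisection), on 100
random small samples.

P-values are Monte Carlo: the dip is compared with the dips of `reps`
(default 10,000) uniform(0,1) samples of the same size — the standard
null calibration — using the add-one estimator
$p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(\mathrm{reps}+1)$,
which is never exactly zero and is uniform under the null (calibration
is tested: 500 draws at $n = 300$, Kolmogorov–Smirnov distance
below 0.05, rejection rate $0.05 \pm 0.02$). Monte Carlo was preferred
over interpolating published quantile tables because it is
self-contained and reproducible given the stored seed; results embed
`reps` and `seed` for provenance.

Following the analysis design this package implements, the dip
*p-value* (not the statistic) is the per-species measure of departure
from unimodality, computed on the **full** pooled sample including
$r > 1$ values; a display-style truncation (`truncate_r = 1.5`) is
available as an explicit variant but is not the default.

## Group comparison

Whether departure from unimodality differs between species groups
(alternate vs. opposite phyllotaxis, 18 vs. 12 species; woody vs.
herbaceous, 18 vs. 12) is tested with the two-sided Brunner–Munzel
test on the species-level dip p-values: a rank test of the relative
effect $\hat p = P(X < Y) + \tfrac12 P(X = Y)$ that tolerates unequal
variances and ties (midranks). The studentized statistic uses
Satterthwaite degrees of freedom and the t distribution. Inputs with
zero rank variance (all values tied, or complete separation) make the
statistic undefined; such results are returned flagged `degenerate`
rather than as numbers.

## Density summaries

Violin-style summaries use a Gaussian kernel with Silverman's
rule-of-thumb bandwidth (`stats::bw.nrd0`; configurable, and reported
in the output so figures are comparable across tools rather than
bit-identical). The grid spans three bandwidths beyond the sample
range, keeping the truncated kernel mass below 0.5% so the trapezoidal
integral stays within 0.01 of one — with a two-bandwidth margin,
boundary-heavy samples measurably violate that bound. Modes are strict
interior local maxima; maxima below 10% of the peak density are
disregarded, since isolated tail points otherwise register as spurious
micro-modes. A numerically constant sample (relative range below
$10^{-9}$) is flagged degenerate with its single mode at the common
value instead of attempting a zero-bandwidth fit.

## The synthetic arrangement generator

No generative model for vein spacing comes with the study design this
package implements, so the generator's distributional choices are
explicit stand-ins, chosen once:

* **Phase** $\delta \in [0, 0.5]$: right-side origins are offset from
  their left partners by $\delta$ times the local internode.
  $\delta = 0$ is ideal opposite, $\delta = 0.5$ ideal alternate; the
  noiseless constructions reproduce the archetypes exactly and are the
  acceptance benchmarks.
* **Internodes**: truncated normal (resampled until positive) with
  mean 100 units and coefficient of variation 0.2 — the minimal
  two-parameter spacing model; a CV of 0.2 is typical of the
  node-to-node variability visible in scanned leaves.
* **Jitter**: independent Gaussian axial noise, default sd 0.05 of the
  mean internode, the level used in the parameter-recovery benchmark.
* **Irregular insertions**: with probability $\pi$ per vein an extra
  origin is inserted on the same side midway to the next same-side
  origin, reproducing the two-successive-same-side-veins pattern
  directly (modelling irregulars as deletions of opposite origins was
  considered and rejected because insertion is what the irregular
  archetype shows). With phase $\delta$ the inserted vein's own ratio
  is $1 + 2\delta$ in the noiseless case, so insertions reliably
  surface as $r > 1$ for $\delta$ away from 0.
* **Lateral offset**: origins sit 2 units (2% of the mean internode)
  off the axis on each side — large enough for geometric side
  assignment, small enough that euclidean and axial metrics agree
  closely.

Ground truth (noiseless per-vein ratios, insertion events and their
relative positions) is stored with every generated leaf, and the same
seed reproduces a leaf bit for bit.

At study scale (about 300 pooled ratios per species, jitter 0.05) the
pipeline separates the phase continuum cleanly: $\delta \le 0.1$ gives
dip $p < 0.05$ and $\delta = 0.5$ gives $p > 0.05$, each in at least
90% of seeded runs (tested at 100 runs per phase).

What the generator does **not** emulate: curved midveins (its axis is
straight; the geometry module handles polylines, exercised separately),
intersecondary veins, digitization error of a human operator,
within-leaf gradients of internode length, and any leaf-shape or
lobation model. Passing tests on synthetic data therefore validate the
statistical machinery under the stated model, not the biology of any
particular real dataset.

## Compound leaves and mirror symmetry

Ternate compound leaves are generated as three independent leaflets
(terminal, left-positioned, right-positioned). Treating a leaflet as a
leaf is itself checked: terminal-only and all-positions analyses give
the same dip verdict ($p \gtrless 0.05$) in at least 90% of seeded runs
at both ends of the phase continuum.

For the mirror-image question, every irregular case on a left/right
leaflet pair is mapped to its relative position (arc length / leaflet
length; 0 = base, 1 = tip) and to a signed pair coordinate: minus the
relative position on the left-positioned leaflet, plus on the right,
so the two tips map to $-1$ and $+1$ and both bases to 0. A case is
mirror-matched if the opposite leaflet has an irregular case within
$\tau$ (default 0.1 of leaflet length — the original judgement was
visual, so $\tau$ is explicit, reported, and swept in tests); a pair's
verdict is "mirror" only when both leaflets have at least one
irregular case and every case is matched. Pairs with no irregular case
are excluded from verdicts. In the mirrored generative mode the two
leaflets receive insertion events at identical relative positions with
sides mirrored; because an insertion can surface as $r > 1$ either at
the inserted origin or at its same-side predecessor (one internode
basal), mirrored pairs match within about one internode of leaflet
length — the unit tests therefore use $\tau = 0.2$ with 15 pairs per
leaflet, and the workflow reports verdict counts at the default
$\tau = 0.1$.

## Problem sizes and determinism

The test suite and the acceptance script run at the study's own scale:
20 leaves of 15 pairs for the archetype benchmarks (about 560 pooled
ratios), 300-ratio samples for dip calibration (2,000 null replicates,
500 draws), 100 seeded runs per phase for parameter recovery, and 200
replicates of the 18-vs-12 group design for the type-I check. The
type-I replicates use phase 0.4, where dip p-values vary continuously
across species — the premise of comparing p-values between groups;
strongly bimodal phases push every species' Monte-Carlo p-value to the
same lower bound, which makes the rank test degenerate rather than
miscalibrated. All randomness flows through R's RNG; every pipeline
function takes seeds explicitly, and identical inputs plus identical
seeds give byte-identical result files.

## Design notes and limitations

* The package is organised as an analysis workflow: the numbered
  drivers under `analysis/` narrate the study (simulate → per-species
  distributions → group comparison → leaflet symmetry) while every
  computation lives in the package and is unit-tested; the drivers,
  exported functions and this vignette are the user interface — no
  separate command-line wrapper is provided.
* Published per-species dip p-values exist only as figure annotations
  in the original study, so group-level outputs are validated by
  calibration properties rather than against printed numbers; archived
  raw coordinate data can be analysed by pointing `read_imagej_xy()` /
  `read_points_csv()` at the exported point files, but no
  network-fetched benchmark is bundled.
* Vein-order classification (which origins count as lateral
  secondaries, exclusion of intersecondaries) is assumed done upstream
  by the digitizing operator, as in the original protocol; the package
  neither detects veins in raster images nor classifies vein orders.
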
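---
title: "Selecting a color tolerance for eelgrass leaf-area estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting a color tolerance for eelgrass leaf-area estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eelgrassArea)
```

## The model

Eelgrass (*Zostera marina*) blades are long, narrow ribbons, so the product
of blade length and width is a faithful area proxy, `a_o = l_o * h_o`.  When
those dimensions are read off a scanned image instead of a ruler, the leaf
must first be segmented.  This package segments by **region growing under a
tolerance of similarity**: colors are points of the discrete RGB cube
`[0, C_max - 1]^3`, two 8-adjacent pixels are connected at tolerance
`ST(x) = [0, x]` when their Euclidean color distance is at most `x`, and the
leaf region is the connected component of this pixel graph containing an
operator-chosen seed inside the blade.  Pixel counts along and across the
region give `l_d = np_l / unp`, `h_d = np_h / unp` (with `unp` pixels per
mm), `a_d = l_d * h_d`, and a Monte Carlo estimate `a_mc = LPN / UPN^2` from
sample points laid over the frame.

The tolerance `x` is the crux.  A wet blade scatters a *humidity halo* of
intermediate tones along its contour; a small `x` rejects the halo but may
fragment the blade, a large `x` admits the halo (inflating the width of an
already narrow object) and eventually the background.  The package therefore
sweeps `x` and selects the value minimizing a cohort-level **selection
index**:

* leaves are grouped by observed length into intervals
  `I_k = [q(k-1), qk)` of width `q` (10 mm by default; the final interval is
  closed so the longest leaf is not orphaned);
* groups with fewer than two leaves carry no information about error spread
  and are excluded; the remaining collection is `C_G`;
* per-group mean errors `delta_l^k = mean(l_o - l_d)` (and analogously for
  width) are compared with bands `dbar +/- sigma` built from the cohort mean
  `dbar` of the group deviations and a pooled standard deviation `sigma`;
* `lambda_a` is the fraction of leaves whose group passes both bands and
  whose own area error `e_a = a_o - a_d` is nonnegative (no overestimation);
  `beta_a = 1 - lambda_a`; and `IS_x = beta_a / lambda_a`, with the Monte
  Carlo analogue `IS_x^mc` using `e_mc = a_o - a_mc`.

The admissible tolerance with the smallest `IS_x` is selected; ties break
toward the smaller `x`, which admits less noise.  A tolerance with
`lambda_a = 0` leaves the index undefined and is reported as inadmissible —
in any comparison it counts as worse than every admissible tolerance.

## Design choices in the open corners

**Pairwise chained similarity.**  Connectivity is defined between adjacent
pixels, so similarity during growth is evaluated pixel-to-neighbor, not
pixel-to-seed.  This follows the printed definition of connectivity, at the
price of non-transitivity: tonality can drift across a smooth gradient and
leak the region outward.  No mitigation is attempted — the tolerance sweep
itself is the control, which is exactly what the selection index exploits.
Growth order is irrelevant: the result is the graph component, verified in
the tests against an independent edge-enumeration + `igraph` component
oracle.

**Border handling.**  The 8-neighborhood is clipped at the image border;
border pixels simply have smaller vicinities (3 or 5 neighbors).  For the
peripheral contour, off-image positions count as *outside*, so a region
touching the border contributes those pixels to its contour.  A region
reaching all four borders has clearly escaped the leaf and is flagged
flooded (recorded per leaf, never fatal to a sweep).

**Length and width axes.**  The length count `np_l` is the pixel extent of
the region projected on its principal axis (major eigenvector of the
coordinate covariance), which reduces to the bounding-box dimension for
axis-aligned blades.  The width count `np_h` is taken on the cross-section
at the midpoint of that extent, mirroring the manual protocol of measuring
width halfway along the blade; a maximum-width mode is available behind
`mode = "max"`.  Curvature-following arc length is out of scope.

**Pooled spread.**  The per-group standard-deviation formula must yield one
value per tolerance for the whole cohort, so the package pools within-group
squared deviations with denominator `sum(n_k - 1)`: every leaf contributes,
and the formula reduces to the single-group expression when only one group
is included.  The choice is recorded in the sweep report metadata
(`sigma_method`).  One consequence: proportions are invariant to
replicating every group only away from band boundaries, because the pooled
denominator makes `sigma` grow weakly under replication.

**Complement convention.**  `beta_a` is the full complement of `lambda_a`
(a leaf counts toward `beta_a` when its group fails a band *or* its area is
overestimated), so `lambda + beta = 1` holds exactly on every sweep row.

**Monte Carlo sampler.**  The default is a deterministic grid of pitch
`1/UPN` over the frame — reproducible with no seed bookkeeping; its error
against the exact pixel-count area `|members|/unp^2` is bounded by
`perimeter/UPN`.  A uniform random sampler is available and requires an
explicit seed, which is recorded in the output.  A sample point belongs to
the leaf iff its containing pixel is a member: the region is inherently a
pixel set, so the membership test is at pixel resolution.

**Color depth.**  `C_max = 256` (8-bit RGB) throughout; images of other
depths are rescaled on load with a message.  Distances are compared against
`x` in floating point — no rounding before the comparison, avoiding tie
artifacts.

## What the synthetic generator emulates

`renderLeaf()` draws an axis-aligned trapezoidal ribbon (default taper 0,
i.e. a rectangle, so the length-times-width truth is exact; optional
sinusoidal midline curvature), rasterized by the pixel-center rule with a
quarter-pixel midline offset so width counts are not forced to a single
parity.  Ground truth follows the manual protocol: `h_o` is the width
halfway along the blade — for the trapezoid this equals the mean width, so
`a_o = l_o * h_o` is also the exact shape area.

The humidity halo is a ring of `haloWidth` pixels around the blade whose
colors are drawn uniformly from the line segment between leaf and background
colors at fractions 0.30–0.55.  This guarantees the geometry the selection
procedure must detect: with the default dark-green leaf (30, 90, 40) and
pale scanner-bed background (235, 235, 240), the leaf-to-background distance
is ≈ 321, the halo joins the region once `x` exceeds ≈ 96 (0.30 · 321), and
the background chains in from the halo's far edge beyond ≈ 145
(0.45 · 321) — three cleanly separated regimes (clean, halo-inflated,
flooded).  Intra-leaf tonal variation is a per-channel uniform jitter
(default ±2 in cohort studies).  All randomness flows from a single seed;
rendering is bit-reproducible.

Defaults represent a field cohort at desk scale: `unp = 10` px/mm (≈254 dpi
flatbed), widths uniform on the species' reported 1.5–12 mm range, lengths
uniform on [20, 300) mm against the 460-mm observed maximum — long enough to
occupy many 10-mm length groups, short enough that a 50-leaf sweep over ten
tolerances runs in seconds.  The tests and the cohort examples use 50-leaf
cohorts, tolerances 16–160 in steps of 16, and an 8×8-pixel cap with ≤4
colors for the 100-image oracle-equivalence suite.

What the generator does *not* emulate — and what passing tests therefore do
not establish about field images: photographic texture and venation,
epiphyte cover and mud particles, multi-leaf scenes, strong curvature or
grazing damage, and halos whose tones are not colinear with the
leaf–background segment.  Field use still requires the cohort-level sweep on
the actual image set; the synthetic results show the machinery is correct,
not that any particular `x` transfers.

## Numerical notes and limitations

* Quotients reported against published tables are *truncated* (not rounded)
  to four decimals (`truncate4()`), matching the convention used when those
  tables were printed.
* Pixel-count measurements quantize at one pixel: expect `l_d`, `h_d` within
  `1/unp` of truth for clean segmentations; relative area error on
  noise-free 50-leaf cohorts stays under 2% at `unp = 10`.
* Two-group cohorts are degenerate for the band test: both group deviations
  sit symmetrically about their mean, so they pass or fail together.
  Cohorts should occupy at least three included groups.
* The selection index compares *overestimation odds*, not absolute error;
  validation against observed values uses the RMSD table
  (`rmsdTable()`), which requires the observed `l_o`, `h_o` for every leaf.

## A minimal run

```{r example, eval = FALSE}
co <- generateCohort(nLeaves = 50, seed = 11, haloWidth = 2, jitter = 2)
res <- runSweepSelect(co$manifest, images = co$images,
                      xValues = seq(16, 160, by = 16))
res$selection        # x*, IS_x, IS_x^mc
sweepStats(res$sweep)
rmsdTable(res$sweep)
```
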
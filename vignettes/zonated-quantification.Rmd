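---
title: "Joint zonated quantification of hepatic lobule parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint zonated quantification of hepatic lobule parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zonequant)
```

## The problem

Liver tissue is organized in roughly hexagonal lobules: blood enters at
portal fields (PF) on the periphery and drains into a central vein (CV) at
the center. Because oxygen and nutrient gradients run along this
porto-central axis, hepatocyte function is *zonated* — pericentral markers
such as glutamine synthetase (GS) and most cytochrome P450 (CYP) enzymes
peak near the CV, while pathologies such as macrovesicular steatosis often
accumulate periportally. Studying how a zonated pathology and zonated
marker expression interact requires quantifying both *jointly*, per lobule
and per intra-lobular zone, from adjacent serial sections carrying
different stains.

`zonequant` implements that workflow: vessel annotations define an
idealized lobular geometry, stain- and fat-signals are detected per pixel,
and everything is aggregated into one per-(lobule, zone) table that feeds
trend fits and visualizations. A synthetic slide generator with exact
ground truth makes every stage testable without any real slide material.

## Geometry: portality, lobules, zones

The geometric backbone is the **portality** of every pixel $x$:

$$\mathrm{portality}(x) = 1 - \frac{d(x, \mathrm{PF}_{\min})}
 {d(x, \mathrm{PF}_{\min}) + d(x, \mathrm{CV}_{\min})}$$

with Euclidean distances to the *nearest* PF and CV center. It is 1 at a
PF, 0 at a CV, and 0.5 on the equidistant locus. Distances assume isotropic
pixels; anisotropic inputs are not supported.

**Lobules** are the catchment basins of a watershed transform of this
surface, flooded from its minima (the CVs). Discretization can produce
spurious shallow minima, so the surface is *pre-flooded*: minima shallower
than `preflood_height` (default 0.05 portality units — small enough to
never suppress a true CV minimum, whose portality is exactly 0) are merged
before basin assignment. If two annotated CVs end up in one merged basin
they share a lobule and the merge is reported, mirroring what anatomically
adjacent central veins should do. Basins are relabeled `1..n` by the
`(y, x)` order of their seed CV, which makes label maps bit-reproducible;
ridge pixels are assigned by the watershed implementation's deterministic
flooding order.

**Zones** quantize portality into `n_zones = 12` half-open bins
`[(i-1)/n, i/n)` with the top edge closed, so every value maps to a zone
and portality 1.0 lands in zone 12. Zone 1 is the most pericentral band,
zone 12 the most periportal. Zones 1 and 12 are kept in the table but
excluded from analysis by default because vessel lumina dominate their
area.

## Stain classification

Marker quantification needs three pixel classes: *unstained* (vacuoles,
vessel lumina, void), *positive* (chromogen, e.g. DAB brown) and
*negative* (counterstained tissue). A rough tissue mask comes from Otsu's
threshold on the luminance image (tissue is darker than background),
followed by closing with a 3-px disk, hole filling — enclosed bright
structures are exactly what the color model must see — and removal of
components below 64 px; all cleanup steps are toggleable.

A 3-component Gaussian mixture is then fitted by EM to the tissue-masked
RGB distribution. The fit operates on the binned 3D RGB histogram (64 bins
per channel) with each occupied bin represented by the *mean color of its
pixels*, weighted by the pixel count — numerically equivalent to raw-pixel
EM at these bin widths and orders of magnitude faster. Initialization is
seeded k-means++ followed by ten weighted Lloyd iterations; EM runs to a
relative log-likelihood tolerance of 1e-5 (cap 200 iterations) with a 0.1
ridge on the covariances. The seed is part of the pipeline configuration,
so the whole model is reproducible.

Class semantics are an interpretation layer: the component with the
highest luminance mean is `unstained`; of the remaining two, the one closer
in RGB to the configured chromogen reference (default DAB brown
`(140, 110, 80)`) is `positive`. Final pixel labeling deliberately uses the
*nearest class mean*, not mixture posteriors, and ties break toward the
lower class index.

Macrovesicular fat droplets are bright, round vacuoles enclosed by tissue.
Candidates are pixels whose every channel exceeds the 0.90 quantile of the
*stained-tissue* luminance (the sub-Otsu part of the mask — including the
vacuoles themselves in the reference population would drag the threshold
into the vacuole brightness range whenever steatosis is pronounced), with
an absolute near-white floor of 200/255: vacuoles are unstained glass near
the illumination white point, and the floor keeps the relative quantile
meaningful on slides that contain no bright population at all.
Candidate components are hole-filled and kept if their physical area lies
in 40–5000 µm² and their circularity $4\pi A/P^2 \ge 0.5$. These defaults
are deliberate approximations of published fat-detection practice and are
fully config-exposed.

## Quantification and trends

Per (lobule, zone): steatosis is the fat area fraction; each marker's
`stained_fraction` is `(positive + negative) / area` and its ratio
`positive / (positive + negative)` is reported only where the stained
fraction reaches 5% (boundary inclusive) — zones dominated by void or
unstained area yield an *absent* value, never a zero, since zero is a
legitimate measurement. The stained-fraction denominator is the full zone
pixel count by default (so void depresses it, which is what the threshold
must catch; a tissue-only denominator is available). The steatosis
denominator is the zone's tissue area when a tissue mask is supplied, so
background at slide borders does not dilute the fraction. Tables from
several stains are outer-joined on the CV UUID and zone index.

Zonal trends use the normalized lobular position $x \in [0, 1]$ (0 =
portal field, 1 = central vein) evaluated at zone *centers*,
$x = 1 - (z - 0.5)/n$, which keeps fitted slopes comparable independent of
the zone count; zone-edge mappings would compress the fitted range and are
not used. Per lobule, ordinary least squares fits $p(x) = m x + p_0$ per
parameter, and $p(s) = m_s s + p_{s,0}$ for marker-versus-steatosis
relations. Lobules with fewer than two usable zones, or with a
zero-variance predictor (e.g. a steatosis-free control in the $p(s)$
model), yield an absent fit with a flag instead of an infinite slope.
Summaries report median, mean, standard deviation, quartiles and Tukey
1.5-IQR whiskers across lobules.

## The synthetic generator

The generator emulates the statistical structure the pipeline measures,
not histological texture:

* CVs on a hexagonal lattice (default pitch 224 px at 0.909 µm/px, the
  quarter-resolution scale typical for whole-slide analysis), PFs at the
  hexagon vertices; only cells whose full portal ring fits the tissue
  rectangle are kept, optional jitter, fresh v4 UUIDs.
* Marker positivity is drawn per pixel as
  Bernoulli$(\mathrm{clip}(m x + p_0))$ at the pixel's true position, so a
  zone's expected positive-pixel fraction *is* the programmed gradient
  value — exactly the estimand of ratio-of-areas quantification. The
  default panel programs slopes +0.8 (pericentral marker), 0 (uniform,
  CYP2D6-like) and −0.8 (periportal marker) with intercepts keeping
  probabilities inside [0.1, 0.9].
* Steatosis follows $s(x) = \mathrm{clip}(-0.2 x + 0.25)$ — a periportal
  gradient of realistic magnitude. Droplets are non-overlapping disks
  (radii 4–8 px) placed by dart throwing with per-(lobule, zone) area
  budgets. A dart is accepted only if at least half its disk lands in
  zones that still have budget, with descending strictness (0.85 / 0.60 /
  0.45) and shrinking radii over three passes; this bounds the per-zone
  overshoot even where a zone band is narrower than a droplet diameter.
  Requested fractions above 0.6 are refused as infeasible for
  non-overlapping placement.
* Colors: unstained `(245,243,240)` (used for vacuoles), DAB-like positive
  `(135,100,70)`, hematoxylin-like negative `(170,150,200)`, white
  background outside the tissue rectangle; i.i.d. Gaussian noise (default
  sigma 8 gray levels) added per channel and clipped. Droplets are drawn
  in the unstained vacuole color — slightly off pure background white —
  so the three color populations the EM model expects are all present.

The `expected_zone_table()` oracle evaluates the programmed gradients at
each zone's *mean* position over its tissue pixels (computed from the true
geometry). The nominal zone-center position is available as an option, but
the zone mean is what per-zone pixel averages of an ideal render converge
to; with steep gradients the two differ by more than the oracle's own
tolerance, so the mean is the honest reference. Trend fits, in contrast,
regress on nominal zone centers — that is the estimator under test.

What the generator does **not** emulate: nuclei/sinusoid texture, stain
variation within a slide, registration misalignment between stains (all
synthetic stains share one frame), microvesicular steatosis, and
three-dimensional sectioning effects. Passing recovery tests therefore
demonstrates the correctness of the measurement chain on data that meets
the model's assumptions, not robustness to real-world staining artifacts.

## Numerical choices and degenerate inputs

* Portality at coincident PF/CV distance zero is defined as 0.5; empty PF
  or CV sets are errors (the ratio is undefined).
* Quantization clamps `floor(p * n) + 1` into `1..n`, so `p = 1` joins
  zone `n`.
* Watershed basins that contain no CV after pre-flooding (spurious minima)
  are merged into the basin of the nearest CV.
* Otsu on a single-valued image is an error; EM with fewer than three
  distinct masked colors is an error; EM non-convergence raises an error
  carrying the log-likelihood tail rather than returning a half-converged
  model.
* Nearest-mean classification ties break toward the lower semantic class
  index; equal chromogen-reference distances break toward the darker
  component, with a warning.
* OLS uses the closed form `cov(x, y)/var(x)`, exact on collinear input.
* Label maps are serialized as 32-bit float TIFF scaled by 2^-15 — exact
  for integer labels below 2^24 — because 32-bit TIFF samples are written
  as IEEE floats clamped to [0, 1].
* Annotation transfer under non-rigid or rotational transforms stores the
  axis-aligned bounding box of the mapped vertices, flagged
  `bbox_approx`; only the center feeds the geometry, so nothing is lost
  downstream. Dense displacement fields are inverted by damped fixed-point
  iteration (max 50 iterations, default residual tolerance 0.5 px).

## Problem sizes used in the tests

The packaged checks run the full pipeline on a 512² slide with 6 complete
lobules for fast unit coverage, and on a 2048² slide (lattice pitch 224 px,
72 complete lobules, noise sigma 8) for gradient-recovery and control
checks — large enough for stable medians across lobules while keeping a
complete run in a few minutes on one core. Real whole-slide images are
orders of magnitude larger; the pipeline's `analysis_downsample` (default
4, i.e. quarter resolution) is the intended operating point there, and
desk-scale rasters up to roughly 8k² are the design target. Gigapixel
streaming and tiling are out of scope.

## Known limitations

* The EM color model is robust to color shifts *between* slides but not to
  local variation *within* a slide, and it estimates the presence of
  positive signal, not protein amount or activity.
* Lobule geometry is idealized from vessel center points; tissue gaps and
  indentations can produce lobules spanning disconnected tissue
  (a topology-aware watershed is not implemented).
* Only the linear trend family is implemented; the fitting interface is
  the place to add exponential or sigmoid families, which would suit
  GS-like step profiles better than a line.
* Fat detection parameters approximate, not reproduce, the published
  reference algorithm.
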
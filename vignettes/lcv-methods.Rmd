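---
title: "Methods: landscape conservation value mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landscape conservation value mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcvmap)
```

This vignette documents the models behind `lcvmap`, the parameters that
matter, the numerical choices made where the method left room, and what the
synthetic tests do and do not demonstrate about real data.

## The model

A landscape conservation value (LCV) map rests on two premises: landform is
the physical skeleton of a landscape (slow-changing, controlling natural
process), land cover its flesh (fast-changing, recording human influence).
Crossing a 5-class landform grid with a 7-class land-cover grid yields up to
35 *landscape types*; an expert panel assigns each type a conservation value;
and the spatial arrangement of those values — not just their magnitude —
identifies where management attention is needed: cells whose neighbourhood
mixes high and low values are the ones most exposed to degradation pressure.

### Terrain derivatives

Two per-cell quantities drive the landform classification.

**Specific upslope contributing area.** Flow is routed downhill cell to
cell, and each cell accumulates the area fractions routed into it plus its
own area; the total is divided by the contour width $b$, taken equal to the
cell size:

$$AS = \frac{1}{b} \sum_{i=1}^{n} p_i A_i .$$

The routing rule defining the fractions $p_i$ is configurable:

* **MFD** (default): outflow splits among all strictly lower 8-neighbours in
  proportion to the downhill slope toward each (drop over distance, with
  $\sqrt{2}\,b$ on diagonals). Chosen as the default because $AS$ here proxies
  the *potential for material movement*, which disperses on convex volcanic
  shields rather than following a single thread.
* **D8**: the whole unit fraction goes to the steepest-descent neighbour
  (ties broken by a fixed neighbour order). Useful when a brute-force oracle
  or channel-threading behaviour is wanted.

A cell with no strictly lower in-grid neighbour emits nothing: on the grid
edge it is an outlet, in the interior a pit. `fill_sinks()` removes interior
pits before routing by epsilon-raising (default 1 mm) any interior cell not
above its lowest neighbour; boundary cells are never raised. This both breaks
flats (the raising propagates a tiny gradient toward the nearest lower cell)
and guarantees an acyclic flow graph, so accumulation in decreasing-elevation
order is exact. Self-inclusion of the cell's own area makes
$AS \ge b$ everywhere and keeps the channel threshold well defined.
With MFD on a pit-free DEM, the accumulated area over outlet cells equals the
grid area exactly (mass conservation — a property the test suite checks to
$10^{-6}$ relative).

**Surface curvature.** The mean elevation difference to the available
8-neighbours, per unit distance:

$$C_s = \frac{1}{n} \sum_{n} \frac{Z_i - Z_n}{d_{in}},$$

positive on convex forms, zero on planes, negative in hollows. The 8-neighbour
stencil is the smallest symmetric one; $d_{in}$ is $b$ on cardinal and
$\sqrt{2} b$ on diagonal links. Nodata neighbours are simply excluded from the
mean, which keeps the statistic defined up to the data edge.

Slope is the arctangent of the central-difference gradient magnitude
(one-sided at edges), in degrees.

### Landform classification

The nine-unit landscape model separates hillslope positions by process
regime. Eight units have operational topographic definitions here; the
classification is a fixed-priority cascade, applied in this order:

1. **channel** — $AS \ge$ `channel_upslope_min`. Channel outranks everything
   because stream cells override whatever unit they cross.
2. **fall face** — slope $\ge 45^\circ$ (the one cutoff fixed by the
   published unit definitions).
3. **summit** — curvature $\ge$ `summit_curvature_min`, slope below the flat
   bound, and a local elevation maximum over the 8-neighbourhood.
4. **shoulder** — curvature $\ge$ `shoulder_curvature_min`.
5. **footslope** — curvature $\le$ `footslope_curvature_max`.
6. **toeslope** — slope $<$ `flat_slope_max_deg`.
7. **backslope** — everything else.

Only the 45° bound is prescribed; the others are configuration with
data-driven defaults: curvature cutoffs at the 95th / 80th / 20th percentiles
of the observed curvature distribution, flat bound 5°, and the channel
threshold at the 99th percentile of $AS$. The channel default is quantile
based deliberately: a multiple-of-the-median rule is unstable across routing
methods (MFD's dispersion compresses the ratio of extreme to median $AS$ by
an order of magnitude relative to D8), while a fixed upper quantile is
routing-stable and matches the empirical rarity of channel cells (a percent
or two of a study area). The defaults are calibrated so that all five final
classes appear on the synthetic island; on real terrain they are starting
points, not doctrine, and every threshold is a parameter.

The nine units are merged to five display classes following the expert
relabelling: backslope and fall face → **Slope**; footslope ("mild slope")
→ Slope by default, configurable to Flat land, since it is a sloping
(depositional) unit but sits at the foot of the hillslope; toeslope → **Flat
land**; stream → **Channel**; summit and shoulder keep their names.
Interfluve — never produced by the default cascade — maps to Flat land. The
NULM provenance grid is retained on the result (`$nulm`).

### Typology

Landscape types are pair codes `landform * 10 + landcover` (tens digit =
landform 1–5, units digit = land cover 1–7), decodable without a legend
file. Overlay requires already-aligned grids — no silent resampling; an
explicit nearest-neighbour helper (`resample_nearest()`) is provided. Area
tabulation reports cells, km² and percentage of the unmasked footprint.

### Expert-survey aggregation

Each expert rates all 12 classes on a 1–5 Likert scale and states a pairwise
importance judgement. Weights multiply ratings: 1.75 ("Very Important"), 1.5
("Important"), 1.25 ("Merely Important"), 1 ("Same"). The published factor
list omits "Somewhat Important"; the one documented use applies ×1.25 to it,
so 1.25 is the default and the weight map is configurable.

Per expert, the weighted land-cover and landform scores multiply into a
7 × 5 product matrix (rank 1 by construction). Panel aggregation is
*mean-then-rescale*: cell-wise arithmetic mean across experts, then one
linear map onto $[1, 10]$:

$$v \mapsto 1 + 9\,\frac{v - \min}{\max - \min}.$$

Min–max is the unique affine map reproducing the published endpoint values
(exactly 1 at the minimum cell, exactly 10 at the maximum, ties preserved).
It is invariant to positive affine transformations of the input, so experts
who use the scale more or less generously but consistently do not change the
result. A rescale-then-mean variant exists for sensitivity analysis. Whether
a real second-round panel rates the 35 types directly or through class
products is ambiguous in practice; both paths are supported
(`aggregate_survey()` for products, `rescale_1_10()` on any directly elicited
mean matrix).

The packaged reference matrix has its printed values verbatim. One printed
irregularity is worth noting: values rise monotonically along every
land-cover row, and down four of the five landform columns, but the Channel
column has Barren land (2.52) above Developed (2.43) — the packaged fixture
keeps the printed numbers rather than "correcting" them, and the integrity
tests assert the orderings that actually hold.

### Conservation-value mapping and susceptibility

`apply_lcv_matrix()` is a per-cell lookup of the normalized matrix over the
type grid. Zonal statistics use a cell-centre-in-polygon test (deterministic,
no partial-cell weighting ambiguity) and *population* SD (divide by $n$), the
convention of raster-GIS zonal/focal tooling; sample SD is available by
argument. The focal SD uses a square moving window, default 3 × 3 — the
smallest symmetric neighbourhood consistent with "each cell and its
surrounding cells" — truncated at edges, with the centre cell included and
nodata excluded; fewer than two valid cells yields nodata.

The susceptibility mask thresholds the focal-SD field at a percentile of its
unmasked values (default 80th, i.e. the top 20%), with linear-interpolation
percentiles and ties at the threshold *included* ($\ge$). Both choices are
deterministic and make the mask monotone in the percentile. The threshold
value and percentile are recorded in the result and the run manifest; the
published case-study threshold (1.74 on the same 1–10 scale) is a property of
that study's real data and is not a target here.

## The synthetic island

The generator supplies study conditions when real rasters are absent. Its
defaults are a 64 × 64 grid of 30 m cells — a desk-scale stand-in for a
volcanic shield island at the published working resolution — with:

* a central cone, 400 m apex, dropping linearly to sea level at the island
  radius (the grid half-extent), so the background slope is ~23°;
* 5 secondary cones ("oreums") of 80–150 m with a 1.5-cell Gaussian radius,
  placed with mutual separation in the mid-radius band; they are tall and
  narrow enough to be strict local maxima against the background gradient,
  which is what makes them detectable summits;
* 3 radially incised channels (40 m incision at the coast, tapering to zero
  at the apex), whose beds descend monotonically — carved drainage that the
  accumulation stage re-discovers;
* Gaussian elevation noise with SD 2 m, enough to give the flat coastal
  apron realistic micro-relief without destroying the cone structure.

Land cover is assigned by elevation band (six breaks, default the DEM's
interior septiles) in the order open water, wetland, developed, agriculture,
forest, grassland, barren land from coast to summit, mimicking the
elevation-zoned cover of a developed volcanic island, plus a 5% seeded
speckle so rare class–landform combinations exist. Simulated panels default
to 13 experts with latent class values spread over the Likert range and
rating noise SD 0.3, discretized by round-half-up and clamping.

All generators are driven by one integer seed per call and restore the
global RNG state (no hidden coupling between calls). Determinism is
bit-exact: identical seeds give identical grids, tables and downstream
checksums.

**What the synthetic tests show — and do not.** They demonstrate that every
algorithmic stage is correct against closed forms and brute-force oracles,
that the pipeline's statistical machinery recovers known latent structure
(panel rank recovery, band proportions, disc areas), and that the
susceptibility logic traces value boundaries exactly. They do not
demonstrate that the default NULM thresholds are geomorphologically tuned
for any real landscape, that elevation-banded cover matches real land-use
pattern (real cover responds to ownership, roads and history, not elevation
alone), or that a 13-expert panel's values transfer between regions.
Applying the workflow to real data requires threshold review against a known
landform map and a genuine elicitation.

## Numerical choices and degenerate inputs

* Problem sizes in the test suite: 64 × 64 end-to-end runs, 6 × 6 grids for
  the 100-replicate D8-vs-enumeration oracle, 8 × 8 for the 100-replicate
  focal-SD oracle, panels of 13–200 experts — sizes at which exhaustive
  oracles are exact and the full suite stays fast.
* D8 steepest-descent ties break by fixed neighbour order (NW, N, NE, W, E,
  SW, S, SE); with continuous elevations ties have probability zero.
* Equal-elevation neighbours exchange no flow (only *strictly* lower
  neighbours receive), so accumulation order among ties is irrelevant.
* `rescale_1_10()` refuses constant matrices (degenerate range);
  `tabulate_type_areas()` refuses all-nodata grids; zones covering no cell
  centre produce a flagged `NA` row with a warning rather than an error.
* ASCII grid output writes 17 significant digits, so doubles round-trip
  bit-exactly and re-runs are checksum-identical.
* Grids are matrices plus georeferencing rather than objects from a raster
  stack; the plain-text Esri ASCII format carries the full north-up affine
  (corner + cell size) and is readable by any GIS.

## Known limitations

* The ninth NULM unit has no operational rule here (the published unit list
  names eight); interfluve is reserved in the legend but never assigned.
* Pit filling is epsilon-based and single-scale; closed basins larger than
  the epsilon cascade handles well would need a priority-flood filler.
* Zonal membership is cell-centre based; thin or sliver polygons smaller
  than a cell may cover no centre.
* The focal window is square and unweighted; anisotropic heterogeneity is
  not distinguished from isotropic.
* Expert aggregation models the panel mean only; disagreement between
  experts is not propagated into the map.
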
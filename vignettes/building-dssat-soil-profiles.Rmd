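---
title: "From gridded soil properties to DSSAT soil profiles: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From gridded soil properties to DSSAT soil profiles: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gensol)
```

Crop simulation models such as DSSAT need a soil profile file — water
retention limits, saturated conductivity, root growth factors, surface
parameters — for every point they simulate. Gridded soil databases supply
only the easily mapped properties (texture, organic carbon, bulk density,
pH, CEC) on six standard depth intervals (0–5, 5–15, 15–30, 30–60,
60–100, 100–200 cm). `gensol` closes the gap: it derives the hydraulic
properties with pedo-transfer functions, classifies every grid cell into
one of 27 generic soil profiles to inherit the parameters that cannot be
derived, aggregates fine grids to a model-friendly coarse resolution, and
writes DSSAT `*.SOL` files partitioned by country.

This vignette documents the model choices, the tunable parameters and the
numerical decisions, in that order of importance.

## Pedo-transfer functions

Water content at wilting point ($\theta_{1500}$, DSSAT `SLLL`), field
capacity ($\theta_{33}$, `SDUL`) and saturation ($\theta_S$, `SSAT`), and
saturated conductivity ($K_S$, `SSKS`), are estimated from sand ($S$),
clay ($C$) and organic matter ($OM$) with the Saxton–Rawls regressions:

$$\theta_{1500t} = -0.024S + 0.487C + 0.006\,OM + 0.005\,S\,OM -
0.013\,C\,OM + 0.068\,S C + 0.031$$
$$\theta_{1500} = \theta_{1500t} + (0.14\,\theta_{1500t} - 0.02)$$
$$\theta_{33t} = -0.251S + 0.195C + 0.011\,OM + 0.006\,S\,OM -
0.027\,C\,OM + 0.452\,S C + 0.299$$
$$\theta_{33} = \theta_{33t} + (1.283\,\theta_{33t}^2 -
0.374\,\theta_{33t} - 0.015)$$
$$\theta_{(S-33)t} = 0.278S + 0.034C + 0.022\,OM - 0.018\,S\,OM -
0.027\,C\,OM - 0.584\,S C + 0.078$$
$$\theta_{S-33} = \theta_{(S-33)t} + (0.636\,\theta_{(S-33)t} - 0.107)$$
$$\theta_S = \theta_{33} + \theta_{S-33} - 0.097S + 0.043$$
$$B = \frac{\ln 1500 - \ln 33}{\ln\theta_{33} - \ln\theta_{1500}},
\qquad \lambda = 1/B, \qquad K_S = 1930\,(\theta_S -
\theta_{33})^{3-\lambda} \;\text{mm h}^{-1}$$

Three conventions matter and are enforced in code:

* **Input scaling.** $S$ and $C$ enter as *decimal fractions* (0–1) and
  $OM$ as mass %. This is the only scaling under which the published
  coefficients produce physical water contents; a sanity assertion
  rejects sand or clay above 1.5 at the equation boundary, since such
  values are almost certainly percentages passed by mistake.
* **Organic matter.** Source grids carry organic carbon in g kg⁻¹. It is
  divided by 10 once at ingest (`SLOC` is a percentage) and multiplied
  by 2 to obtain $OM$ — the factor-2 carbon-to-matter conversion, chosen
  deliberately over the conventional van-Bemmelen 1.724.
* **Units.** $K_S$ is evaluated in mm h⁻¹ and divided by 10 for the
  `SSKS` column (cm h⁻¹); bulk density is passed through (kg m⁻³ →
  g cm⁻³ by /1000) and is *not* used to density-adjust the regressions,
  which use texture and organic matter only.

### Validity domain and clamping

Regressions of this family were fitted on agricultural soils; very sandy
or very clayey inputs can produce non-physical output (e.g. a negative
wilting point on pure sand). `gensol` defines a validity domain —
$\theta_{1500} \ge 0.01$, $\theta_{33}-\theta_{1500} \ge 0.01$,
$\theta_S \le 0.60$, and $\theta_S > \theta_{33}$ — and clamps output to
the nearest bound outside it. Every clamped layer is flagged
(`ptf_clamped`) and counted in the run report; inverted or negative
water contents are never silently emitted. No additional cap below total
porosity is applied. The polynomials are evaluated in double precision
with the terms in their printed order, so an independent transcription
of the equations reproduces the implementation to machine precision.

## Generic-profile classification

Parameters that cannot be derived from the grids (surface parameters,
root growth factor, total nitrogen) are inherited from a set of 27
generic profiles keyed by texture × fertility × rooting depth
(clay/loam/sand × high/medium/low × deep/medium/shallow), identified as
`HC_GEN0001` (clay, high, deep) through `HC_GEN0027` (sand, low,
shallow), texture varying slowest.

* **Texture** collapses the texture triangle to three regions:
  clay ≥ 40 % → CLAY; sand ≥ 65 % and clay < 18 % → SAND; else LOAM.
  The collapse rule is a configuration default of this package, not a
  published constant, and is overridable (`texture_rule`).
* **Fertility** uses topsoil organic carbon (thickness-weighted mean
  over 0–30 cm): HIGH ≥ 1.2 %, MEDIUM ≥ 0.7 %, LOW below. These
  thresholds are likewise configuration defaults
  (`fertility_thresholds_pct`).
* **Rooting depth** uses the available water content of the top metre,
  $AWC = 1000\,(SDUL - SLLL)\,Z_r$ with $Z_r = 1$ m, accumulated over
  the part of each layer intersecting 0–100 cm (the 100–200 cm layer
  contributes nothing). The per-texture lookup is: clay — deep above
  150 mm m⁻¹, medium (100, 150], shallow ≤ 100; loam — 150/75; sand —
  125/75; intervals lower-exclusive/upper-inclusive. The published
  source for this lookup prints ambiguously, so the default table is a
  reconstruction chosen to honor the worked example (clay at
  140 mm m⁻¹ → medium), the printed class edges (150, 125, 100, 75, 50,
  15) and monotonicity; it is fully overridable (`depth_lookup_mm`).

Classification uses topsoil (0–30 cm) texture so that one class — and
one generic profile — describes the whole cell.

### Packaged templates

The original contents of the 27 generic profiles are not redistributed
here, so the package builds synthetic stand-in templates: root growth
factor 1.0 down to a 15 cm layer midpoint, then
$e^{-0.02\,(\text{midpoint}-15)}$, zeroed below the rootable depth of
the class (deep 180 cm, medium 120 cm, shallow 60 cm); surface
parameters take crop-model-conventional per-texture defaults (albedo
0.13/0.12/0.15 for clay/loam/sand, runoff curve numbers 85/76/64,
drainage 0.25/0.50/0.75 day⁻¹); template water contents are computed
from the package's own pedo-transfer functions on a representative
texture per class, keeping every template internally consistent. Total
nitrogen decays with depth from a fertility-dependent topsoil value
(0.15/0.10/0.05 %). These are documented stand-ins: supplying real
template files via `load_templates(dir)` is the supported path to
fidelity, and user-supplied templates are validated against the same
invariants (27 unique IDs; SRGF within [0,1], non-increasing, zero
below the class rootable depth) with hard errors.

## Layer remapping

Templates carry seven layers (0–10, 10–30, 30–60, 60–90, 90–120,
120–150, 150–180 cm); output profiles carry the six standard intervals.
Template-native values (SRGF, SLNI) transfer by fixed weighted
averages: 0–5 ← layer 1; 5–15 ← ½·layer 1 + ½·layer 2; 15–30 ← layer 2;
30–60 ← layer 3; 60–100 ← 0.75·layer 4 + 0.25·layer 5; 100–200 ←
0.2·layer 5 + 0.3·layer 6 + 0.5·layer 7. The 5–15 cm entry uses the
published equal weights rather than exact overlap fractions — the two
template layers only partially overlap the output interval, and the
published allocation is kept verbatim. The same scheme is applied to
SLNI as a documented extension of the SRGF rule. Weights are declarative
(a tibble) and overridable; within each output layer they must sum to
exactly 1, which makes the remap conservative (constant in → same
constant out), linear, and monotonicity-preserving.

## Aggregation and the smoothing effect

Fine grids are aggregated to coarse cells (default 10×10 fine pixels
per cell) by the arithmetic mean over valid pixels, treating the target
cell as one homogeneous unit. A coarse cell is emitted only if at least
`min_valid_fraction` (default 0.5) of its block is valid — partial
coastline blocks below the threshold become nodata and are counted in
the run report. Because sand, silt and clay are averaged independently,
their means no longer sum to 100; they are rescaled to close the
simplex exactly, and the pre-rescale deviation is logged.

By default the pedo-transfer functions run at the fine resolution and
the derived water contents are averaged (`ptf_stage = "fine"`); setting
`ptf_stage = "coarse"` applies them to the coarse-cell means instead.
The two orders differ because the regressions are nonlinear; both are
supported so the difference can be surfaced on any input.

Averaging narrows spatial distributions. `smoothing_variance_ratio()`
quantifies this per property and layer as the ratio of the coarse-cell
variance to the fine-pixel variance, with each block mean weighted by
its valid-pixel count and population (not sample) variances on both
sides. Under exactly that weighting the law of total variance makes the
ratio at most 1 — which is the level at which the package asserts it.
With unweighted sample variances the bound can fail spuriously (small-n
denominator bias of the coarse sample, unequal valid counts across
partial blocks) even though the mechanism is real.

## Output

Each complete coarse cell yields one profile: six layers at bottoms
5/15/30/60/100/200 cm, master horizons fixed at A, A, AB, BA, B, BC,
grid-derived `SBDM`, `SLOC`, `SLCL`, `SLSI`, `SLHW`, `SCEC`, derived
`SLLL`/`SDUL`/`SSAT`/`SSKS`, template-inherited surface parameters and
remapped `SRGF`/`SLNI`, and `-99` in `SLCF` and `SLHB` (the
missing-value sentinel the crop model replaces with defaults; it
appears in no other column). Profile IDs are the 2-letter country code
plus an 8-character base-36 encoding of the coarse cell index —
deterministic, unique and within DSSAT's 10-character limit. Output is
partitioned into one `<ISO>.SOL` file per country by the cell-center
rule, with a catch-all code (default `XX`) for unmasked cells; no file
is written for an empty country.

The `*.SOL` writer emits fixed-width records — every column 6
characters, right-aligned, water contents and SRGF at 3 decimals,
conductivity/bulk density/organic carbon at 2, the rest at 1 — as
defined by the format-descriptor tables in the I/O module; that
descriptor *is* the package's definition of bit-exactness. Files are
ASCII with LF endings and no trailing whitespace, profiles ordered
row-major and countries sorted, so reruns are byte-identical. The
companion reader is tolerant (whitespace-tokenized, header-driven,
unknown trailing columns preserved) and round-trips everything the
writer emits at printed precision. The optional trailing `SADC` column
is omitted.

## Synthetic fixtures

`generate_input_stack()` emulates the statistical structure the
pipeline assumes: spatially correlated fields built by Gaussian kernel
smoothing of white noise (the algorithm is pinned in the package rather
than delegated to a library, so seeded output is stable across
versions), texture closed to exactly 100 % per pixel, organic carbon
log-scaled positive and decaying with depth, bulk density in 900–1800
kg m⁻³, pH in 4–9, CEC increasing with clay, and a contiguous
low-lying nodata region shared by all properties, emulating a
coastline. The `three-zone` preset lays out clayey/loamy/sandy vertical
bands whose constructed classes the downstream classification should
recover — the recovery is a test, not a tautology, because noise,
aggregation and renormalization intervene. The generator reproduces
plausible marginal ranges and spatial smoothness; it does **not**
emulate the true global covariance of any real soil database, depth
discontinuities, or survey artifacts, so green tests demonstrate
pipeline correctness, not fidelity of any particular soil map.

Tests run the pipeline on grids between 20×20 and 60×60 fine pixels
with 10×10 aggregation blocks — sizes chosen so the full suite
exercises every path (nodata, partial blocks, all three presets) while
each landscape still contains tens of coarse cells; the mechanisms
asserted (variance reduction, closure, determinism) are scale-free.

## Known limitations

* All inputs must share one grid; there is no reprojection.
* The rooting-depth lookup and the fertility/texture thresholds are
  reconstructions or package defaults, clearly marked as configuration;
  conclusions sensitive to them should vary them.
* The packaged templates are synthetic stand-ins (above).
* Aggregation uncertainty is not quantified; only the variance
  diagnostic is provided.
* Grid-derived properties are aggregated per property, independently;
  no co-aggregation scheme (dominant soil type, area weighting beyond
  the block mean) is offered.
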
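# gensol

Crop simulation models such as DSSAT simulate one soil profile at a
time, and need that profile as a `*.SOL` text file: water retention
limits, saturated conductivity, a per-layer root growth factor, surface
parameters. Gridded soil databases provide none of these directly —
they map the easy-to-measure properties (sand, silt, clay, organic
carbon, bulk density, pH, CEC) on six standard depth intervals (0–5,
5–15, 15–30, 30–60, 60–100, 100–200 cm). `gensol` is for crop modellers
and agro-ecosystem researchers who need to run gridded simulations over
regions where no measured profile data exist: it turns property grids
into complete, model-ready soil profile files, one per coarse grid
cell, partitioned into per-country `*.SOL` files.

The chain, per grid cell:

1. **Pedo-transfer functions** (Saxton–Rawls). With sand `S` and clay
   `C` as fractions and organic matter `OM = 2 × OC` in %, wilting
   point θ₁₅₀₀ (`SLLL`), field capacity θ₃₃ (`SDUL`) and saturation θS
   (`SSAT`) come from the published regressions, and saturated
   conductivity from

   `KS = 1930 (θS − θ₃₃)^(3−λ)` mm h⁻¹,  `λ = 1/B`,
   `B = [ln 1500 − ln 33] / [ln θ₃₃ − ln θ₁₅₀₀]`.

   Out-of-domain output (very sandy / very clayey soils) is clamped to
   a stated validity domain and flagged, never silently emitted.
2. **Generic-profile classification.** Texture (clay/loam/sand),
   fertility (topsoil organic carbon) and rooting depth (available
   water content of the top metre, `AWC = 1000 (SDUL − SLLL) Zr`,
   looked up per texture) select one of 27 generic profiles
   `HC_GEN0001`…`HC_GEN0027`, which contribute the surface parameters,
   root growth factor and total nitrogen.
3. **Layer remapping.** Template values on the seven generic-profile
   layers are transferred to the six output layers by fixed weighted
   averages (e.g. 60–100 cm ← 0.75 × 90 cm layer + 0.25 × 120 cm
   layer).
4. **Aggregation.** Fine pixels are averaged to coarse cells
   (arithmetic block mean, default 10×10) with a minimum-valid-fraction
   rule and exact re-closure of the texture simplex.
5. **Output.** Fixed-width `*.SOL` records, `-99` for
   model-default fields, byte-identical across reruns, one file per
   country.

A seeded synthetic-grid generator (`generate_input_stack()`) emulates
the input statistics — correlated fields, texture closure, nodata
coastlines — so the whole pipeline runs and is tested without any
download.

## Worked example

Build profiles for a synthetic landscape with clayey, loamy and sandy
zones and two countries:

```r
library(gensol)

spec  <- fixture_spec(nrow = 40, ncol = 60, seed = 42,
                      preset = "three-zone", nodata_fraction = 0.1)
stack <- generate_input_stack(spec)
mask  <- generate_country_mask(spec, block = 10, n_countries = 2)
build <- sol_build_pipeline(stack, out_dir = "out", mask = mask)
build
#> <sol_build> 22 profiles from 24 coarse cells (2 skipped, ptf_stage=fine)
build$files
#> # A tibble: 2 × 3
#>   iso   file       n_profiles
#>   <chr> <chr>           <int>
#> 1 AA    out/AA.SOL         12
#> 2 AB    out/AB.SOL         10
```

22 of the 24 coarse cells had enough valid fine pixels to be built (the
2 skipped cells sit on the synthetic coastline); each country file
holds that country's profiles. The per-cell classification is a tibble:

```r
dplyr::count(tidy(build), texture, fertility, depth)
#> # A tibble: 7 × 4
#>   texture fertility depth       n
#>   <chr>   <chr>     <chr>   <int>
#> 1 CLAY    HIGH      MEDIUM      3
#> 2 CLAY    MEDIUM    MEDIUM      5
#> 3 LOAM    HIGH      MEDIUM      2
#> 4 LOAM    MEDIUM    MEDIUM      6
#> 5 SAND    HIGH      SHALLOW     1
#> 6 SAND    LOW       SHALLOW     1
#> 7 SAND    MEDIUM    SHALLOW     4
```

The three constructed zones come back as the three texture classes;
sandy cells hold less plant-available water, so they classify shallow.
The emitted file is a regular DSSAT soil file:

```
*AA00000000  GENSOL      C       200 clay high medium generic profile
@SITE        COUNTRY          LAT     LONG SCS FAMILY
 Grid        AA            -0.042   30.042 Generic
@ SCOM  SALB  SLU1  SLDR  SLRO  SLNF  SLPF  SMHB  SMPX  SMKE
    BN  0.13  10.0  0.25  85.0  1.00  1.00 IB001 IB001 IB001
@  SLB  SLMH  SLLL  SDUL  SSAT  SRGF  SSKS  SBDM  SLOC  SLCL  SLSI  SLCF  SLNI  SLHW  SLHB  SCEC
     5     A 0.307 0.426 0.514 1.000  0.16  1.26  1.61  52.0  28.1   -99 0.150   6.4   -99  25.4
    15     A 0.307 0.427 0.513 0.952  0.15  1.28  1.47  52.0  28.1   -99 0.135   6.4   -99  25.4
```

Here `SLLL 0.307` / `SDUL 0.426` / `SSAT 0.514` cm³ cm⁻³ are the
derived wilting point, field capacity and saturation of a clay layer;
`SRGF` tapers with depth from the inherited generic profile; `-99` in
`SLCF`/`SLHB` tells the model to use its defaults. `read_sol()` parses
any such file back; `autoplot()` on a profile draws its water-retention
depth curves, and on a build maps the classification.

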
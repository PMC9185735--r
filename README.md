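# ecoclim

Compare-locations ecoclimatic niche modelling in the CLIMEX tradition,
with a shipped parameter set for the entomopathogenic nematode
*Heterorhabditis indica*.

Entomopathogenic nematodes are soil-dwelling biocontrol agents whose
infective juveniles kill insect pests. Where such an organism can
establish is largely a question of climate: soil temperature and soil
moisture drive population growth, while cold winters, hot spells,
drought and waterlogging kill accumulated stock. `ecoclim` turns
long-term monthly climate normals into an annual **Ecoclimatic Index**
(EI, 0–100) per location or grid cell, for survey planning and release
siting: which regions are climatically suitable, what limits the range
where it is not, and when in the year populations grow.

## The model

For each location, monthly normals (Tmax, Tmin, precipitation, RH at
09:00 and 15:00) are interpolated to a 52-week year and a weekly
soil-moisture series `SM` (fraction of field capacity) is derived with a
single-layer bucket model. Weekly growth is

    TI_w = trapezoid(Tmean_w; DV0, DV1, DV2, DV3)
    MI_w = trapezoid(SM_w;    SM0, SM1, SM2, SM3)
    GI_w = TI_w × MI_w,   GI_A = 100 × mean(GI_w)

and four stresses accumulate beyond their thresholds at weekly rates,
each weekly increment being `rate × exceedance × run-length` (run
length = successive stressed weeks, counted across the year boundary):
cold (Tmin < TTCS), heat (Tmean > TTHS), dry (SM < SMDS), wet
(SM > SMWS). The annual index is

    EI = GI_A × Π_s max(0, 1 − min(S_s, 1))

so any stress total reaching 1 is lethal. Classes: EI = 0 unsuitable,
< 10 marginal, 10–19 suitable, ≥ 20 very suitable; regional area
summaries count cells with EI ≥ 1 as climatically suitable.

The shipped *H. indica* parameters: DV0–DV3 = 18, 25, 30, 33 °C;
SM0–SM3 = 0.08, 0.1, 0.7, 1.7; TTCS = 11 °C, THCS = 0.0002;
TTHS = 36 °C, THHS = 0.0003; SMDS = 0.08, HDS = 0.001; SMWS = 1.7,
HWS = 0.003.

Because no real climate surface is bundled, the package includes a
synthetic Köppen–Geiger archetype generator (Af, Aw, BWh, Csa, Cfb,
Dfb) producing normals, grids and presence-only occurrence records with
the seasonal structure the model consumes, so every stage is testable
offline. See `vignettes/ecoclimatic-model.Rmd` for the full methods
account, including the bucket-hydrology design and its limits.

## Worked example

```r
library(ecoclim)
p <- load_species_parameters(
  system.file("extdata", "heterorhabditis_indica.params", package = "ecoclim"))

# a leeward wet-tropics climate (uniform 2000 mm rain)
nadi_like <- generate_archetype_normals("Af", lat = -18, label = "wet tropics (Af)")
run_location(nadi_like, p)
#> Ecoclimatic model result for wet tropics (Af) (Heterorhabditis indica)
#>   EI = 41.5 (very_suitable), annual GI = 41.5, stress index = 1.000
#>   stresses: cold 0.0000, heat 0.0000, dry 0.0000, wet 0.0000 (limiting: none)
```

EI 41.5 with zero stress: growth is moisture-limited (soil sits above
the 0.7 optimum most weeks) but nothing kills the population — a very
suitable climate. A windward counterpart with a pronounced 2400 mm wet
season shows the characteristic rainfall penalty:

```r
suva_like <- generate_archetype_normals(
  archetype_spec("Af", annual_rainfall = 2400, rainfall_shape = "summer-peak",
                 seasonal_amplitude = 2), lat = -18, label = "wet season (Af)")
growth_curve(suva_like, p)
#> Growth curve for wet season (Af): annual GI 37.9, EI 12.1
#>   stressful period: weeks 44-21 (30 weeks)
```

Wet stress (0.68) cuts EI to 12.1 — merely suitable — and the growth
index is depressed through the high-rainfall weeks: rainfall relates
negatively to growth, and release timing should avoid the wet-season
trough. On a grid:

```r
g <- generate_grid(matrix(c("Af", "Csa", "Aw", "Dfb"), 2, 2),
                   block = 2, resolution = 0.5, origin = c(177, -16))
r <- run_grid(g, p)
r
#> Suitability raster: 4 x 4 cells, 16 land cells (Heterorhabditis indica)
#>   EI: min 0.0, median 23.7, max 81.2; suitable (EI >= 1): 75.0% of land cells
#>   classes: unsuitable 4, marginal 4, suitable 0, very_suitable 8
regional_area_summary(r)
#>   region total_area_mkm2 suitable_area_mkm2 pct_suitable
#> 1     Af      0.01187020         0.01187020    100.00000
#> ...
#> 5  World      0.04735644         0.03554842     75.06566
export_map(r, "suitability")   # writes suitability.tif (+ sidecars) and .png
```

Cold-continental (Dfb) cells score EI = 0 with cold stress ≥ 1 as the
limiting factor; occurrence records can be checked against the raster
with `verify_occurrences()` (fraction of presences in EI > 0 cells).

A command-line front end covering the same stages
(`synth`, `run`, `verify`, `summarize`, `curve`) ships in
`inst/cli/ecoclim.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","ecoclim.R",package="ecoclim"))')" \
  synth --config config.yaml
```

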
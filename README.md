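# frugalNPZD

A desk-scale water-column ecosystem model for studying what happens to
marine biogeochemistry when phytoplankton stop being Redfieldian.

## The problem

Low-complexity plankton ecosystem models (NPZD: nutrients, phytoplankton,
zooplankton, detritus) almost universally hard-wire the elemental
composition of organic matter to the Redfield ratio — 16 mol nitrogen per
mol phosphorus — both in what the phytoplankton build and in the threshold
that decides whether nitrogen or phosphorus limits growth. In strongly
phosphate-depleted seas this assumption produces dissolved nutrient fields
and limitation patterns that disagree with observations: real phytoplankton
are *frugal* with phosphorus where it is scarce, packing more nitrogen per
unit phosphorus into their biomass.

`frugalNPZD` implements that frugality as a drop-in stoichiometry policy
and provides everything needed to quantify its consequences: a
mass-conservative NPZD model with three plankton functional types
(diatom-like, flagellate-like, nitrogen-fixing cyanobacteria-like), a
compiled 0-D box / 1-D column integrator, synthetic seasonal forcing
presets for a co-limited western and a phosphate-starved eastern
open-sea regime, twin-simulation experiment drivers, and diagnostics for
nutrient ratios, limitation climatologies, deep chlorophyll maxima and
Taylor-diagram model skill. The package is aimed at biogeochemical
modellers who want to isolate the stoichiometric mechanism from the
3-D circulation it is usually entangled with.

## The model in brief

The internal P:N molar uptake ratio is either fixed,

```
iRfr = 1/16                      (policy "redfield")
```

or linear in ambient phosphate (the empirical "line of frugality" for
P:C, divided by a constant N:C of 144 permil):

```
iRfr = (6.9 * PO4 + 6) / 144     (policy "lof")
```

so the N:P of newly produced organic matter falls from 24 at PO4 = 0 and
crosses 16 at PO4 = 3/6.9 ≈ 0.435 mmol m⁻³. Growth of each functional
type is limited by the Liebig minimum of squared Michaelis–Menten factors

```
nlim = (NH4 + NO3)² / (α² + (NH4 + NO3)²)
plim = PO4² / ((iRfr·α)² + PO4²)
```

and a light term, scaled by a Q10 temperature factor. Because `iRfr`
appears inside `plim`, the nitrogen/phosphorus limitation boundary itself
moves with ambient phosphate under the `lof` policy. Every organic pool
carries an explicit phosphorus ledger next to its nitrogen pool, so
variable composition propagates through grazing, mortality and
remineralization without creating or destroying mass; nitrogen fixation is
tracked in its own ledger, making conservation audits exact.

## Worked example

Twin simulations of the phosphate-starved eastern regime — identical
forcing, grid and parameters, only the stoichiometry policy differs:

```r
library(frugalNPZD)

lof <- stoichiometryPolicy("lof")
round(npOM(lof, c(0, 0.1, 3/6.9, 1)), 3)
#> [1] 24.000 21.525 16.000 11.163

tw <- experimentTwin("siteB", years = 3, seed = 1)
keep <- !isSpinup(tw$lof)

sprintf("mean surface chl  rfr: %.3f  lof: %.3f mg/m3",
        mean(surfaceMean(tw$rfr)[keep]), mean(surfaceMean(tw$lof)[keep]))
#> "mean surface chl  rfr: 0.184  lof: 0.263 mg/m3"

sprintf("surface chl anomaly (lof - rfr): %.3f mg/m3", tw$anomaly$meanSurface)
#> "surface chl anomaly (lof - rfr): 0.079 mg/m3"

sprintf("percent of time P-limited (lof): %.1f",
        tw$limitation$lof$percentPLimited)
#> "percent of time P-limited (lof): 100.0"

d <- dcmMetrics(tw$lof)
sprintf("summer DCM: %.0f m, %.2f mg/m3 (mixed layer %.0f m)",
        d$depth, d$intensity, d$mldMean)
#> "summer DCM: 115 m, 0.31 mg/m3 (mixed layer 35 m)"

tw$lof
#> NpzdRun: scenario 'siteB', policy 'lof', 25 layers x 1095 snapshots
#>   dt 0.01 d, seed 1, spin-up 1 yr, version 0.2.0
#>   assays: phyN1, phyN2, phyN3, phyP1, phyP2, phyP3, zooN, zooP, detN,
#>   detP, no3, nh4, po4, chl
```

Reading the numbers: the surface layer of this regime is phosphate-limited
at every post-spin-up snapshot; the frugal policy packs more nitrogen (and
hence chlorophyll, at a fixed Chl:N of 1.6 mg per mmol) onto the same
phosphorus supply, raising mean surface chlorophyll from 0.184 to
0.263 mg m⁻³; and during summer stratification a deep chlorophyll maximum
of 0.31 mg m⁻³ sits at 115 m, far below the ~35 m mixed layer. The run
object is a `SummarizedExperiment` subclass — depth layers × daily
snapshots per tracer — with the full parameter set, forcing, seed and flux
ledgers in its metadata.

Other entry points: `runSimulation()` for single runs,
`experimentNoCyano()` (nitrogen-fixer removal), `experimentRiver()`
(×5 river nutrient-load perturbations), `makeReference()` +
`skillStats()` for Taylor-diagram skill, `writeRunTables()` for CSV/JSON
export, and a thin command-line wrapper in `inst/scripts/npzd-cli.R`.
The methods vignette (`vignettes/frugal-stoichiometry.Rmd`) documents the
model equations, parameter defaults, numerics and design decisions.

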
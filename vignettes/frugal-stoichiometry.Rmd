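---
title: "Variable-stoichiometry NPZD modelling with frugalNPZD"
author: "frugalNPZD authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variable-stoichiometry NPZD modelling with frugalNPZD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frugalNPZD)
```

# The scientific problem

In most low-complexity marine biogeochemical models the elemental
composition of plankton is frozen at the Redfield ratio: 16 mol of nitrogen
per mol of phosphorus, both in the organic matter produced and in the
threshold that decides which nutrient limits growth. In strongly
P-depleted marginal seas this assumption misbehaves: observed dissolved
N:P ratios far exceed 16, organic matter is nitrogen-enriched, and models
that insist on 16:1 both distort the simulated nutrient fields and
misplace the nitrogen/phosphorus limitation boundary.

An empirical alternative is the *line of frugality*: across the world
ocean, the P:C content of particulate organic matter rises approximately
linearly with ambient phosphate, while N:C is nearly constant. Dividing
the two lines yields a phosphate-dependent internal P:N uptake ratio —
phytoplankton are frugal with phosphorus exactly where it is scarce.
`frugalNPZD` implements this rule inside a
nutrient–phytoplankton–zooplankton–detritus (NPZD) ecosystem model and
provides the twin-simulation machinery (one run with the fixed ratio, one
with the variable ratio, identical in everything else) plus the
diagnostics needed to compare them.

# The stoichiometry rules

The internal P:N molar ratio of newly produced organic matter,
`iRfr`, is either

* **redfield**: `iRfr = 1/16`, independent of the environment, or
* **lof**: `iRfr = (6.9 * PO4 + 6) / 144`,

where `PO4` is ambient phosphate in mmol m^-3, `6.9` and `6` are the slope
(permil per mmol P m^-3) and intercept (permil) of the P:C-vs-phosphate
line, and `144` permil is the constant N:C ratio. The organic-matter N:P
ratio `npOM = 1/iRfr` therefore falls from a maximum of `144/6 = 24` at
zero phosphate and crosses the Redfield value 16 at
`PO4 = 3/6.9 ≈ 0.435` mmol m^-3:

```{r}
lof <- stoichiometryPolicy("lof")
npOM(lof, c(0, 0.1, 3 / 6.9, 1))
```

Nutrient limitation uses squared Michaelis–Menten factors with a Liebig
minimum rule. With `D = NH4 + NO3` and a per-type half-saturation `alpha`
(in nitrogen units),

* `nlim = D^2 / (alpha^2 + D^2)`
* `plim = PO4^2 / ((iRfr * alpha)^2 + PO4^2)`

and the smaller factor scales growth. The phosphorus half-saturation is
the nitrogen half-saturation rescaled by the uptake ratio, so under the
`lof` policy the nitrogen/phosphorus decision boundary itself moves with
ambient phosphate: the identity of the limiting nutrient reduces to the
comparison `PO4 < iRfr * D`, independent of `alpha`. The printed source
for the phosphorus factor is typographically ambiguous about its
exponents; the squared form was adopted because it mirrors the nitrogen
factor exactly and because the half-saturation term is only dimensionally
meaningful as a squared phosphorus-unit quantity. Both factors equal 0.5
exactly at their respective half-saturation points, which the tests
exploit.

Two water-column diagnostics follow the field conventions: `npWater` is
nitrate over phosphate (nitrate only, no ammonium), with an `NA` sentinel
where phosphate is zero so gridded diagnostics never abort; `npOM` of a
simulation is the ratio of summed organic N to summed organic P ledgers.

# The ecosystem model

Three plankton functional types are carried in nitrogen currency: a
fast-growing, sinking, nutrient-hungry **diatom**; a slower **flagellate**
efficient at low nutrients; and a slow, warm-adapted **cyanobacterium**
that can fix dinitrogen. Each type grows as

```
growth_i = muMax_i * fT(T) * min(nlim_i, plim_i, llim_i) * phyN_i
```

with `llim = I / (I + lightHalfSat)` and `fT` an exponential Q10 factor
(default Q10 = 2 about 10 °C). Nitrogen uptake is drawn from ammonium
first, then nitrate — the simplest rule consistent with a limitation term
that only sees their sum. Phosphorus uptake is `growth * iRfr(PO4)`.

**The phosphorus ledger.** The defining numerical commitment of the
package is that variable stoichiometry must not leak mass. Every organic
pool (each phytoplankton type, zooplankton, detritus) therefore carries an
explicit phosphorus ledger alongside its nitrogen pool. All transfers —
grazing, mortality, excretion, remineralization — move phosphorus at the
*actual* P:N ratio of the source pool, so non-Redfield composition
propagates unchanged through the food web and returns to the dissolved
pools at the stored ratio. Whether real zooplankton and detritus carry
variable stoichiometry is not resolved by the source analysis; carrying
full ledgers is the conservative superset, and it is what makes exact
conservation audits possible.

When the cyanobacterium's Liebig minimum would be nitrogen, the nitrogen
term is waived and the nitrogen shortfall is supplied from a tracked
fixed-N ledger — fixation only operates when nitrogen would otherwise
limit, consistent with the ecological argument that fixers outcompete
ordinary phytoplankton under low N:P. The ledger makes the bookkeeping
identity testable: total system nitrogen growth equals the ledger exactly.

Closure is ERGOM-heritage: Holling type III grazing on total phytoplankton
nitrogen partitioned by biomass, assimilation fraction `beta = 0.7` with
the rest to detritus, linear temperature-dependent excretion to the
dissolved pools, quadratic zooplankton mortality to detritus (quadratic
closure is what keeps the box model on a bounded seasonal cycle rather
than predator-prey blow-up). Detrital N and P remineralize with separate
first-order knobs; **their defaults are equal** (0.05 d^-1), deliberately:
with equal rates a fixed-Redfield run keeps every organic pool at exactly
16:1 at machine precision, a degeneracy the regression tests use to tell
the two policies apart structurally. Nitrification (NH4 to NO3) runs at
0.1 d^-1; in the discrete step it acts on post-uptake ammonium, giving
uptake priority while keeping the nitrogen budget closed. Chlorophyll is
diagnosed as `1.6 mg Chl (mmol N)^-1` times total phytoplankton nitrogen —
a single recorded conversion, adequate for the qualitative chlorophyll
diagnostics the package makes (no photoacclimation).

None of the process constants above are asserted by the source analysis;
they are a named, versioned preset (`npzdParams()`), every value is
overridable, and every run embeds the full set in its output metadata.

# Synthetic forcing and the scenario presets

The forcing generator fabricates the *statistical structure* of the
physical environment rather than any particular year: a sinusoidal
mixed-layer cycle (winter maximum, default peak day 45), a surface
irradiance cycle peaking at the summer solstice, a surface temperature
cycle peaking in August, exponential light attenuation with optional
chlorophyll self-shading, and a two-valued vertical diffusivity — high
(100 m^2 d^-1) above the mixed layer, background (0.2 m^2 d^-1) below,
a contract the forcing validity method enforces at a factor of at least
100. Optional seeded AR(1) weather noise (decorrelation 10 d) can perturb
the mixed layer and irradiance; it is off by default so twin experiments
are exactly periodic. Nutrient renewal is by relaxation of nitrate and
phosphate towards deep-reservoir values below 200 m (timescale 30 d),
standing in for the advective supply a 1-D column cannot represent.

Two open-sea presets bracket the regimes of interest:

* **siteA** — co-limited north-western regime: deep NO3 8.0 and deep PO4
  0.44 mmol m^-3 (deep N:P ≈ 18), winter convection to 180 m, SST 13–25 °C.
* **siteB** — strongly P-depleted eastern regime: deep NO3 4.6 and deep
  PO4 0.16 mmol m^-3 (deep N:P ≈ 29), winter convection to 200 m, warmer
  and optically clearer.

The deep and initial surface nutrient values are initialization constants
for the regimes being emulated. The siteB winter mixed-layer maximum of
200 m was set to reach the restored reservoir: with the restoring horizon
fixed at 200 m, a shallower winter mixed layer leaves a permanently
unmixed gap in which the nutricline equilibrates just out of reach, winter
entrainment vanishes, and the scenario cannot express the winter/spring
bloom that defines it. Deep winter mixing of this order is documented for
the Levantine intermediate-water formation areas. A third preset,
`adriatic_river`, is a coastal column fed by a high-N:P river-like surface
nutrient flux (1.5 mmol N and 0.03 mmol P m^-2 d^-1), the substrate for
the ×5 nutrient-load perturbation experiment.

What the generator does **not** emulate: 3-D circulation and fronts,
episodic dense-water cascades, tides, interannual atmospheric variability,
and lateral river plumes (the river is a vertical flux into the top
layer). Conclusions from this package are therefore about the
*stoichiometric mechanism* — how a phosphate-dependent uptake ratio
reshapes nutrient pools, limitation patterns and chlorophyll in a
seasonally forced column — not about any real shoreline.

# Numerics

Each time step is operator-split in this order: explicit biological
fluxes, upwind sinking, implicit vertical diffusion, deep restoring,
boundary source.

* **Explicit biology with demand capping.** All sinks of a pool within a
  step are jointly rescaled by `available/demand` whenever demand exceeds
  the pool — capping the fluxes, not clipping the state, so the mass
  ledgers stay exact and no concentration can go negative. The step is
  first-order; the convergence test refines `dt` against a tiny-`dt`
  oracle run and checks the observed order. The default `dt = 0.01` d sits
  far inside the stability bound `dt < 0.25 / (max muMax * max fT)`, which
  is asserted at startup, as is the sinking CFL condition `w dt < dz`.
* **Implicit diffusion.** A flux-form tridiagonal (Thomas) solve per
  tracer; flux form plus zero-flux boundaries makes the scheme exactly
  conservative, which the spike test verifies to 1e-12.
* **Upwind sinking** for the diatom (0.5 m d^-1) and detritus (3 m d^-1),
  with no export through the sea floor: material reaching the bottom layer
  remineralizes there, keeping the column budget closed apart from the
  explicitly ledgered fluxes (fixation, restoring, boundary).
* **Tie-breaks and sentinels.** The DCM detector searches the mean
  stratified-season profile below the mean mixed layer, reports the
  shallower depth on ties, and flags surface-intensified profiles as
  having no DCM; `npWater` returns `NA` at zero phosphate; the
  limitation climatology breaks modal ties toward the nutrient with the
  smaller mean limitation factor.
* **Composition envelope.** Under the `lof` policy every organic pool's
  P:N stays inside the attainable uptake range `[1/24, 1/16]`, checked
  with a 1% upper tolerance: the siteA deep phosphate (0.44) sits
  marginally above the crossing concentration 0.435 at which the variable
  ratio equals 1/16, so residual light-limited uptake at depth can carry a
  pool about 0.4% past 1/16 by construction of the scenario constants.

Default problem sizes, chosen to match the analysis the package performs:
a 250 m column in 25 layers of 10 m (the depth range in which subsurface
chlorophyll maxima live), 8 simulated years of 365 days with the first
year flagged as spin-up, daily snapshots. A twin pair at these sizes runs
in well under a minute.

# Experiments and diagnostics

`experimentTwin()` embodies the central design: both policies are run over
*bit-identical* forcing (verified downstream through a forcing hash — the
"twin contract"), so any difference is attributable to the stoichiometry
rule alone. `experimentNoCyano()` removes the nitrogen fixer by setting
its maximum growth rate to exactly zero; `experimentRiver()` scales the
river-like boundary fluxes (×5 nitrate, ×5 phosphate, both), with the
cumulative boundary inputs ledgered so the perturbation is auditable.
`makeReference()` fabricates a noisy seasonal chlorophyll series for
exercising `skillStats()`, whose report (bias, correlation,
standard-deviation ratio, centered RMS difference, relative error
`mean(|ref - model|)/mean(ref)`) uses population-variance conventions so
the Taylor identity holds exactly and is asserted by the class validity
method.

The qualitative behaviour the test-suite pins down, all emergent rather
than prescribed: the frugal policy raises surface chlorophyll where the
system is co-limited (siteA) much more than where phosphate limitation is
overwhelming (siteB); the eastern preset is phosphate-limited essentially
always; both presets produce a winter/spring surface bloom and a summer
deep chlorophyll maximum below the mixed layer. What passing these tests
does *not* show: agreement with any satellite or in-situ magnitude, basin
means, or horizontal patterns — those require the 3-D circulation this
package deliberately replaces with synthetic forcing.

# Known limitations

* No carbon currency: N:C is collapsed into the constant 144 permil of the
  uptake rule, and chlorophyll is a fixed conversion from nitrogen.
* No oxygen, denitrification, sediment or carbonate chemistry.
* The ammonium-preference split, Q10 form, grazing and closure constants
  are plausible defaults, not calibrated values; conclusions should be
  tested for robustness across `npzdParams()` overrides (the positivity
  property test sweeps random parameter sets for exactly this reason).
* One zooplankton compartment; no size structure or diel vertical
  migration.
* The limitation climatology is computed from monthly-binned daily
  snapshots; shorter-lived limitation switches are averaged away.
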
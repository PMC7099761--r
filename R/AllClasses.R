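#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats approx rnorm filter
#' @importFrom utils modifyList write.csv packageVersion tail
#' @useDynLib frugalNPZD, .registration = TRUE
NULL

#' Stoichiometry policy: fixed Redfield or phosphate-dependent P:N uptake
#'
#' Encapsulates the rule that sets the internal P:N molar ratio of newly
#' produced organic matter. Under `mode = "redfield"` the ratio is the
#' constant 1/16. Under `mode = "lof"` (line of frugality) the ratio varies
#' linearly with ambient phosphate: the P:C content of organic matter follows
#' `slope * PO4 + intercept` (in permil), which divided by a constant N:C of
#' 144 permil gives `iRfr = (6.9 * PO4 + 6) / 144`.
#'
#' @slot mode `"redfield"` or `"lof"`.
#' @slot pToN constant P:N molar ratio used in redfield mode (1/16).
#' @slot lofSlope slope of the P:C vs phosphate line (permil per mmol P m^-3).
#' @slot lofIntercept intercept of the P:C line (permil).
#' @slot nToC constant N:C ratio (permil).
#'
#' @seealso [stoichiometryPolicy()], [iRfr()], [npOM()]
#' @exportClass StoichiometryPolicy
setClass("StoichiometryPolicy",
  representation(mode = "character", pToN = "numeric",
                 lofSlope = "numeric", lofIntercept = "numeric",
                 nToC = "numeric"),
  prototype(mode = "lof", pToN = 1 / 16, lofSlope = 6.9,
            lofIntercept = 6, nToC = 144))

setValidity("StoichiometryPolicy", function(object) {
  msg <- NULL
  if (length(object@mode) != 1L || !object@mode %in% c("redfield", "lof"))
    msg <- c(msg, "mode must be one of 'redfield', 'lof'")
  if (object@mode == "redfield" && !isTRUE(all.equal(object@pToN, 1 / 16)))
    msg <- c(msg, "pToN must be exactly 1/16 in redfield mode")
  if (any(c(object@lofSlope, object@lofIntercept, object@nToC) <= 0))
    msg <- c(msg, "lof constants must be strictly positive")
  if (object@nToC <= object@lofIntercept)
    msg <- c(msg, "nToC must exceed lofIntercept (keeps N:P_OM bounded)")
  if (is.null(msg)) TRUE else msg
})

#' Plankton functional type parameters
#'
#' Physiological constants for one of the three functional types. Rates are
#' daily; `muMax = 0` is allowed and is how the cyanobacteria-removal
#' experiment switches a type off.
#'
#' @slot name `"diatom"`, `"flagellate"` or `"cyanobacteria"`.
#' @slot muMax maximum growth rate (d^-1).
#' @slot alphaNutrient half-saturation constant for nutrients
#'   (mmol N m^-3); a single value shared by the N and P limitation terms,
#'   rescaled to phosphorus units by the P:N ratio.
#' @slot lightHalfSat light half-saturation (W m^-2).
#' @slot sinkingSpeed sinking velocity (m d^-1).
#' @slot mortalityRate linear mortality to detritus (d^-1).
#' @slot fixesNitrogen whether the type can fix dinitrogen (cyanobacteria
#'   only).
#'
#' @seealso [pftParams()], [defaultPftParams()]
#' @exportClass PftParams
setClass("PftParams",
  representation(name = "character", muMax = "numeric",
                 alphaNutrient = "numeric", lightHalfSat = "numeric",
                 sinkingSpeed = "numeric", mortalityRate = "numeric",
                 fixesNitrogen = "logical"))

setValidity("PftParams", function(object) {
  msg <- NULL
  if (!object@name %in% c("diatom", "flagellate", "cyanobacteria"))
    msg <- c(msg, "name must be diatom, flagellate or cyanobacteria")
  rates <- c(object@muMax, object@alphaNutrient, object@lightHalfSat,
             object@sinkingSpeed, object@mortalityRate)
  if (any(!is.finite(rates)) || any(rates < 0))
    msg <- c(msg, "all rates must be finite and >= 0")
  if (object@alphaNutrient <= 0 || object@lightHalfSat <= 0)
    msg <- c(msg, "half-saturation constants must be > 0")
  if (object@fixesNitrogen && object@name != "cyanobacteria")
    msg <- c(msg, "only cyanobacteria may fix nitrogen")
  if (is.null(msg)) TRUE else msg
})

#' Scenario preset: nutrient regime, boundary sources and forcing amplitudes
#'
#' Bundles the initialization constants and seasonal-forcing amplitudes of one
#' study site. `siteA` emulates a co-limited, nutrient-richer northwestern
#' regime (deep NO3 8.0, deep PO4 0.44 mmol m^-3); `siteB` a strongly
#' phosphate-depleted eastern regime (deep NO3 4.6, deep PO4 0.16);
#' `adriatic_river` a shallow coastal regime with a river-like surface
#' nutrient source.
#'
#' @slot name preset name.
#' @slot deepNO3,deepPO4 deep-reservoir nutrient concentrations (mmol m^-3).
#' @slot surfNO3,surfPO4 initial surface nutrient concentrations (mmol m^-3).
#' @slot nutriclineTop depth (m) above which initial nutrients take surface
#'   values; below, a linear ramp reaches the deep values at `restoreDepth`.
#' @slot mldMin,mldMax,mldPeakDay mixed-layer-depth cycle (m, m, day of year
#'   of the winter maximum).
#' @slot parMin,parMax surface photosynthetically available radiation cycle
#'   (W m^-2), summer maximum at day 172.
#' @slot sstMin,sstMax sea-surface temperature cycle (deg C), maximum at day
#'   233.
#' @slot tempDeep deep temperature (deg C).
#' @slot thermoclineScale e-folding scale (m) of the sub-mixed-layer
#'   temperature decay.
#' @slot kzHigh,kzBg vertical diffusivity above / below the mixed layer
#'   (m^2 d^-1).
#' @slot attenuationKw,attenuationKchl background light attenuation (m^-1)
#'   and chlorophyll self-shading coefficient (m^2 (mg Chl)^-1).
#' @slot boundaryNO3Flux,boundaryPO4Flux river-like surface nutrient fluxes
#'   (mmol m^-2 d^-1).
#' @slot restoreDepth,restoreTau depth (m) below which nutrients are relaxed
#'   to the deep reservoir, and the relaxation timescale (d).
#'
#' @seealso [scenarioPreset()], [scaleBoundarySource()], [makeForcing()]
#' @exportClass ScenarioPreset
setClass("ScenarioPreset",
  representation(name = "character",
                 deepNO3 = "numeric", deepPO4 = "numeric",
                 surfNO3 = "numeric", surfPO4 = "numeric",
                 nutriclineTop = "numeric",
                 mldMin = "numeric", mldMax = "numeric", mldPeakDay = "numeric",
                 parMin = "numeric", parMax = "numeric",
                 sstMin = "numeric", sstMax = "numeric",
                 tempDeep = "numeric", thermoclineScale = "numeric",
                 kzHigh = "numeric", kzBg = "numeric",
                 attenuationKw = "numeric", attenuationKchl = "numeric",
                 boundaryNO3Flux = "numeric", boundaryPO4Flux = "numeric",
                 restoreDepth = "numeric", restoreTau = "numeric"))

setValidity("ScenarioPreset", function(object) {
  msg <- NULL
  if (object@deepNO3 < 0 || object@deepPO4 < 0 ||
      object@surfNO3 < 0 || object@surfPO4 < 0)
    msg <- c(msg, "nutrient concentrations must be >= 0")
  if (object@mldMin <= 0 || object@mldMax < object@mldMin)
    msg <- c(msg, "need 0 < mldMin <= mldMax")
  if (object@kzHigh < 100 * object@kzBg)
    msg <- c(msg, "stratification contract: kzHigh must be >= 100 * kzBg")
  if (object@boundaryNO3Flux < 0 || object@boundaryPO4Flux < 0)
    msg <- c(msg, "boundary fluxes must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Synthetic seasonal forcing series
#'
#' Daily series of mixed-layer depth, surface irradiance and sea-surface
#' temperature over the run, plus the diffusivity and optical constants needed
#' to expand them into depth-resolved profiles. Sinusoidal seasonal cycles
#' with 365-day period; optional seeded red noise.
#'
#' @slot time sample times (days, daily resolution, starting at 0).
#' @slot mld mixed-layer depth (m), winter maximum.
#' @slot par surface photosynthetically available radiation (W m^-2).
#' @slot sst sea-surface temperature (deg C).
#' @slot kzHigh,kzBg diffusivity above / below the mixed layer (m^2 d^-1).
#' @slot attenuationKw,attenuationKchl light attenuation constants.
#' @slot tempDeep,thermoclineScale sub-mixed-layer temperature structure.
#' @slot mldRange admissible `[min, max]` for the mixed-layer depth.
#' @slot seed,noiseSd noise generation record.
#'
#' @seealso [makeForcing()], [kzProfile()]
#' @exportClass ForcingSeries
setClass("ForcingSeries",
  representation(time = "numeric", mld = "numeric", par = "numeric",
                 sst = "numeric", kzHigh = "numeric", kzBg = "numeric",
                 attenuationKw = "numeric", attenuationKchl = "numeric",
                 tempDeep = "numeric", thermoclineScale = "numeric",
                 mldRange = "numeric", seed = "numeric", noiseSd = "numeric"))

setValidity("ForcingSeries", function(object) {
  msg <- NULL
  n <- length(object@time)
  if (length(object@mld) != n || length(object@par) != n ||
      length(object@sst) != n)
    msg <- c(msg, "time, mld, par and sst must have equal length")
  if (any(object@mld < object@mldRange[1] - 1e-9) ||
      any(object@mld > object@mldRange[2] + 1e-9))
    msg <- c(msg, "mld outside its admissible range")
  if (any(object@par < 0)) msg <- c(msg, "par must be >= 0")
  if (object@kzHigh < 100 * object@kzBg)
    msg <- c(msg, "stratification contract: kzHigh must be >= 100 * kzBg")
  if (is.null(msg)) TRUE else msg
})

#' Vertical grid for the simulator
#'
#' Either a single well-mixed box (`mode = "box"`) or a 1-D column with
#' contiguous layers from the surface down.
#'
#' @slot mode `"box"` or `"column"`.
#' @slot edges layer edges (m), strictly increasing from 0.
#'
#' @seealso [npzdGrid()]
#' @exportClass NpzdGrid
setClass("NpzdGrid",
  representation(mode = "character", edges = "numeric"))

setValidity("NpzdGrid", function(object) {
  msg <- NULL
  if (!object@mode %in% c("box", "column"))
    msg <- c(msg, "mode must be 'box' or 'column'")
  e <- object@edges
  if (length(e) < 2 || e[1] != 0 || any(diff(e) <= 0))
    msg <- c(msg, "edges must start at 0 and be strictly increasing")
  if (object@mode == "box" && length(e) != 2)
    msg <- c(msg, "box mode must have a single layer")
  if (is.null(msg)) TRUE else msg
})

#' Simulation result container
#'
#' Extends [SummarizedExperiment::SummarizedExperiment]: one assay per tracer
#' field (three phytoplankton N pools and their internal P pools, zooplankton
#' N/P, detritus N/P, NO3, NH4, PO4) plus diagnosed chlorophyll, with rows =
#' depth layers (rowData: depth, thickness) and columns = saved time steps
#' (colData: time, year, month, spinup flag). `metadata()` carries the policy,
#' scenario, parameter set, forcing, seed, cumulative flux ledgers and a
#' version stamp — everything needed to audit conservation or re-run the
#' simulation bit-identically.
#'
#' @seealso [runSimulation()], [ledgers()], [surfaceMean()]
#' @exportClass NpzdRun
setClass("NpzdRun", contains = "SummarizedExperiment")

#' Model-vs-reference skill statistics
#'
#' The Taylor-diagram statistics plus mean bias and the relative error
#' `mean(|data - model|) / mean(data)`. Standard deviations and the centered
#' RMS difference use the population (1/n) convention so the Taylor identity
#' `crmsd^2 = sdModel^2 + sdReference^2 - 2 * sdModel * sdReference * corr`
#' holds exactly; the constructor asserts it to 1e-12.
#'
#' @slot bias mean(model - reference).
#' @slot correlation Pearson correlation, in `[-1, 1]`.
#' @slot sdModel,sdReference population standard deviations.
#' @slot sdRatio `sdModel / sdReference`.
#' @slot crmsd centered root-mean-square difference.
#' @slot relError `mean(|reference - model|) / mean(reference)`.
#' @slot n number of pairwise-complete observations used.
#'
#' @seealso [skillStats()]
#' @exportClass SkillReport
setClass("SkillReport",
  representation(bias = "numeric", correlation = "numeric",
                 sdModel = "numeric", sdReference = "numeric",
                 sdRatio = "numeric", crmsd = "numeric",
                 relError = "numeric", n = "integer"))

setValidity("SkillReport", function(object) {
  msg <- NULL
  if (is.finite(object@correlation) &&
      (object@correlation < -1 - 1e-12 || object@correlation > 1 + 1e-12))
    msg <- c(msg, "correlation must lie in [-1, 1]")
  lhs <- object@crmsd^2
  rhs <- object@sdModel^2 + object@sdReference^2 -
    2 * object@sdModel * object@sdReference * object@correlation
  if (is.finite(lhs) && is.finite(rhs) &&
      abs(lhs - rhs) > 1e-12 * max(1, abs(lhs), abs(rhs)))
    msg <- c(msg, "Taylor identity violated")
  if (is.null(msg)) TRUE else msg
})
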
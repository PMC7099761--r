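#' Canonical tracer field names
#'
#' Order used throughout the package for state matrices and assays: three
#' phytoplankton nitrogen pools, their internal phosphorus pools, zooplankton
#' N and P, detritus N and P, then dissolved nitrate, ammonium and phosphate.
#' @return Character vector of the 13 tracer names.
#' @export
stateFields <- function() {
  c("phyN1", "phyN2", "phyN3", "phyP1", "phyP2", "phyP3",
    "zooN", "zooP", "detN", "detP", "no3", "nh4", "po4")
}

.pftNames <- c("diatom", "flagellate", "cyanobacteria")

#' Construct parameters for one plankton functional type
#'
#' @param name `"diatom"`, `"flagellate"` or `"cyanobacteria"`.
#' @param muMax maximum growth rate (d^-1); 0 switches the type off (used by
#'   the cyanobacteria-removal experiment).
#' @param alphaNutrient nutrient half-saturation (mmol N m^-3).
#' @param lightHalfSat light half-saturation (W m^-2).
#' @param sinkingSpeed sinking velocity (m d^-1).
#' @param mortalityRate linear mortality to detritus (d^-1).
#' @param fixesNitrogen whether the type fixes dinitrogen when nitrogen would
#'   otherwise limit (cyanobacteria only).
#' @return A [PftParams-class] object.
#' @export
pftParams <- function(name, muMax, alphaNutrient, lightHalfSat,
                      sinkingSpeed = 0, mortalityRate = 0.05,
                      fixesNitrogen = FALSE) {
  new("PftParams", name = name, muMax = muMax,
      alphaNutrient = alphaNutrient, lightHalfSat = lightHalfSat,
      sinkingSpeed = sinkingSpeed, mortalityRate = mortalityRate,
      fixesNitrogen = fixesNitrogen)
}

setMethod("show", "PftParams", function(object) {
  cat(sprintf(
    "PftParams '%s': muMax %g/d, alpha %g mmol N/m3, Ih %g W/m2, w %g m/d%s\n",
    object@name, object@muMax, object@alphaNutrient, object@lightHalfSat,
    object@sinkingSpeed, if (object@fixesNitrogen) ", N-fixer" else ""))
})

#' Default functional-type parameter set
#'
#' ERGOM-heritage defaults: a fast-growing, sinking diatom with a relatively
#' high nutrient half-saturation; a slower non-sinking flagellate efficient at
#' low nutrients; a slow, warm-adapted nitrogen-fixing cyanobacterium.
#'
#' @return Named list of three [PftParams-class] objects.
#' @export
defaultPftParams <- function() {
  list(
    diatom        = pftParams("diatom", muMax = 1.8, alphaNutrient = 0.30,
                              lightHalfSat = 35, sinkingSpeed = 0.5),
    flagellate    = pftParams("flagellate", muMax = 1.0, alphaNutrient = 0.15,
                              lightHalfSat = 50),
    cyanobacteria = pftParams("cyanobacteria", muMax = 0.6,
                              alphaNutrient = 0.45, lightHalfSat = 60,
                              fixesNitrogen = TRUE))
}

#' Full ecosystem parameter set
#'
#' Assembles the versioned default parameter preset: the three functional
#' types, zooplankton closure, remineralization and nitrification rates, the
#' shared Q10 temperature factor, the chlorophyll conversion and detritus
#' sinking. Any element can be overridden; every run embeds the full set in
#' its output metadata.
#'
#' Defaults (daily rates): Holling-III grazing `gmax` 0.5, half-saturation
#' `kg` 0.5 mmol N m^-3, assimilation `beta` 0.7; zooplankton excretion 0.05,
#' quadratic mortality 0.3 (mmol N m^-3)^-1; detritus remineralization 0.05
#' for both N and P (equal by default so fixed-Redfield organic matter keeps
#' an exact 16:1 composition); nitrification 0.1; Q10 = 2 about a 10 deg C
#' reference; chlorophyll:N 1.6 mg Chl (mmol N)^-1; detritus sinking
#' 3 m d^-1.
#'
#' @param pfts list of three [PftParams-class] objects.
#' @param zoo,remin,temperature named lists overriding individual closure,
#'   remineralization or temperature constants.
#' @param chlToN chlorophyll-to-nitrogen conversion (mg Chl (mmol N)^-1).
#' @param detritusSinking detritus sinking speed (m d^-1).
#' @param fixation logical; master switch for dinitrogen fixation.
#' @return Named list with class `"npzdParams"`.
#' @export
npzdParams <- function(pfts = defaultPftParams(),
                       zoo = list(), remin = list(), temperature = list(),
                       chlToN = 1.6, detritusSinking = 3, fixation = TRUE) {
  stopifnot(length(pfts) == 3L,
            all(vapply(pfts, is, TRUE, "PftParams")))
  if (!identical(unname(vapply(pfts, function(p) p@name, "")), .pftNames))
    stop("pfts must be diatom, flagellate, cyanobacteria in that order")
  p <- list(
    pfts = pfts,
    zoo = utils::modifyList(
      list(gmax = 0.5, kg = 0.5, beta = 0.7, excretion = 0.05,
           mortalityQ = 0.3), zoo),
    remin = utils::modifyList(
      list(detN = 0.05, detP = 0.05, nitrification = 0.1), remin),
    temperature = utils::modifyList(list(q10 = 2, tref = 10), temperature),
    chlToN = chlToN,
    detritusSinking = detritusSinking,
    fixation = isTRUE(fixation),
    presetName = "frugalNPZD-default-1")
  stopifnot(p$zoo$beta >= 0, p$zoo$beta <= 1, chlToN > 0,
            detritusSinking >= 0)
  class(p) <- "npzdParams"
  p
}

#' @export
print.npzdParams <- function(x, ...) {
  cat("npzdParams preset '", x$presetName, "'\n", sep = "")
  for (p in x$pfts) show(p)
  cat(sprintf("  zoo: gmax %g, kg %g, beta %g, excr %g, mortQ %g\n",
              x$zoo$gmax, x$zoo$kg, x$zoo$beta, x$zoo$excretion,
              x$zoo$mortalityQ))
  cat(sprintf("  remin: detN %g, detP %g, nitrif %g; Q10 %g (Tref %g)\n",
              x$remin$detN, x$remin$detP, x$remin$nitrification,
              x$temperature$q10, x$temperature$tref))
  cat(sprintf("  chl:N %g mg/mmol, detritus sinking %g m/d, fixation %s\n",
              x$chlToN, x$detritusSinking, x$fixation))
  invisible(x)
}

# flat parameter list consumed by the compiled core
.corePars <- function(policy, params, scenario) {
  pf <- params$pfts
  list(
    mode = if (policy@mode == "redfield") 0L else 1L,
    pToN = policy@pToN, lofSlope = policy@lofSlope,
    lofIntercept = policy@lofIntercept, nToC = policy@nToC,
    muMax = vapply(pf, function(p) p@muMax, 0),
    alpha = vapply(pf, function(p) p@alphaNutrient, 0),
    ih = vapply(pf, function(p) p@lightHalfSat, 0),
    wsink = vapply(pf, function(p) p@sinkingSpeed, 0),
    mort = vapply(pf, function(p) p@mortalityRate, 0),
    fixes = vapply(pf, function(p) as.integer(p@fixesNitrogen), 0L),
    fixationOn = as.integer(params$fixation),
    gmax = params$zoo$gmax, kg = params$zoo$kg, beta = params$zoo$beta,
    zExcr = params$zoo$excretion, zMortQ = params$zoo$mortalityQ,
    rdn = params$remin$detN, rdp = params$remin$detP,
    nitrif = params$remin$nitrification,
    q10 = params$temperature$q10, tref = params$temperature$tref,
    kw = scenario$kw, kchl = scenario$kchl, chlToN = params$chlToN,
    wdet = params$detritusSinking,
    kzHigh = scenario$kzHigh, kzBg = scenario$kzBg,
    restoreDepth = scenario$restoreDepth, restoreTau = scenario$restoreTau,
    deepNO3 = scenario$deepNO3, deepPO4 = scenario$deepPO4,
    boundNO3 = scenario$boundNO3, boundPO4 = scenario$boundPO4,
    tempDeep = scenario$tempDeep, thermoclineScale = scenario$thermoclineScale)
}

# physics block with no transport and no sources: used by box mode and by
# the process-level functions where only biology matters
.nullScenario <- function(kw = 0.05, kchl = 0.03) {
  list(kw = kw, kchl = kchl, kzHigh = 100, kzBg = 0.2,
       restoreDepth = Inf, restoreTau = 0, deepNO3 = 0, deepPO4 = 0,
       boundNO3 = 0, boundPO4 = 0, tempDeep = 13, thermoclineScale = 40)
}

.checkState <- function(state) {
  if (is.null(dim(state))) state <- matrix(state, nrow = 1)
  state <- as.matrix(state)
  if (ncol(state) != 13L)
    stop("state must have 13 columns (see stateFields())", call. = FALSE)
  if (any(state < 0)) stop("state pools must be >= 0", call. = FALSE)
  colnames(state) <- stateFields()
  state
}

.fT <- function(temp, params) {
  params$temperature$q10^((temp - params$temperature$tref) / 10)
}

#' Phytoplankton growth tendency
#'
#' Per-type growth rate `muMax * fT(temp) * min(nlim, plim, llim) * phyN`
#' with `llim = light / (light + lightHalfSat)`, evaluated at the ambient
#' state (no demand capping; capping is a property of the time step, not of
#' the rate). Nitrogen uptake is drawn from ammonium first, then nitrate;
#' phosphorus uptake is `growth * iRfr(policy, po4)`. For a nitrogen-fixing
#' type whose Liebig minimum would be nitrogen, the nitrogen term is waived
#' and the nitrogen demand is met from the fixed-N ledger instead of the
#' dissolved pools.
#'
#' @param state numeric matrix (layers x 13, columns per [stateFields()]) or
#'   a single-layer vector.
#' @param light photosynthetically available radiation (W m^-2) per layer.
#' @param temp temperature (deg C) per layer.
#' @param policy a [StoichiometryPolicy-class].
#' @param params an [npzdParams()] set.
#' @return List of per-day rates: `growth` (layers x 3, mmol N m^-3 d^-1),
#'   `fixation`, `uptakeNH4`, `uptakeNO3`, `uptakeP` (per layer).
#' @export
growthTendency <- function(state, light, temp, policy, params = npzdParams()) {
  state <- .checkState(state)
  n <- nrow(state)
  fT <- .fT(temp, params)
  po4 <- state[, "po4"]
  irfr <- iRfr(policy, po4)
  growth <- matrix(0, n, 3, dimnames = list(NULL, .pftNames))
  fixation <- numeric(n)
  for (i in seq_len(3)) {
    p <- params$pfts[[i]]
    nl <- nLim(state[, "no3"], state[, "nh4"], p@alphaNutrient)
    pl <- pLim(po4, p@alphaNutrient, irfr)
    ll <- light / (light + p@lightHalfSat)
    waive <- p@fixesNitrogen & params$fixation & nl < pmin(pl, ll)
    lim <- ifelse(waive, pmin(pl, ll), pmin(nl, pl, ll))
    g <- p@muMax * fT * lim * state[, paste0("phyN", i)]
    growth[, i] <- g
    fixation <- fixation + ifelse(waive, g, 0)
  }
  uptakeDIN <- rowSums(growth) - fixation
  # instantaneous rates: ammonium supplies all uptake while it lasts
  uptakeNH4 <- ifelse(state[, "nh4"] > 0, uptakeDIN, 0)
  list(growth = growth, fixation = fixation,
       uptakeNH4 = uptakeNH4, uptakeNO3 = uptakeDIN - uptakeNH4,
       uptakeP = rowSums(growth) * irfr)
}

#' Grazing and zooplankton loss tendencies
#'
#' Holling type III functional response on total phytoplankton nitrogen,
#' partitioned over the three types in proportion to their biomass.
#' Phosphorus is transferred at each prey pool's actual P:N ratio, so
#' non-Redfield composition propagates unchanged into zooplankton (fraction
#' `beta`) and detritus (fraction `1 - beta`). Zooplankton excrete to the
#' dissolved pools at a linear rate and die quadratically to detritus, both
#' at the zooplankton pool's own P:N ratio.
#'
#' @inheritParams growthTendency
#' @param temp temperature (deg C) per layer.
#' @return List of per-day rates: `grazingN`, `grazingP` (layers x 3),
#'   `toZooN`, `toZooP`, `toDetN`, `toDetP`, `zooExcretionN`,
#'   `zooExcretionP`, `zooMortalityN`, `zooMortalityP`.
#' @export
grazingTendency <- function(state, temp, params = npzdParams()) {
  state <- .checkState(state)
  n <- nrow(state)
  fT <- .fT(temp, params)
  z <- params$zoo
  pn <- state[, paste0("phyN", 1:3), drop = FALSE]
  pp <- state[, paste0("phyP", 1:3), drop = FALSE]
  pt <- rowSums(pn)
  g <- ifelse(pt > 0,
              z$gmax * fT * pt^2 / (z$kg^2 + pt^2) * state[, "zooN"], 0)
  share <- pn / ifelse(pt > 0, pt, 1)
  grazingN <- share * g
  ratio <- ifelse(pn > 0, pp / pn, 0)
  grazingP <- grazingN * ratio
  zr <- ifelse(state[, "zooN"] > 0, state[, "zooP"] / state[, "zooN"], 0)
  exN <- z$excretion * fT * state[, "zooN"]
  moN <- z$mortalityQ * state[, "zooN"]^2
  list(grazingN = grazingN, grazingP = grazingP,
       toZooN = z$beta * rowSums(grazingN),
       toZooP = z$beta * rowSums(grazingP),
       toDetN = (1 - z$beta) * rowSums(grazingN),
       toDetP = (1 - z$beta) * rowSums(grazingP),
       zooExcretionN = exN, zooExcretionP = z$excretion * fT * state[, "zooP"],
       zooMortalityN = moN, zooMortalityP = moN * zr)
}

#' Remineralization and nitrification tendencies
#'
#' First-order return of detrital nitrogen to ammonium and detrital
#' phosphorus to phosphate, each with its own rate, so organic matter of
#' non-Redfield composition releases nutrients at its stored ratio.
#' Nitrification oxidizes ammonium to nitrate. All rates share the Q10
#' temperature factor.
#'
#' @inheritParams grazingTendency
#' @return List of per-day rates: `reminN`, `reminP`, `nitrification`.
#' @export
remineralizationTendency <- function(state, temp, params = npzdParams()) {
  state <- .checkState(state)
  fT <- .fT(temp, params)
  list(reminN = params$remin$detN * fT * state[, "detN"],
       reminP = params$remin$detP * fT * state[, "detP"],
       nitrification = params$remin$nitrification * fT * state[, "nh4"])
}

#' Chlorophyll diagnosed from phytoplankton nitrogen
#'
#' `chl = chlToN * sum(phytoplankton N pools)`, a single configurable linear
#' conversion recorded in run metadata.
#'
#' @inheritParams growthTendency
#' @param chlToN conversion factor (mg Chl (mmol N)^-1).
#' @return Chlorophyll (mg Chl m^-3) per layer.
#' @export
chlorophyllFromN <- function(state, chlToN = npzdParams()$chlToN) {
  state <- .checkState(state)
  chlToN * rowSums(state[, paste0("phyN", 1:3), drop = FALSE])
}

#' Advance the ecosystem by one biological step
#'
#' One explicit step of length `dt` of the biological terms only (no
#' transport), exactly as executed inside [runSimulation()]: all sinks of a
#' pool are demand-capped by the available mass so no concentration can go
#' negative, and the fixed-N ledger receives any nitrogen supplied by
#' fixation. Exposed for step-level testing and for building custom
#' integrators.
#'
#' @inheritParams growthTendency
#' @param dt step length (d).
#' @return List with the updated `state` matrix and all process fluxes
#'   (amounts over `dt`, mmol m^-3).
#' @export
stepEcosystem <- function(state, light, temp, dt, policy,
                          params = npzdParams()) {
  state <- .checkState(state)
  stopifnot(dt > 0)
  cpp_bio_fluxes(state, rep_len(light, nrow(state)),
                 rep_len(temp, nrow(state)), dt,
                 .corePars(policy, params, .nullScenario()))
}
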
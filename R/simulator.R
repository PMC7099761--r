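#' Build a vertical grid
#'
#' @param mode `"column"` for a 1-D water column, `"box"` for a single
#'   well-mixed layer with no transport (closed system apart from the
#'   fixed-N ledger).
#' @param depth total depth (m). The default 250 m column spans the depth
#'   range of interest for subsurface chlorophyll maxima (60-100 m).
#' @param nLayers number of equal layers in column mode (default 25).
#' @return An [NpzdGrid-class].
#' @export
npzdGrid <- function(mode = c("column", "box"), depth = if (mode == "box") 10 else 250,
                     nLayers = 25) {
  mode <- match.arg(mode)
  if (mode == "box") nLayers <- 1L
  new("NpzdGrid", mode = mode, edges = seq(0, depth, length.out = nLayers + 1))
}

setMethod("show", "NpzdGrid", function(object) {
  n <- length(object@edges) - 1
  cat(sprintf("NpzdGrid: %s, %d layer%s, 0-%g m\n", object@mode, n,
              if (n > 1) "s" else "", max(object@edges)))
})

.gridCenters <- function(grid) {
  e <- grid@edges
  (e[-1] + e[-length(e)]) / 2
}

.gridThickness <- function(grid) diff(grid@edges)

# initial profiles: surface values above the nutricline top, linear ramp to
# the deep reservoir at restoreDepth, deep values below; organic pools seeded
# small in the photic layer at Redfield composition
.initialState <- function(scenario, grid) {
  zc <- .gridCenters(grid)
  ramp <- function(surf, deep) {
    top <- scenario@nutriclineTop
    bot <- min(scenario@restoreDepth, max(grid@edges))
    w <- pmin(1, pmax(0, (zc - top) / max(bot - top, 1)))
    surf + (deep - surf) * w
  }
  photic <- ifelse(zc <= 100, 1, 0.1)
  seed <- 0.01 * photic
  state <- cbind(
    phyN1 = seed, phyN2 = seed, phyN3 = seed,
    phyP1 = seed / 16, phyP2 = seed / 16, phyP3 = seed / 16,
    zooN = seed, zooP = seed / 16,
    detN = 0 * zc, detP = 0 * zc,
    no3 = ramp(scenario@surfNO3, scenario@deepNO3),
    nh4 = 0.02 * photic,
    po4 = ramp(scenario@surfPO4, scenario@deepPO4))
  state
}

.monthOfDay <- function(time) {
  doy <- ((ceiling(time) - 1) %% 365) + 1
  ends <- cumsum(c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31))
  findInterval(doy, c(0, ends), left.open = TRUE)
}

.forcingHash <- function(forcing) {
  rlang::hash(list(forcing@time, forcing@mld, forcing@par, forcing@sst,
                   forcing@kzHigh, forcing@kzBg, forcing@attenuationKw,
                   forcing@attenuationKchl))
}

#' Run a twin-capable NPZD simulation
#'
#' Integrates the ecosystem under the given stoichiometry policy and
#' synthetic forcing. Each step is operator-split: explicit biology with
#' demand capping (no pool can go negative and all caps keep the mass
#' ledgers exact), upwind sinking of phytoplankton and detritus, implicit
#' vertical diffusion (flux-form tridiagonal solve, exactly conservative),
#' deep-reservoir nutrient restoring and the optional river-like surface
#' source. The run is deterministic given `(scenario, policy, years, seed)`;
#' two runs differing only in `policy` share bit-identical forcing (the twin
#' contract, checked by [chlAnomaly()] via a forcing hash).
#'
#' The explicit biological step requires `dt` below the stability bound
#' `0.25 / max growth rate`; the default `dt = 0.01` d is far inside it.
#'
#' @param scenario a [ScenarioPreset-class] or preset name.
#' @param policy a [StoichiometryPolicy-class].
#' @param years simulated years (365-day calendar); the first `spinupYears`
#'   are flagged as spin-up in the output.
#' @param seed integer seed (forcing noise; recorded in metadata).
#' @param grid an [NpzdGrid-class].
#' @param params an [npzdParams()] set.
#' @param dt time step (d).
#' @param saveEvery snapshot interval (d).
#' @param spinupYears years flagged as spin-up.
#' @param forcing optional pre-built [ForcingSeries-class] (must cover
#'   `years`); defaults to `makeForcing(scenario, years, seed, noiseSd)`.
#' @param noiseSd forcing weather-noise amplitude (fraction of seasonal
#'   amplitude; 0 = exact sinusoids).
#' @return An [NpzdRun-class].
#' @examples
#' \donttest{
#' run <- runSimulation("siteB", stoichiometryPolicy("lof"), years = 2)
#' surfaceMean(run, "chl")[1:5]
#' }
#' @export
runSimulation <- function(scenario = "siteA",
                          policy = stoichiometryPolicy("lof"),
                          years = 8, seed = 1,
                          grid = npzdGrid("column"),
                          params = npzdParams(),
                          dt = 0.01, saveEvery = 1, spinupYears = 1,
                          forcing = NULL, noiseSd = 0) {
  if (is.character(scenario)) scenario <- scenarioPreset(scenario)
  stopifnot(is(scenario, "ScenarioPreset"), is(policy, "StoichiometryPolicy"),
            is(grid, "NpzdGrid"), inherits(params, "npzdParams"),
            years > 0, dt > 0, saveEvery >= dt)
  if (is.null(forcing))
    forcing <- makeForcing(scenario, max(1, ceiling(years)), seed = seed,
                           noiseSd = noiseSd)
  stopifnot(is(forcing, "ForcingSeries"))
  if (max(forcing@time) < years * 365)
    stop("forcing series shorter than the requested run", call. = FALSE)

  # stability bound for the explicit biological step
  maxMu <- max(vapply(params$pfts, function(p) p@muMax, 0))
  maxFt <- params$temperature$q10 ^
    ((max(forcing@sst) - params$temperature$tref) / 10)
  if (dt * maxMu * maxFt > 0.25)
    stop(sprintf("dt = %g d exceeds the stability bound %.4g d", dt,
                 0.25 / (maxMu * maxFt)), call. = FALSE)

  nsteps <- round(years * 365 / dt)
  saveSteps <- max(1L, round(saveEvery / dt))
  h <- .gridThickness(grid)
  init <- .initialState(scenario, grid)
  phys <- list(
    kw = forcing@attenuationKw, kchl = forcing@attenuationKchl,
    kzHigh = forcing@kzHigh, kzBg = forcing@kzBg,
    restoreDepth = scenario@restoreDepth, restoreTau = scenario@restoreTau,
    deepNO3 = scenario@deepNO3, deepPO4 = scenario@deepPO4,
    boundNO3 = scenario@boundaryNO3Flux, boundPO4 = scenario@boundaryPO4Flux,
    tempDeep = forcing@tempDeep, thermoclineScale = forcing@thermoclineScale)
  res <- cpp_run(init, h, grid@mode == "column", dt, nsteps, saveSteps,
                 forcing@mld, forcing@par, forcing@sst,
                 .corePars(policy, params, phys))

  fields <- res$fields
  names(fields) <- c(stateFields(), "chl")
  time <- res$times
  ledg <- res$ledgers
  colnames(ledg) <- c("fixedN", "boundaryN", "boundaryP",
                      "restoringN", "restoringP")
  year <- ceiling(time / 365)
  cd <- S4Vectors::DataFrame(
    time = time, year = year, month = .monthOfDay(time),
    spinup = year <= spinupYears)
  rd <- S4Vectors::DataFrame(depth = .gridCenters(grid), thickness = h)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = fields, rowData = rd, colData = cd,
    metadata = list(
      policy = policy, scenario = scenario, params = params, grid = grid,
      forcing = forcing, forcingHash = .forcingHash(forcing),
      seed = seed, dt = dt, saveEvery = saveEvery,
      spinupYears = spinupYears, ledgers = ledg, nCaps = res$nCaps,
      finalState = res$final,
      version = as.character(utils::packageVersion("frugalNPZD"))))
  new("NpzdRun", se)
}

setMethod("show", "NpzdRun", function(object) {
  md <- S4Vectors::metadata(object)
  cat(sprintf("NpzdRun: scenario '%s', policy '%s', %d layers x %d snapshots\n",
              md$scenario@name, md$policy@mode, nrow(object), ncol(object)))
  cat(sprintf("  dt %g d, seed %g, spin-up %d yr, version %s\n",
              md$dt, md$seed, md$spinupYears, md$version))
  cat("  assays:", paste(SummarizedExperiment::assayNames(object),
                         collapse = ", "), "\n")
})

#' NpzdRun accessors
#'
#' Small accessors over the run container: metadata components, depth
#' geometry, cumulative flux ledgers and per-area mass totals.
#'
#' @param run an [NpzdRun-class].
#' @name run-accessors
NULL

#' @rdname run-accessors
#' @export
runPolicy <- function(run) S4Vectors::metadata(run)$policy

#' @rdname run-accessors
#' @export
runScenario <- function(run) S4Vectors::metadata(run)$scenario

#' @rdname run-accessors
#' @export
runParams <- function(run) S4Vectors::metadata(run)$params

#' @rdname run-accessors
#' @export
runForcing <- function(run) S4Vectors::metadata(run)$forcing

#' @rdname run-accessors
#' @export
depths <- function(run) SummarizedExperiment::rowData(run)$depth

#' @rdname run-accessors
#' @export
layerThickness <- function(run) SummarizedExperiment::rowData(run)$thickness

#' @rdname run-accessors
#' @export
runTime <- function(run) SummarizedExperiment::colData(run)$time

#' @rdname run-accessors
#' @export
isSpinup <- function(run) SummarizedExperiment::colData(run)$spinup

#' @rdname run-accessors
#' @export
ledgers <- function(run) {
  md <- S4Vectors::metadata(run)
  data.frame(time = runTime(run), md$ledgers)
}

#' @rdname run-accessors
#' @param name assay name (one of [stateFields()] or `"chl"`).
#' @export
fieldMatrix <- function(run, name) SummarizedExperiment::assay(run, name)

#' Depth-integrated nitrogen and phosphorus (mmol m^-2)
#'
#' Totals over all pools of each element at every snapshot; together with
#' [ledgers()] these support the conservation audit
#' `total(t) - total(0) == sum of ledger fluxes`.
#'
#' @param run an [NpzdRun-class].
#' @return Numeric vector over snapshots.
#' @export
totalNitrogen <- function(run) {
  h <- layerThickness(run)
  pools <- c("phyN1", "phyN2", "phyN3", "zooN", "detN", "no3", "nh4")
  Reduce(`+`, lapply(pools, function(f) colSums(fieldMatrix(run, f) * h)))
}

#' @rdname totalNitrogen
#' @export
totalPhosphorus <- function(run) {
  h <- layerThickness(run)
  pools <- c("phyP1", "phyP2", "phyP3", "zooP", "detP", "po4")
  Reduce(`+`, lapply(pools, function(f) colSums(fieldMatrix(run, f) * h)))
}

#' Surface (0-10 m) mean of a field
#'
#' Thickness-weighted mean over the layers whose centers lie within the top
#' `maxDepth` meters — the "surface" of all surface diagnostics.
#'
#' @param run an [NpzdRun-class].
#' @param name assay name.
#' @param maxDepth surface definition (m).
#' @return Numeric vector over snapshots.
#' @export
surfaceMean <- function(run, name = "chl", maxDepth = 10) {
  sel <- depths(run) <= maxDepth
  if (!any(sel)) sel <- seq_len(nrow(run)) == 1
  w <- layerThickness(run)[sel]
  colSums(fieldMatrix(run, name)[sel, , drop = FALSE] * w) / sum(w)
}

#' Write a run to plain-text tables
#'
#' Exports every assay as a wide CSV (rows = layers, columns = snapshots),
#' the ledgers as CSV, and a JSON metadata manifest (policy, scenario
#' constants, full parameter set, seed, forcing hash, version) sufficient to
#' re-run the simulation bit-identically.
#'
#' @param run an [NpzdRun-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
writeRunTables <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (a in SummarizedExperiment::assayNames(run)) {
    m <- fieldMatrix(run, a)
    df <- data.frame(depth = depths(run), m, check.names = FALSE)
    colnames(df) <- c("depth", sprintf("t%g", runTime(run)))
    utils::write.csv(df, file.path(dir, paste0(a, ".csv")), row.names = FALSE)
  }
  utils::write.csv(ledgers(run), file.path(dir, "ledgers.csv"),
                   row.names = FALSE)
  man <- runManifest(run)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man)
}

#' Machine-readable run manifest
#'
#' @param run an [NpzdRun-class].
#' @return List with the configuration hash, seed, policy, scenario
#'   constants, parameter preset and version stamp.
#' @export
runManifest <- function(run) {
  md <- S4Vectors::metadata(run)
  pol <- md$policy
  sc <- md$scenario
  cfg <- list(
    scenario = sc@name, policy = pol@mode,
    lofSlope = pol@lofSlope, lofIntercept = pol@lofIntercept,
    nToC = pol@nToC,
    deepNO3 = sc@deepNO3, deepPO4 = sc@deepPO4,
    boundaryNO3Flux = sc@boundaryNO3Flux, boundaryPO4Flux = sc@boundaryPO4Flux,
    years = max(runTime(run)) / 365, dt = md$dt, seed = md$seed,
    spinupYears = md$spinupYears,
    gridMode = md$grid@mode, gridDepth = max(md$grid@edges),
    nLayers = nrow(run),
    paramsPreset = md$params$presetName,
    pft = lapply(md$params$pfts, function(p) list(
      muMax = p@muMax, alpha = p@alphaNutrient, lightHalfSat = p@lightHalfSat,
      sinking = p@sinkingSpeed, mortality = p@mortalityRate,
      fixesNitrogen = p@fixesNitrogen)),
    zoo = md$params$zoo, remin = md$params$remin,
    temperature = md$params$temperature, chlToN = md$params$chlToN,
    fixation = md$params$fixation,
    forcingHash = md$forcingHash, version = md$version)
  cfg$configHash <- rlang::hash(cfg)
  cfg
}
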
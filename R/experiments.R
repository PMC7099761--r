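#' Twin-simulation experiment: fixed Redfield vs line of frugality
#'
#' Runs the redfield and line-of-frugality policies over bit-identical
#' forcing (built once and shared, which is the twin contract) and bundles
#' the paired runs with the chlorophyll anomaly (`lof - rfr`) and the
#' limitation statistics of each run.
#'
#' @param scenario a [ScenarioPreset-class] or preset name.
#' @param years,seed,grid,params,dt,noiseSd as in [runSimulation()].
#' @return List: `rfr`, `lof` ([NpzdRun-class]), `anomaly`
#'   (from [chlAnomaly()]), `limitation` (list `rfr`, `lof`), `manifest`.
#' @export
experimentTwin <- function(scenario = "siteA", years = 8, seed = 1,
                           grid = npzdGrid("column"), params = npzdParams(),
                           dt = 0.01, noiseSd = 0) {
  if (is.character(scenario)) scenario <- scenarioPreset(scenario)
  forcing <- makeForcing(scenario, years, seed = seed, noiseSd = noiseSd)
  rfr <- runSimulation(scenario, stoichiometryPolicy("redfield"),
                       years = years, seed = seed, grid = grid,
                       params = params, dt = dt, forcing = forcing)
  lof <- runSimulation(scenario, stoichiometryPolicy("lof"),
                       years = years, seed = seed, grid = grid,
                       params = params, dt = dt, forcing = forcing)
  list(rfr = rfr, lof = lof,
       anomaly = chlAnomaly(rfr, lof),
       limitation = list(rfr = limitationStats(rfr),
                         lof = limitationStats(lof)),
       manifest = list(rfr = runManifest(rfr), lof = runManifest(lof)))
}

#' Cyanobacteria-removal experiment
#'
#' Re-runs the line-of-frugality configuration with the cyanobacteria type
#' switched off by setting its maximum growth rate to exactly zero (its
#' biomass then only decays), over the same forcing as a baseline run, and
#' reports the surface-chlorophyll change. With the only nitrogen fixer
#' inert, the fixed-N ledger of the removal run stays identically zero.
#'
#' @inheritParams experimentTwin
#' @return List: `baseline`, `noCyano` ([NpzdRun-class]), `chl` (data.frame
#'   of post-spin-up mean surface chlorophyll and their difference),
#'   `fixedN` (final fixed-N ledger of each run, mmol m^-2).
#' @export
experimentNoCyano <- function(scenario = "siteA", years = 8, seed = 1,
                              grid = npzdGrid("column"),
                              params = npzdParams(), dt = 0.01) {
  if (is.character(scenario)) scenario <- scenarioPreset(scenario)
  forcing <- makeForcing(scenario, years, seed = seed)
  lof <- stoichiometryPolicy("lof")
  baseline <- runSimulation(scenario, lof, years = years, seed = seed,
                            grid = grid, params = params, dt = dt,
                            forcing = forcing)
  pfts <- params$pfts
  pfts$cyanobacteria@muMax <- 0
  paramsNC <- npzdParams(pfts = pfts, zoo = params$zoo, remin = params$remin,
                         temperature = params$temperature,
                         chlToN = params$chlToN,
                         detritusSinking = params$detritusSinking,
                         fixation = params$fixation)
  noCyano <- runSimulation(scenario, lof, years = years, seed = seed,
                           grid = grid, params = paramsNC, dt = dt,
                           forcing = forcing)
  keep <- !isSpinup(baseline)
  chl <- data.frame(
    run = c("baseline", "noCyano"),
    meanSurfaceChl = c(mean(surfaceMean(baseline)[keep]),
                       mean(surfaceMean(noCyano)[keep])))
  chl$difference <- c(NA, diff(chl$meanSurfaceChl))
  list(baseline = baseline, noCyano = noCyano, chl = chl,
       fixedN = c(baseline = utils::tail(ledgers(baseline)$fixedN, 1),
                  noCyano = utils::tail(ledgers(noCyano)$fixedN, 1)))
}

#' River nutrient-load perturbation experiment
#'
#' Runs the river-influenced scenario with its boundary nutrient source
#' scaled by each `(no3Factor, po4Factor)` pair — by default the identity
#' plus five-fold nitrate, five-fold phosphate and both — and tabulates the
#' post-spin-up mean surface chlorophyll and the cumulative boundary inputs
#' recorded in each run's ledger.
#'
#' @param scenario a river-influenced [ScenarioPreset-class] or preset name.
#' @param factors list of length-2 numeric vectors `c(no3Factor, po4Factor)`.
#' @inheritParams experimentTwin
#' @return List: `runs` (named [NpzdRun-class] list), `table` (data.frame
#'   with factors, mean surface chlorophyll, boundary N and P totals).
#' @export
experimentRiver <- function(scenario = "adriatic_river",
                            factors = list(c(1, 1), c(5, 1), c(1, 5), c(5, 5)),
                            years = 8, seed = 1, grid = npzdGrid("column"),
                            params = npzdParams(), dt = 0.01) {
  if (is.character(scenario)) scenario <- scenarioPreset(scenario)
  forcing <- makeForcing(scenario, years, seed = seed)
  lof <- stoichiometryPolicy("lof")
  runs <- list()
  rows <- list()
  for (f in factors) {
    sc <- scaleBoundarySource(scenario, f[1], f[2])
    key <- sprintf("no3x%g_po4x%g", f[1], f[2])
    run <- runSimulation(sc, lof, years = years, seed = seed, grid = grid,
                         params = params, dt = dt, forcing = forcing)
    runs[[key]] <- run
    keep <- !isSpinup(run)
    led <- ledgers(run)
    rows[[key]] <- data.frame(
      no3Factor = f[1], po4Factor = f[2],
      meanSurfaceChl = mean(surfaceMean(run)[keep]),
      boundaryN = utils::tail(led$boundaryN, 1),
      boundaryP = utils::tail(led$boundaryP, 1))
  }
  list(runs = runs, table = do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Fabricate a synthetic reference chlorophyll series
#'
#' A seasonal surface-chlorophyll series (winter/spring maximum) with
#' configurable mean, amplitude, phase and multiplicative lognormal noise,
#' standing in for an observational record when exercising the skill
#' statistics. Deterministic given `seed`.
#'
#' @param years length of the series (365-day years).
#' @param mean,amplitude mean and seasonal amplitude (mg Chl m^-3).
#' @param peakDay day of year of the seasonal maximum (default 75, early
#'   spring).
#' @param noiseSd standard deviation of the lognormal noise on the log scale
#'   (0 gives the exact sinusoid).
#' @param seed integer seed.
#' @return data.frame with `time` (days) and `chl` (mg m^-3).
#' @export
makeReference <- function(years = 7, mean = 0.2, amplitude = 0.15,
                          peakDay = 75, noiseSd = 0, seed = 0) {
  stopifnot(amplitude >= 0, mean > amplitude)
  time <- seq(1, years * 365)
  chl <- mean + amplitude * cos(2 * pi * ((time %% 365) - peakDay) / 365)
  if (noiseSd > 0) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    chl <- chl * exp(stats::rnorm(length(time), sd = noiseSd) - noiseSd^2 / 2)
  }
  data.frame(time = time, chl = chl)
}
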
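# Shared fixtures. Long column runs are computed once per test session and
# cached, since several independent diagnostics are checked on the same twin
# pairs.

.runCache <- new.env(parent = emptyenv())

cachedTwin <- function(site, years = 8, seed = 1) {
  key <- sprintf("twin_%s_%d_%d", site, years, seed)
  if (is.null(.runCache[[key]]))
    .runCache[[key]] <- experimentTwin(site, years = years, seed = seed)
  .runCache[[key]]
}

# random valid interior state away from pool depletion, for process tests
randomState <- function(n, seed) {
  set.seed(seed)
  cbind(
    matrix(runif(n * 3, 0.1, 1), n),        # phyN
    matrix(runif(n * 3, 0.1, 1) / 18, n),   # phyP
    runif(n, 0.1, 0.5), runif(n, 0.1, 0.5) / 16,  # zooN, zooP
    runif(n, 0, 1), runif(n, 0, 0.06),      # detN, detP
    runif(n, 0.1, 2), runif(n, 0.1, 0.5),   # no3, nh4
    runif(n, 0.02, 0.3))                    # po4
}

totalsN <- function(state) sum(state[, c(1:3, 7, 9, 11, 12)])
totalsP <- function(state) sum(state[, c(4:6, 8, 10, 13)])

# hand-constructed NpzdRun with prescribed fields, for diagnostics fixtures
makeFakeRun <- function(fields = list(), nTime = 730, nLayers = 1,
                        depth = 10, policy = stoichiometryPolicy("lof"),
                        scenario = scenarioPreset("siteA"),
                        params = npzdParams(), spinupYears = 1,
                        forcingSeed = 0) {
  grid <- if (nLayers == 1) npzdGrid("box", depth = depth) else
    npzdGrid("column", depth = depth, nLayers = nLayers)
  years <- max(1, ceiling(nTime / 365))
  forcing <- makeForcing(scenario, years, seed = forcingSeed)
  assays <- list()
  for (f in c(stateFields(), "chl")) {
    v <- if (!is.null(fields[[f]])) fields[[f]] else 0
    m <- matrix(v, nLayers, nTime, byrow = is.null(dim(v)) && length(v) == nTime)
    assays[[f]] <- m
  }
  if (is.null(fields[["chl"]]))
    assays[["chl"]] <- params$chlToN *
      (assays$phyN1 + assays$phyN2 + assays$phyN3)
  time <- seq_len(nTime)
  year <- ceiling(time / 365)
  cd <- S4Vectors::DataFrame(time = time, year = year,
                             month = frugalNPZD:::.monthOfDay(time),
                             spinup = year <= spinupYears)
  e <- grid@edges
  rd <- S4Vectors::DataFrame(depth = (e[-1] + e[-length(e)]) / 2,
                             thickness = diff(e))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowData = rd, colData = cd,
    metadata = list(policy = policy, scenario = scenario, params = params,
                    grid = grid, forcing = forcing,
                    forcingHash = frugalNPZD:::.forcingHash(forcing),
                    seed = forcingSeed, dt = 0.01, saveEvery = 1,
                    spinupYears = spinupYears,
                    ledgers = matrix(0, nTime, 5), nCaps = 0,
                    finalState = matrix(0, nLayers, 13),
                    version = "test-fixture"))
  new("NpzdRun", se)
}
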
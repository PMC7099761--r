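lof <- stoichiometryPolicy("lof")

# zero-rate parameter set: biology inert, physics only
zeroBio <- function() {
  pfts <- defaultPftParams()
  for (k in seq_along(pfts)) {
    pfts[[k]]@muMax <- 0
    pfts[[k]]@mortalityRate <- 0
    pfts[[k]]@sinkingSpeed <- 0
  }
  npzdParams(pfts = pfts,
             zoo = list(gmax = 0, excretion = 0, mortalityQ = 0),
             remin = list(detN = 0, detP = 0, nitrification = 0),
             detritusSinking = 0, fixation = FALSE)
}

physOnlyPars <- function(params, kzHigh = 100, kzBg = 0.2) {
  phys <- list(kw = 0.04, kchl = 0, kzHigh = kzHigh, kzBg = kzBg,
               restoreDepth = Inf, restoreTau = 0, deepNO3 = 0, deepPO4 = 0,
               boundNO3 = 0, boundPO4 = 0, tempDeep = 13,
               thermoclineScale = 40)
  frugalNPZD:::.corePars(lof, params, phys)
}

test_that("implicit diffusion of a spike conserves mass exactly", {
  n <- 25
  h <- rep(10, n)
  init <- matrix(0, n, 13)
  init[8, 9] <- 5                        # detrital N spike at 75 m
  res <- frugalNPZD:::cpp_run(init, h, TRUE, 0.1, 300, 300,
                              rep(120, 31), rep(50, 31), rep(15, 31),
                              physOnlyPars(zeroBio()))
  prof <- res$final[, 9]
  expect_equal(sum(prof * h), 5 * 10, tolerance = 1e-12)
  expect_true(all(prof >= 0))
  expect_lt(max(prof), 5)                # spike has spread out
  expect_gt(prof[1], 0)                  # reached the surface (mld 120 m)
})

test_that("upwind sinking moves detritus at the prescribed speed", {
  n <- 25
  h <- rep(10, n)
  init <- matrix(0, n, 13)
  init[3, 9] <- 2; init[3, 10] <- 0.1    # spike at 25 m
  params <- zeroBio()
  params$detritusSinking <- 5
  res <- frugalNPZD:::cpp_run(init, h, TRUE, 0.01, 2000, 2000,
                              rep(120, 31), rep(0, 31), rep(15, 31),
                              physOnlyPars(params, kzHigh = 0, kzBg = 0))
  prof <- res$final[, 9]
  zc <- seq(5, 245, by = 10)
  expect_equal(sum(prof * h), 2 * 10, tolerance = 1e-12)   # no bottom export
  com0 <- 25
  com <- sum(zc * prof * h) / sum(prof * h)
  expect_equal(com - com0, 5 * 20, tolerance = 10 / (5 * 20))  # +- one layer
})

test_that("runs are deterministic and twins share bit-identical forcing", {
  r1 <- runSimulation("siteB", lof, years = 1, seed = 3, dt = 0.02,
                      noiseSd = 0.1)
  r2 <- runSimulation("siteB", lof, years = 1, seed = 3, dt = 0.02,
                      noiseSd = 0.1)
  expect_identical(fieldMatrix(r1, "chl"), fieldMatrix(r2, "chl"))
  expect_identical(ledgers(r1), ledgers(r2))
  tw <- cachedTwin("siteA")
  expect_identical(S4Vectors::metadata(tw$rfr)$forcingHash,
                   S4Vectors::metadata(tw$lof)$forcingHash)
  fa <- runForcing(tw$rfr); fb <- runForcing(tw$lof)
  expect_identical(mixedLayerDepth(fa), mixedLayerDepth(fb))
  expect_identical(surfacePar(fa), surfacePar(fb))
  # ... while the ecosystems differ
  expect_false(identical(fieldMatrix(tw$rfr, "chl"),
                         fieldMatrix(tw$lof, "chl")))
})

test_that("ledger identity: mass change equals the sum of tracked fluxes", {
  run <- cachedTwin("siteA")$lof
  tn <- totalNitrogen(run); tp <- totalPhosphorus(run)
  led <- ledgers(run)
  ledN <- led$fixedN + led$boundaryN + led$restoringN
  ledP <- led$boundaryP + led$restoringP
  i <- 10; j <- length(tn)
  expect_equal(tn[j] - tn[i], ledN[j] - ledN[i], tolerance = 1e-9)
  expect_equal(tp[j] - tp[i], ledP[j] - ledP[i], tolerance = 1e-9)
})

test_that("stability and CFL bounds are enforced at startup", {
  expect_error(runSimulation("siteA", lof, years = 1, dt = 0.2),
               "stability")
  params <- npzdParams(detritusSinking = 600)
  expect_error(runSimulation("siteA", lof, years = 1, dt = 0.04,
                             params = params), "CFL")
})

test_that("box runs under constant forcing stay bounded and non-negative", {
  p <- scenarioPreset("siteA", mldMin = 50, mldMax = 50, parMin = 80,
                      parMax = 80, sstMin = 18, sstMax = 18)
  run <- runSimulation(p, lof, years = 5, grid = npzdGrid("box"), dt = 0.02)
  chl <- as.numeric(fieldMatrix(run, "chl"))
  expect_true(all(is.finite(chl)))
  for (f in stateFields())
    expect_true(all(fieldMatrix(run, f) >= 0))
  y4 <- chl[(3 * 365 + 1):(4 * 365)]
  y5 <- chl[(4 * 365 + 1):(5 * 365)]
  # fixed point or bounded cycle: year 5 repeats year 4
  expect_equal(y5, y4, tolerance = 0.05)
})

test_that("run container exposes geometry, metadata and tables", {
  run <- cachedTwin("siteA")$lof
  expect_s4_class(run, "NpzdRun")
  expect_equal(length(depths(run)), 25)
  expect_equal(sum(layerThickness(run)), 250)
  expect_identical(policyMode(runPolicy(run)), "lof")
  expect_identical(runScenario(run)@name, "siteA")
  expect_true(all(c("time", "fixedN", "boundaryN") %in% colnames(ledgers(run))))
  expect_true(any(isSpinup(run)) && !all(isSpinup(run)))
  man <- runManifest(run)
  expect_true(all(c("seed", "configHash", "forcingHash", "version",
                    "pft") %in% names(man)))
  d <- file.path(tempdir(), "npzd_tables_test")
  on.exit(unlink(d, recursive = TRUE))
  writeRunTables(run, d)
  expect_true(file.exists(file.path(d, "chl.csv")))
  expect_true(file.exists(file.path(d, "ledgers.csv")))
  man2 <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_identical(man2$configHash, man$configHash)
})
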
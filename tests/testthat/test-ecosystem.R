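lof <- stoichiometryPolicy("lof")
rfr <- stoichiometryPolicy("redfield")

test_that("growth follows mu_max * fT * Liebig * biomass with uptake ledgers", {
  params <- npzdParams()
  state <- randomState(1, 11)
  # switched-off type grows exactly zero (the removal-experiment mechanism)
  pfts <- defaultPftParams()
  pfts$diatom@muMax <- 0
  g <- growthTendency(state, light = 50, temp = 18, lof,
                      npzdParams(pfts = pfts))
  expect_equal(g$growth[, "diatom"], 0, ignore_attr = TRUE)
  expect_gt(g$growth[, "flagellate"], 0)
  # no phosphate, no growth for non-fixers (plim = 0); the fixer is also
  # stopped because fixation waives nitrogen, not phosphorus
  s0 <- state
  s0[, 13] <- 0
  g0 <- growthTendency(s0, 50, 18, lof, params)
  expect_true(all(g0$growth == 0))
  # P drawn per unit N uptake is the policy ratio: smaller under lof at
  # po4 = 0.05 than the fixed 1/16
  s1 <- state
  s1[, 13] <- 0.05
  gl <- growthTendency(s1, 50, 18, lof, params)
  gr <- growthTendency(s1, 50, 18, rfr, params)
  expect_equal(gl$uptakeP / sum(gl$growth), (6.9 * 0.05 + 6) / 144,
               ignore_attr = TRUE)
  expect_equal(gr$uptakeP / sum(gr$growth), 1 / 16, ignore_attr = TRUE)
  expect_lt(gl$uptakeP / sum(gl$growth), gr$uptakeP / sum(gr$growth))
})

test_that("nitrogen fixation waives only the nitrogen term, to a ledger", {
  params <- npzdParams()
  state <- randomState(1, 3)
  state[, 11] <- 0; state[, 12] <- 0   # no DIN at all
  g <- growthTendency(state, 80, 22, lof, params)
  expect_equal(g$growth[, "diatom"], 0, ignore_attr = TRUE)
  expect_equal(g$growth[, "flagellate"], 0, ignore_attr = TRUE)
  expect_gt(g$growth[, "cyanobacteria"], 0)
  expect_equal(g$fixation, g$growth[, "cyanobacteria"], ignore_attr = TRUE)
  expect_equal(g$uptakeNO3 + g$uptakeNH4, 0, ignore_attr = TRUE)
  # master switch off: the fixer is nitrogen-limited like the others
  g2 <- growthTendency(state, 80, 22, lof, npzdParams(fixation = FALSE))
  expect_true(all(g2$growth == 0))
})

test_that("grazing transfers phosphorus at the prey's actual composition", {
  params <- npzdParams()
  # zero phytoplankton, zero grazing
  state <- randomState(1, 5)
  state[, 1:6] <- 0
  gr <- grazingTendency(state, 18, params)
  expect_true(all(gr$grazingN == 0) && gr$toDetN == 0)
  # prey at N:P = 24 reaches detritus and zooplankton at N:P = 24
  state <- randomState(1, 6)
  state[, 4:6] <- state[, 1:3] / 24
  gr <- grazingTendency(state, 18, params)
  expect_equal(gr$toDetN / gr$toDetP, 24)
  expect_equal(gr$toZooN / gr$toZooP, 24)
  expect_equal(rowSums(gr$grazingN) / rowSums(gr$grazingP), 24)
  # perfect assimilation routes nothing to detritus
  gr1 <- grazingTendency(state, 18, npzdParams(zoo = list(beta = 1)))
  expect_identical(gr1$toDetN, 0)
  expect_identical(gr1$toDetP, 0)
})

test_that("remineralization returns nutrients at the stored composition", {
  params <- npzdParams()
  state <- randomState(1, 7)
  state[, 9] <- 0                      # no detrital N
  r <- remineralizationTendency(state, temp = 10, params)
  expect_equal(r$reminN, 0, ignore_attr = TRUE)
  state[, 9] <- 2; state[, 10] <- 1    # det P = 1 at reference temperature
  r <- remineralizationTendency(state, temp = 10, params)
  expect_equal(r$reminP, params$remin$detP * 1, ignore_attr = TRUE)
  expect_equal(r$reminN / r$reminP,
               params$remin$detN / params$remin$detP * 2, ignore_attr = TRUE)
})

test_that("chlorophyll is a linear conversion of phytoplankton nitrogen", {
  state <- randomState(1, 8)
  state[, 1:3] <- 0
  expect_identical(chlorophyllFromN(state), 0)
  state[, 1:3] <- c(0.05, 0.03, 0.02)  # sums to 0.1
  expect_equal(chlorophyllFromN(state, 1.6), 0.16)
  expect_equal(chlorophyllFromN(state, 3.2), 2 * chlorophyllFromN(state, 1.6))
})

test_that("one biological step conserves N and P and respects positivity", {
  params <- npzdParams()
  for (seed in 1:5) {
    state <- randomState(8, seed)
    st <- stepEcosystem(state, light = runif(8, 1, 120),
                        temp = runif(8, 10, 26), dt = 0.01, lof, params)
    expect_true(all(st$state >= 0))
    expect_equal(totalsN(st$state) - totalsN(state), sum(st$fixation),
                 tolerance = 1e-12)
    expect_equal(totalsP(st$state), totalsP(state), tolerance = 1e-12)
  }
  # capping: a step that would overdraw phosphate empties it, never below 0
  state <- randomState(1, 9)
  state[, 13] <- 1e-6
  st <- stepEcosystem(state, 100, 25, dt = 1, lof, params)
  expect_gte(st$state[, 13], 0)
})

test_that("R process rates match the compiled kernel at interior states", {
  params <- npzdParams()
  dt <- 1e-6
  for (seed in c(21, 22, 23)) {
    state <- randomState(6, seed)
    light <- runif(6, 1, 100); temp <- runif(6, 12, 26)
    st <- stepEcosystem(state, light, temp, dt, lof, params)
    g <- growthTendency(state, light, temp, lof, params)
    gr <- grazingTendency(state, temp, params)
    rm <- remineralizationTendency(state, temp, params)
    expect_equal(st$growth / dt, g$growth, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(st$fixation / dt, g$fixation, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(st$uptakeP / dt, g$uptakeP, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(st$uptakeNH4 / dt, g$uptakeNH4, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(st$grazingN / dt, gr$grazingN, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(st$zooMortalityP / dt, gr$zooMortalityP, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(st$reminN / dt, rm$reminN, tolerance = 1e-10,
                 ignore_attr = TRUE)
    # nitrification acts on post-uptake ammonium in the discrete step, so it
    # agrees with the instantaneous rate to first order in dt
    expect_equal(st$nitrification / dt, rm$nitrification, tolerance = 1e-4,
                 ignore_attr = TRUE)
  }
})

test_that("pools stay non-negative over 10-year runs under random parameters", {
  set.seed(42)
  for (i in 1:3) {
    pfts <- defaultPftParams()
    for (k in seq_along(pfts)) {
      pfts[[k]]@muMax <- runif(1, 0.3, 2.5)
      pfts[[k]]@alphaNutrient <- runif(1, 0.05, 0.6)
      pfts[[k]]@mortalityRate <- runif(1, 0.01, 0.1)
    }
    params <- npzdParams(
      pfts = pfts,
      zoo = list(gmax = runif(1, 0.2, 1.2), kg = runif(1, 0.2, 1),
                 beta = runif(1, 0.4, 0.9), excretion = runif(1, 0.01, 0.1),
                 mortalityQ = runif(1, 0.05, 0.5)),
      remin = list(detN = runif(1, 0.02, 0.1), detP = runif(1, 0.02, 0.1),
                   nitrification = runif(1, 0.05, 0.2)))
    run <- runSimulation("siteA", lof, years = 10, seed = i,
                         grid = npzdGrid("box"), params = params, dt = 0.02)
    for (f in stateFields())
      expect_true(all(fieldMatrix(run, f) >= 0),
                  label = sprintf("non-negative %s (sweep %d)", f, i))
  }
})
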
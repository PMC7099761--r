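lof <- stoichiometryPolicy("lof")

test_that("limitation statistics recover constructed limitation records", {
  # phosphate always zero, nitrogen present: phosphorus-limited throughout
  r <- makeFakeRun(list(no3 = 1, nh4 = 0.1, po4 = 0, phyN1 = 0.1,
                        phyN2 = 0.1, phyN3 = 0.1))
  s <- limitationStats(r)
  expect_equal(s$percentPLimited, 100)
  expect_true(all(s$monthly$aggregate == "phosphorus"))
  # huge phosphate reservoir, scarce nitrogen: never phosphorus-limited
  r <- makeFakeRun(list(no3 = 0.01, nh4 = 0, po4 = 5, phyN1 = 0.1,
                        phyN2 = 0.1, phyN3 = 0.1))
  s <- limitationStats(r)
  expect_equal(s$percentPLimited, 0)
  expect_true(all(s$monthly$aggregate == "nitrogen"))
  # alternating record, phosphorus-limited on exactly half the saved steps
  alt <- rep(c(0, 5), length.out = 730)
  r <- makeFakeRun(list(no3 = 1, nh4 = 0, po4 = alt, phyN1 = 0.1,
                        phyN2 = 0.1, phyN3 = 0.1))
  for (def in c("biomass_weighted", "any_pft")) {
    s <- limitationStats(r, definition = def)
    expect_equal(s$percentPLimited, 50, tolerance = 0.01)
  }
})

test_that("biomass-weighted limitation lies within the per-type envelope", {
  run <- cachedTwin("siteA")$lof
  s <- limitationStats(run, definition = "biomass_weighted")
  expect_gte(s$percentPLimited, min(s$perPft) - 1e-9)
  expect_lte(s$percentPLimited, max(s$perPft) + 1e-9)
  expect_true(all(s$monthly$aggregate %in% c("nitrogen", "phosphorus")))
  expect_gte(s$percentPLimited, 0)
  expect_lte(s$percentPLimited, 100)
})

test_that("nutrient-ratio fields handle composition and sentinels", {
  # all-detritus organic matter at N:P = 2.4/0.1 = 24
  r <- makeFakeRun(list(detN = 2.4, detP = 0.1, no3 = 1.6, po4 = 0.1))
  f <- npFields(r)
  expect_true(all(abs(f$npOM - 24) < 1e-9))
  expect_true(all(abs(f$npWater - 16) < 1e-9))
  # zero phosphorus: sentinel, not infinity
  r <- makeFakeRun(list(detN = 1, detP = 0, no3 = 1, po4 = 0))
  f <- npFields(r)
  expect_true(all(is.na(f$npOM)))
  expect_true(all(is.na(f$npWater)))
})

test_that("twin anomaly is b minus a and enforces the twin contract", {
  a <- makeFakeRun(list(chl = 0.2))
  expect_equal(chlAnomaly(a, a)$meanSurface, 0)
  b <- makeFakeRun(list(chl = 0.3))
  an <- chlAnomaly(a, b)
  expect_equal(an$meanSurface, 0.1)
  expect_true(all(abs(an$surfaceSeries - 0.1) < 1e-12))
  expect_equal(an$profile, 0.1)
  # different forcing (different seed) violates the twin contract
  c <- makeFakeRun(list(chl = 0.3), forcingSeed = 99,
                   scenario = scenarioPreset("siteA", mldMax = 150))
  expect_error(chlAnomaly(a, c), "twin contract")
})

test_that("skill statistics satisfy the Taylor construction", {
  set.seed(1)
  r <- runif(200)
  self <- skillStats(r, r)
  expect_equal(skillBias(self), 0)
  expect_equal(skillCorrelation(self), 1)
  expect_equal(skillSdRatio(self), 1)
  expect_equal(skillCrmsd(self), 0)
  expect_equal(skillRelError(self), 0)
  # constant offset: bias only
  off <- skillStats(r + 0.3, r)
  expect_equal(skillBias(off), 0.3)
  expect_equal(skillCorrelation(off), 1)
  expect_equal(skillCrmsd(off), 0)
  # doubled zero-mean signal: correlation 1, sd ratio 2
  z <- r - mean(r)
  dbl <- skillStats(2 * z, z)
  expect_equal(skillCorrelation(dbl), 1)
  expect_equal(skillSdRatio(dbl), 2)
  # NaN masking is pairwise-complete
  m <- r + rnorm(200, sd = 0.1)
  m[c(3, 50)] <- NA; r2 <- r; r2[100] <- NaN
  sk <- skillStats(m, r2)
  expect_identical(sk@n, 197L)
  # Taylor identity on random pairs
  for (i in 1:20) {
    a <- rnorm(50); b <- rnorm(50, mean = a)
    sk <- skillStats(a, b)
    lhs <- skillCrmsd(sk)^2
    rhs <- sk@sdModel^2 + sk@sdReference^2 -
      2 * sk@sdModel * sk@sdReference * skillCorrelation(sk)
    expect_lt(abs(lhs - rhs), 1e-12 * max(1, lhs))
  }
})

test_that("DCM detector finds subsurface maxima and flags surface blooms", {
  depth <- seq(5, 245, by = 10)
  # constructed profile peaking in the layer centered at 93... nearest layer 95
  chl <- 0.1 + 0.3 * exp(-((depth - 95) / 25)^2)
  d <- dcmFromProfile(depth, chl, mld = 20)
  expect_true(d$present)
  expect_equal(d$depth, 95)
  expect_equal(d$intensity, max(chl))
  # monotone decreasing profile: no DCM
  d <- dcmFromProfile(depth, 0.5 * exp(-depth / 30), mld = 20)
  expect_false(d$present)
  expect_true(is.na(d$depth))
  # two equal maxima: the shallower is reported
  chl2 <- rep(0.1, length(depth))
  chl2[c(8, 12)] <- 0.4
  d <- dcmFromProfile(depth, chl2, mld = 20)
  expect_equal(d$depth, depth[8])
  # a constructed run whose profile peaks at 93 m
  nL <- 25
  prof <- 0.05 + 0.25 * exp(-((seq(5, 245, by = 10) - 93) / 20)^2)
  r <- makeFakeRun(list(chl = matrix(prof, nL, 730)), nLayers = nL,
                   depth = 250)
  d <- dcmMetrics(r, months = 6:8)
  expect_true(d$present)
  expect_equal(d$depth, 95)   # nearest layer center to 93 m
})
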
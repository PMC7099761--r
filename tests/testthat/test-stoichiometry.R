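lof <- stoichiometryPolicy("lof")
rfr <- stoichiometryPolicy("redfield")

test_that("uptake P:N ratio follows the fixed and variable formulations", {
  expect_equal(iRfr(lof, 0), 6 / 144)
  expect_equal(iRfr(rfr, 0.5), 0.0625)
  expect_equal(iRfr(rfr, c(0, 1, 5)), rep(1 / 16, 3))
  # crossing with Redfield at po4 = 3/6.9, solved by hand from (6.9p+6)/144 = 1/16
  expect_equal(iRfr(lof, 3 / 6.9), 1 / 16, tolerance = 1e-15)
  # strictly increasing in phosphate
  po4 <- seq(0, 2, by = 0.01)
  expect_true(all(diff(iRfr(lof, po4)) > 0))
  expect_error(iRfr(lof, -0.1), "-0.1")
})

test_that("organic-matter N:P is the reciprocal ratio, peaking at 24", {
  expect_identical(npOM(lof, 0), 24)
  expect_equal(npOM(rfr, 0.37), 16)
  expect_equal(npOM(lof, 3 / 6.9), 16, tolerance = 1e-15)
  po4 <- seq(0, 2, by = 0.005)
  v <- npOM(lof, po4)
  expect_true(all(diff(v) < 0))           # strictly decreasing
  expect_true(all(v <= 24))
  expect_true(all(v[po4 > 0] < 24))       # equality only at po4 = 0
  expect_equal(v, 1 / iRfr(lof, po4))
  # redfield threshold: lof ratio below 1/16 iff po4 below the crossing
  expect_true(all((iRfr(lof, po4) < 1 / 16) == (po4 < 3 / 6.9)))
})

test_that("nitrogen limitation has squared Michaelis-Menten form", {
  expect_identical(nLim(0, 0, 0.3), 0)
  # half-saturation exactly at D = alpha, a property of the squared form
  expect_identical(nLim(0.12, 0.18, 0.3), 0.5)
  expect_identical(nLim(0.7, 0, 0.7), 0.5)
  expect_equal(nLim(0.4, 0.2, 0.3), 0.36 / (0.09 + 0.36))  # = 0.8 by hand
  d <- seq(0, 3, by = 0.01)
  v <- nLim(d, 0, 0.3)
  expect_true(all(v >= 0 & v < 1))
  expect_true(all(diff(v) > 0))
  expect_error(nLim(0.1, 0.1, 0), "alpha")
  expect_error(nLim(-1, 0, 0.3), ">= 0")
})

test_that("phosphorus limitation mirrors it with a rescaled half-saturation", {
  expect_identical(pLim(0, 0.3, 1 / 16), 0)
  expect_identical(pLim(0.3 / 16, 0.3, 1 / 16), 0.5)    # po4 = pToN * alpha
  expect_equal(pLim(0.05, 0.3, 1 / 16), 0.0025 / ((0.3 / 16)^2 + 0.0025))
  po4 <- seq(0, 0.5, by = 0.005)
  expect_true(all(diff(pLim(po4, 0.3, 1 / 16)) > 0))    # increasing in po4
  expect_true(all(pLim(0.05, 0.3, seq(0.02, 0.09, 0.01)) ==
                    cummin(pLim(0.05, 0.3, seq(0.02, 0.09, 0.01)))))
  expect_error(pLim(0.1, -1, 1 / 16), "alpha")
})

test_that("Liebig minimum rule picks the lower factor and flags ties", {
  r <- limitation(no3 = 0, nh4 = 0, po4 = 1, alpha = 0.3, policy = rfr)
  expect_identical(r$limiting, "nitrogen")
  expect_identical(r$factor, 0)
  r <- limitation(no3 = 1, nh4 = 0, po4 = 0, alpha = 0.3, policy = lof)
  expect_identical(r$limiting, "phosphorus")
  expect_identical(r$factor, 0)
  # constructed tie: D = 0.32 and po4 = 0.32/16 sit at equal saturation
  r <- limitation(no3 = 0.2, nh4 = 0.12, po4 = 0.02, alpha = 0.3, policy = rfr)
  expect_identical(r$limiting, "tie")
  expect_equal(r$nlim, r$plim)
  expect_equal(r$nlim, 0.32^2 / (0.3^2 + 0.32^2))
  expect_equal(r$factor, pmin(r$nlim, r$plim))
})

test_that("the limitation decision boundary moves with phosphate under lof", {
  # at low po4 the frugal ratio makes phosphorus less limiting than under
  # redfield for the same nutrient field
  pl_lof <- pLim(0.02, 0.3, iRfr(lof, 0.02))
  pl_rfr <- pLim(0.02, 0.3, 1 / 16)
  expect_gt(pl_lof, pl_rfr)
})

test_that("seawater N:P uses nitrate only and a sentinel at zero phosphate", {
  expect_equal(npWater(1.6, 0.1), 16)
  expect_identical(npWater(0, 0.1), 0)
  expect_identical(npWater(1, 0), NA_real_)
  expect_identical(npWater(c(1, 2), c(0.1, 0)), c(10, NA_real_))
})

test_that("policy object enforces its invariants", {
  expect_error(stoichiometryPolicy("lof", nToC = 5), "nToC")
  expect_error(stoichiometryPolicy("lof", lofSlope = -1), "positive")
  expect_error(stoichiometryPolicy("redfieldian"), "arg")
  expect_identical(policyMode(rfr), "redfield")
})
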
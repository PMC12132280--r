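test_that("aTc to dCas9 transfer is a bounded increasing Hill function", {
  p <- defP
  expect_equal(atcToDcas9(0, p), p[["d_basal"]])
  expect_equal(atcToDcas9(p[["theta_atc"]], p),
               p[["d_basal"]] + p[["d_max"]] / 2)
  grid <- seq(0, 60, by = 2)
  vals <- atcToDcas9(grid, p)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals <= p[["d_basal"]] + p[["d_max"]]))
  expect_lt(atcToDcas9(8, p), atcToDcas9(15, p))
  expect_error(atcToDcas9(-1, p), "non-negative")
})

test_that("dCas9 partition conserves the pool and matches trivial cases", {
  p <- defP
  Kd <- p[["Kd"]]
  expect_equal(unlist(dcas9Partition(0, 0, 10, p)),
               c(c1 = 0, c2 = 0, dFree = 10))
  sym <- dcas9Partition(Kd, Kd, 9, p)
  expect_equal(unlist(sym), c(c1 = 3, c2 = 3, dFree = 3))
  expect_error(dcas9Partition(-1, 0, 5, p), "non-negative")
  ## conservation over random triples
  set.seed(42)
  for (i in 1:200) {
    g1 <- stats::runif(1, 0, 100); g2 <- stats::runif(1, 0, 100)
    d <- stats::runif(1, 0, 50)
    pt <- dcas9Partition(g1, g2, d, p)
    expect_lt(abs(pt$c1 + pt$c2 + pt$dFree - d) / max(d, 1e-30), 1e-12)
  }
})

test_that("quasi-steady-state partition agrees with the mass-action oracle", {
  p <- defP
  cases <- list(c(2 * p[["Kd"]], 0.5 * p[["Kd"]], 7),
                c(10, 40, 12), c(0.3, 0.1, 30))
  for (cs in cases) {
    pt <- dcas9Partition(cs[1], cs[2], cs[3], p)
    eq <- bindingEquilibrium(cs[1], cs[2], cs[3], p[["Kd"]])
    expect_equal(pt$c1, eq[1], tolerance = 0.01)
    expect_equal(pt$c2, eq[2], tolerance = 0.01)
  }
})

test_that("raising the competing sgRNA strictly lowers the other complex", {
  p <- defP
  g1s <- seq(0.5, 40, length.out = 20)
  g2s <- seq(0, 40, length.out = 20)
  for (d in c(1, 8, 30)) {
    for (g1 in g1s) {
      c1s <- vapply(g2s, function(g2) dcas9Partition(g1, g2, d, p)$c1,
                    numeric(1))
      expect_true(all(diff(c1s) < 0))
    }
  }
})

test_that("inducer activity gates the transcription factor", {
  expect_equal(inducerActivity(5, 0, 10, 2), 0)
  expect_equal(inducerActivity(5, 10, 10, 2), 2.5)
  expect_equal(inducerActivity(5, Inf, 10, 2), 5)
  expect_error(inducerActivity(-1, 1, 10, 2), "non-negative")
})

test_that("promoter demand interpolates basal to maximal monotonically", {
  expect_equal(promoterDemand(0, 3, 150, 10, 3), 3)
  expect_equal(promoterDemand(10, 3, 150, 10, 3), 3 + 147 / 2)
  a <- seq(0, 100, length.out = 200)
  v <- promoterDemand(a, 3, 150, 10, 3)
  expect_true(all(diff(v) >= 0))
  expect_true(all(v >= 3 & v <= 150))
})

test_that("repression factor is 1 without complex and relieved by overlap", {
  expect_equal(repressionFactor(0, 4, 3), 1)
  expect_equal(repressionFactor(4, 4, 1), 0.5)
  ## Lux-box overlap: high activator weakens repression at fixed complex
  lo <- repressionFactor(8, 4, 3, a = 0, luxOverlap = TRUE, KaOverlap = 40)
  hi <- repressionFactor(8, 4, 3, a = 400, luxOverlap = TRUE, KaOverlap = 40)
  expect_gt(hi, lo)
  expect_error(repressionFactor(-1, 4, 3), "non-negative")
})

test_that("resource allocation throttles joint demand into the observed range", {
  p <- defP
  one <- resourceAllocation(20, 0, p)
  expect_equal(one$rho1, 20 / (1 + 20 / p[["J1"]]))
  expect_equal(one$rho2, 0)
  sym <- resourceAllocation(50, 50, p)
  expect_equal(sym$rho1, sym$rho2)
  ## each module's realized rate at maximal joint demand is 40-60% below
  ## its sole-module value (the competition magnitude the design targets)
  a1 <- p[["alpha1"]]
  sole <- resourceAllocation(a1, 0, p)$rho1
  both <- resourceAllocation(a1, p[["alpha2"]], p)$rho1
  expect_gt(1 - both / sole, 0.40)
  expect_lt(1 - both / sole, 0.60)
  ## rho1 strictly decreasing in the competing demand
  rhos <- vapply(seq(0, 150, length.out = 30),
                 function(P2) resourceAllocation(60, P2, p)$rho1, numeric(1))
  expect_true(all(diff(rhos) < 0))
})

test_that("the RHS has a fixed point at the origin without leak", {
  p0 <- circuitParams(basal1 = 0, basal2 = 0, d_basal = 0)
  f <- circuitRHS(statev(), dsaT, inducers(), p0)
  expect_equal(unname(f), rep(0, 4))
})

test_that("the non-targeting controller is exactly inert", {
  pz <- circuitParams(d_basal = 0)
  ind <- inducers(lAra = 2e-3, c6 = 40, atc = 0)   # atc 0, no leak
  set.seed(7)
  for (i in 1:50) {
    s <- statev(stats::runif(1, 0, 60), stats::runif(1, 0, 60),
                stats::runif(1, 0, 40), stats::runif(1, 0, 40))
    expect_identical(circuitRHS(s, dsaC, ind, pz),
                     circuitRHS(s, dsaT, ind, pz))
  }
})

test_that("sgRNA sequestration by the rival module relieves self-repression", {
  p <- defP
  d <- atcToDcas9(15, p)
  ## complex on module 1 with and without the competing guide
  withRival <- dcas9Partition(2, 30, d, p)$c1
  alone <- dcas9Partition(2, 0, d, p)$c1
  expect_lt(withRival, alone)
})

test_that("parameter validation rejects malformed sets", {
  expect_error(circuitParams(alpha1 = -5), "strictly positive")
  expect_error(circuitParams(nonsense = 1), "unknown parameter")
  expect_error(circuitParams(basal1 = 200), "basal1")
  expect_error(inducers(lAra = -1), "non-negative")
  expect_error(topology("XYZ"), "arg")
})
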
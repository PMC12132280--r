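test_that("per-cell parameter draws have the designed moments", {
  nm <- noiseModel(cvExtrinsic = 0.2)
  cp <- sampleCellParams(defP, nm, 10000, seed = 5)
  expect_equal(names(cp), c("alpha1", "alpha2", "K1", "K2"))
  ## lognormal multipliers have mean 1: sample mean within 3 s.e.
  se <- 0.2 * defP[["alpha1"]] / sqrt(10000)
  expect_lt(abs(mean(cp$alpha1) - defP[["alpha1"]]), 3 * se)
  ## zero CV collapses to the base parameters
  cp0 <- sampleCellParams(defP, noiseModel(cvExtrinsic = 0), 50, seed = 5)
  expect_true(all(cp0$K1 == defP[["K1"]]))
  ## seed determinism
  expect_identical(sampleCellParams(defP, nm, 100, seed = 9),
                   sampleCellParams(defP, nm, 100, seed = 9))
})

test_that("noise-free population collapses to the deterministic attractor", {
  sc <- studyConditions()$dsa_forward
  ind <- inducers(lAra = sc$l_ara, c6 = 0, atc = sc$atc)
  tab <- simulatePopulation(dsaC, ind, defP, noiseFree, nEvents = 100,
                            seed = 1)
  ev <- events(tab)
  ## all events identical
  expect_equal(max(ev$gfp) - min(ev$gfp), 0)
  expect_equal(max(ev$rfp) - min(ev$rfp), 0)
  ## and equal to the deterministic attractor readout (scale 10)
  ss <- attractorFromOff(dsaC, ind, defP)
  expect_equal(ev$gfp[1] / 10, ss@state[["x1"]], tolerance = 0.02)
  expect_equal(ev$rfp[1] / 10, ss@state[["x2"]], tolerance = 0.02)
})

test_that("population summaries converge to the deterministic limit as noise vanishes", {
  sc <- studyConditions()$dsa_forward
  ind <- inducers(lAra = sc$l_ara, c6 = 0, atc = sc$atc)
  ss <- attractorFromOff(dsaC, ind, defP)
  err <- vapply(c(0.1, 0.01, 0.001), function(cv) {
    nm <- noiseModel(cvExtrinsic = cv, sigmaMeas = 0, doubletFrac = 0,
                     autofluorGfp = 0, autofluorRfp = 0)
    tab <- simulatePopulation(dsaC, ind, defP, nm, nEvents = 300, seed = 2)
    abs(median(events(tab)$gfp) / 10 - ss@state[["x1"]])
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.5)
})

test_that("a population at intermediate C6 splits across quadrants", {
  sc <- studyConditions()$dsa_forward
  ind <- inducers(lAra = sc$l_ara, c6 = 20, atc = sc$atc)
  tab <- simulatePopulation(dsaC, ind, defP, noiseModel(), nEvents = 500,
                            seed = 3)
  fr <- quadrantFractions(tab, gateConfig())
  occupied <- sum(fr@mean > 0.05)
  expect_gte(occupied, 2)
})

test_that("population simulation is reproducible and seed-sensitive", {
  ind <- inducers(lAra = 1.25e-3, c6 = 100, atc = 15)
  a <- simulatePopulation(dsaT, ind, defP, noiseModel(), nEvents = 200,
                          seed = 7)
  b <- simulatePopulation(dsaT, ind, defP, noiseModel(), nEvents = 200,
                          seed = 7)
  c <- simulatePopulation(dsaT, ind, defP, noiseModel(), nEvents = 200,
                          seed = 8)
  expect_identical(events(a), events(b))
  expect_false(identical(events(a), events(c)))
})

test_that("quadrant fractions vary across seeds within binomial error", {
  ind <- inducers(lAra = 1.25e-3, c6 = 31.6, atc = 15)
  fr <- vapply(1:4, function(s) {
    tab <- simulatePopulation(dsaT, ind, defP, noiseModel(),
                              nEvents = 1000, seed = s)
    quadrantFractions(tab, gateConfig())@mean[["coactivation"]]
  }, numeric(1))
  pbar <- mean(fr)
  expect_true(all(abs(fr - pbar) < 4 * sqrt(pbar * (1 - pbar) / 1000)))
})

test_that("plate simulation recovers basal and repressed kinetics", {
  nm0 <- noiseModel(sigmaMeas = 0, cvExtrinsic = 0, autofluorGfp = 0,
                    autofluorRfp = 0)
  ## zero inducers: GFP/OD flat at the basal level
  ps <- simulatePlate(dsaC, inducers(), defP, nm0, horizon = 16, seed = 1)
  ratio <- ps@data$gfp / ps@data$od600
  lateHalf <- ps@data$time_h > 8
  expect_lt(diff(range(ratio[lateHalf])) / mean(ratio[lateHalf]), 0.15)
  expect_lt(mean(ratio[lateHalf]) / 10, defP[["theta_on1"]])
  ## targeting rises more slowly and saturates lower at intermediate L-ara
  ind <- inducers(lAra = 1.25e-3, c6 = 0, atc = 15)
  con <- simulatePlate(dsaC, ind, defP, nm0, horizon = 16, seed = 1)
  tar <- simulatePlate(dsaT, ind, defP, nm0, horizon = 16, seed = 1)
  rc <- con@data$gfp / con@data$od600
  rt <- tar@data$gfp / tar@data$od600
  expect_true(all(rt <= rc + 1e-9))
  expect_lt(rt[length(rt)], 0.6 * rc[length(rc)])
  ## halving dt changes the sampled series negligibly
  fine <- simulatePlate(dsaC, ind, defP, nm0, horizon = 16, dt = 0.125,
                        seed = 1)
  coarse <- con
  sharedT <- intersect(fine@data$time_h, coarse@data$time_h)
  fv <- fine@data$gfp[match(sharedT, fine@data$time_h)]
  cv <- coarse@data$gfp[match(sharedT, coarse@data$time_h)]
  expect_lt(max(abs(fv - cv) / pmax(cv, 1)), 0.01)
})
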
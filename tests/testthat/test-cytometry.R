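test_that("the singlet gate removes planted doublets and spares singlets", {
  mix <- plantedMixture(fractions = c(0.25, 0.25, 0.25, 0.25),
                        nEvents = 10000, doubletFrac = 0.05, seed = 21)
  gen <- generateFlow(mix)
  gate <- gateConfig()
  gated <- singletGate(gen$events, gate)
  kept <- meta(gated)$gateReport$keptIndex
  isDbl <- gen$truth$doublet
  removedDbl <- sum(isDbl[-kept]) / sum(isDbl)
  lostSinglets <- sum(!isDbl[-kept]) / sum(!isDbl)
  expect_gte(removedDbl, 0.95)
  expect_lte(lostSinglets, 0.02)
})

test_that("a fully open gate is the identity and an all-doublet table errors", {
  mix <- plantedMixture(nEvents = 500, doubletFrac = 0, seed = 3)
  gen <- generateFlow(mix)
  open <- gateConfig(fscRatioBand = c(0, Inf), minFsc = 0)
  gated <- singletGate(gen$events, open)
  expect_equal(nrow(events(gated)), 500)
  ## every event a doublet: gate leaves nothing
  allDbl <- eventTable(within(events(gen$events), fsc_a <- 3 * fsc_h))
  expect_error(singletGate(allDbl, gateConfig()), "singlet gate")
})

test_that("blank-quantile thresholds match the analytic lognormal quantile", {
  set.seed(9)
  n <- 10000
  ctrl <- eventTable(data.frame(
    fsc_a = rep(5e4, n), fsc_h = rep(5e4, n),
    gfp = stats::rlnorm(n, log(10), 0.3),
    rfp = stats::rlnorm(n, log(10), 0.3)))
  thr <- estimateThresholds(ctrl, quantile = 0.995)
  expect_equal(unname(thr[["gfp_thresh"]]),
               stats::qlnorm(0.995, log(10), 0.3), tolerance = 0.05)
  ## quantile 1 is the max; identical channels give identical thresholds
  thrMax <- estimateThresholds(ctrl, quantile = 1)
  expect_equal(unname(thrMax[["gfp_thresh"]]), max(events(ctrl)$gfp))
  ctrl2 <- eventTable(within(events(ctrl), rfp <- gfp))
  thr2 <- estimateThresholds(ctrl2)
  expect_equal(thr2[["gfp_thresh"]], thr2[["rfp_thresh"]])
  ## degenerate constant channel warns and applies the margin
  ctrl3 <- eventTable(within(events(ctrl), gfp <- 5))
  expect_warning(thr3 <- estimateThresholds(ctrl3), "constant")
  expect_equal(unname(thr3[["gfp_thresh"]]), 6)
})

test_that("quadrant classification follows threshold semantics exactly", {
  gate <- gateConfig(gfpThresh = 100, rfpThresh = 100)
  ev <- eventTable(data.frame(fsc_a = rep(5e4, 4), fsc_h = rep(5e4, 4),
                              gfp = c(1000, 10, 1000, 10),
                              rfp = c(10, 1000, 1000, 10)))
  fr <- quadrantFractions(ev, gate, applyGate = FALSE)
  expect_equal(unname(fr@mean),
               c(0.25, 0.25, 0.25, 0.25))
  ## all events below both thresholds
  lo <- eventTable(data.frame(fsc_a = 5e4, fsc_h = 5e4, gfp = 1, rfp = 1))
  frLo <- quadrantFractions(lo, gate, applyGate = FALSE)
  expect_equal(unname(frLo@mean), c(1, 0, 0, 0))
})

test_that("planted mixture fractions are recovered within binomial error", {
  fr <- c(OFF = 0.10, M1_only = 0.25, M2_only = 0.25, coactivation = 0.40)
  mix <- plantedMixture(fractions = fr, nEvents = 10000, doubletFrac = 0.05,
                        seed = 33)
  gen <- generateFlow(mix)
  est <- quadrantFractions(singletGate(gen$events, gateConfig()),
                           gateConfig())
  for (lab in names(fr)) {
    tol <- 3 * sqrt(fr[[lab]] * (1 - fr[[lab]]) / 10000)
    expect_lt(abs(est@mean[[lab]] - fr[[lab]]), tol + 0.005)
  }
})

test_that("fraction invariances hold: order, joint rescaling, sum to one", {
  mix <- plantedMixture(fractions = c(0.3, 0.3, 0.2, 0.2), nEvents = 2000,
                        seed = 12)
  ev <- events(generateFlow(mix)$events)
  gate <- gateConfig()
  base <- quadrantFractions(eventTable(ev), gate, applyGate = FALSE)
  expect_equal(sum(base@fractions), 1, tolerance = 1e-12)
  ## permutation of events
  perm <- quadrantFractions(eventTable(ev[sample(nrow(ev)), ]), gate,
                            applyGate = FALSE)
  expect_equal(perm@mean, base@mean)
  ## joint rescaling of channels and thresholds
  ev2 <- within(ev, {gfp <- gfp * 7; rfp <- rfp * 7})
  gate2 <- gateConfig(gfpThresh = gate@gfpThresh * 7,
                      rfpThresh = gate@rfpThresh * 7)
  resc <- quadrantFractions(eventTable(ev2), gate2, applyGate = FALSE)
  expect_equal(resc@mean, base@mean)
})

test_that("replicate aggregation reports mean and n-1 dispersion", {
  mix <- function(s) generateFlow(
    plantedMixture(fractions = c(0.2, 0.3, 0.3, 0.2), nEvents = 1000,
                   seed = s),
    metadata = list(l_ara = 0, c6 = 50, atc = 15, topology = "DSA",
                    mode = "non_targeting", replicate = s))$events
  tabs <- lapply(1:3, mix)
  fs <- fractionSeries(tabs, gateConfig())
  expect_equal(length(fs), 1L)
  f <- fs[[1]]
  expect_equal(nrow(f@fractions), 3L)
  expect_equal(unname(f@sd),
               unname(apply(f@fractions, 2, stats::sd)))
  ## identical replicates have zero dispersion
  same <- list(tabs[[1]], tabs[[1]])
  fSame <- fractionSeries(same, gateConfig())[[1]]
  expect_equal(max(fSame@sd), 0)
  ## single replicate per condition is rejected
  expect_error(fractionSeries(tabs[1], gateConfig()), "replicates")
})

test_that("plate dose-response recovers planted ratios", {
  pl <- plantedPlate(ratios = c("0" = 5, "0.001" = 120, "0.01" = 400),
                     noiseSd = 0, replicates = 2, seed = 4)
  gen <- generatePlate(pl)
  dr <- plateDoseResponse(gen$series, window = 4)
  expect_equal(dr$mean, unname(gen$truth[as.character(dr$dose)]),
               tolerance = 1e-6)
  ## linearity: doubling the planted ratio doubles the readout
  pl2 <- plantedPlate(ratios = c("0" = 10, "0.001" = 240, "0.01" = 800),
                      noiseSd = 0, replicates = 2, seed = 4)
  dr2 <- plateDoseResponse(generatePlate(pl2)$series, window = 4)
  expect_equal(dr2$mean / dr$mean, rep(2, 3), tolerance = 1e-6)
  ## window shrink barely moves the readout; blank well reads ~0
  drNarrow <- plateDoseResponse(gen$series, window = 1)
  expect_equal(drNarrow$mean, dr$mean, tolerance = 0.01)
  blk <- Filter(function(s) isTRUE(meta(s)$blank), gen$series)[[1]]
  blk@metadata$blank <- FALSE
  blk@metadata$dose <- 99
  drB <- plateDoseResponse(c(gen$series, blk), window = 4, odFloor = 0.01)
  expect_lt(abs(drB$mean[drB$dose == 99]), 1)
  ## noisy recovery within 5%
  plN <- plantedPlate(noiseSd = 0.02, replicates = 3, seed = 8)
  drN <- plateDoseResponse(generatePlate(plN)$series, window = 4)
  expect_equal(drN$mean, unname(plN@ratios[as.character(drN$dose)]),
               tolerance = 0.05)
})
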
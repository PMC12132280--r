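test_that("integration holds a fixed point and converges to OFF", {
  off <- offState(dsaC, defP)
  f <- circuitRHS(off, dsaC, inducers(), defP)
  expect_lt(sqrt(sum(f^2)) / (1 + sqrt(sum(off^2))), 1e-7)
  ## constant trajectory from the fixed point
  tr <- integrateCircuit(off, 10, dsaC, inducers(), defP)
  expect_lt(max(abs(as.numeric(tr[nrow(tr), -1]) - off)), 1e-5)
  ## generic start relaxes to OFF at zero inducers
  tr2 <- integrateCircuit(statev(30, 30, 10, 10), 60, dsaC, inducers(), defP)
  expect_equal(as.numeric(tr2[nrow(tr2), -1]), unname(off), tolerance = 1e-4)
  ## tightening tolerances barely moves the endpoint
  a <- integrateCircuit(statev(5, 5, 1, 1), 16, dsaC,
                        inducers(1e-3, 10, 15), defP,
                        rtol = 1e-8, atol = 1e-10)
  b <- integrateCircuit(statev(5, 5, 1, 1), 16, dsaC,
                        inducers(1e-3, 10, 15), defP,
                        rtol = 1e-10, atol = 1e-12)
  expect_equal(as.numeric(a[nrow(a), -1]), as.numeric(b[nrow(b), -1]),
               tolerance = 1e-6)
})

test_that("state classification follows the ON thresholds", {
  p <- defP
  th <- p[["theta_on1"]]
  expect_equal(classifyState(statev(0.1 * th, 0.1 * th), p), "OFF")
  expect_equal(classifyState(statev(10 * th, 0.1 * th), p), "M1_only")
  expect_equal(classifyState(statev(0.1 * th, 10 * th), p), "M2_only")
  expect_equal(classifyState(statev(10 * th, 10 * th), p), "coactivation")
})

test_that("multi-start root finding recovers the attractor structure", {
  ## zero inducers: a single stable OFF state
  ss0 <- findSteadyStates(dsaC, inducers(), defP, nStarts = 16, seed = 1)
  stable0 <- Filter(function(s) isTRUE(s@stable), ss0)
  expect_equal(length(stable0), 1L)
  expect_equal(stable0[[1]]@label, "OFF")
  ## both inducers high in the control circuit: winner-takes-all
  ## bistability with M1-only and M2-only coexisting
  indHi <- inducers(lAra = 5e-3, c6 = 100, atc = 15)
  ss <- findSteadyStates(dsaC, indHi, defP, nStarts = 24, seed = 1)
  labs <- vapply(Filter(function(s) isTRUE(s@stable), ss),
                 function(s) s@label, character(1))
  expect_true(all(c("M1_only", "M2_only") %in% labs))
  for (s in ss) expect_lt(s@rhsNorm, 1e-8)
})

test_that("steady states swap under module exchange", {
  ## mirror parameters and inducers; the stable-state set must mirror too
  ind <- inducers(lAra = 1.25e-3, c6 = 25 * 1.25e-3 / 5e-4 * 0.4, atc = 15)
  p <- defP
  ss <- findSteadyStates(dsaC, inducers(lAra = 2e-3, c6 = 10, atc = 0), p,
                         nStarts = 16, seed = 3)
  ## swapped problem: exchange module roles (inducer saturations equal)
  f1 <- 2e-3 / (p[["theta_ara"]] + 2e-3)
  c6sw <- p[["theta_c6"]] * (f1 / (1 - f1))^(1 / p[["n_c6"]])
  f2 <- 10^p[["n_c6"]] / (p[["theta_c6"]]^p[["n_c6"]] + 10^p[["n_c6"]])
  arasw <- p[["theta_ara"]] * f2 / (1 - f2)
  ssSw <- findSteadyStates(dsaC, inducers(lAra = arasw, c6 = c6sw, atc = 0),
                           p, nStarts = 16, seed = 3)
  labs <- sort(vapply(Filter(function(s) isTRUE(s@stable), ss),
                      function(s) s@label, character(1)))
  swapBack <- c(M1_only = "M2_only", M2_only = "M1_only", OFF = "OFF",
                coactivation = "coactivation")
  labsSw <- sort(unname(swapBack[vapply(
    Filter(function(s) isTRUE(s@stable), ssSw),
    function(s) s@label, character(1))]))
  expect_equal(labsSw, labs)
})

test_that("attractor from OFF reproduces induction outcomes", {
  expect_equal(attractorFromOff(dsaC, inducers(), defP)@label, "OFF")
  sc <- studyConditions()$dsa_forward
  hiC6 <- inducers(lAra = sc$l_ara, c6 = max(sc$grid), atc = sc$atc)
  expect_equal(attractorFromOff(dsaC, hiC6, defP)@label, "M2_only")
  expect_equal(attractorFromOff(dsaT, hiC6, defP)@label, "coactivation")
})

test_that("stability flags agree with perturbed long-time integration", {
  ind <- inducers(lAra = 5e-3, c6 = 100, atc = 15)
  ss <- findSteadyStates(dsaC, ind, defP, nStarts = 16, seed = 2)
  stable <- Filter(function(s) isTRUE(s@stable), ss)
  set.seed(11)
  for (s in stable[seq_len(min(2, length(stable)))]) {
    for (k in 1:3) {
      pert <- pmax(s@state * (1 + stats::rnorm(4, 0, 0.02)), 0)
      tr <- integrateCircuit(pert, 60, dsaC, ind, defP, nOut = 5L)
      fin <- as.numeric(tr[nrow(tr), -1])
      expect_lt(sqrt(sum((fin - s@state)^2)) / (1 + sqrt(sum(s@state^2))),
                1e-3)
    }
  }
})

test_that("dose response from OFF tracks the WTA transition", {
  sc <- studyConditions()$dsa_forward
  dr <- doseResponse(dsaC, inducers(lAra = sc$l_ara, atc = sc$atc), "c6",
                     sc$grid, defP)
  expect_equal(nrow(dr), length(sc$grid))
  expect_equal(dr$label[1], "M1_only")
  expect_equal(dr$label[nrow(dr)], "M2_only")
  ## basal point: all-zero inducers give the basal readout
  dr0 <- doseResponse(dsaC, inducers(), "c6",
                      c(0, 1e-4, 2e-4, 3e-4, 4e-4), defP)
  expect_lt(dr0$x2[1], defP[["theta_on2"]])
  expect_error(doseResponse(dsaC, inducers(), "c6", c(3, 2, 1, 0.5, 0.1),
                            defP), "strictly increasing")
})

test_that("hysteresis scan finds the bistable window of M1", {
  grid <- c(0, 10^seq(-4.2, -2.4, length.out = 16))
  hy <- hysteresisScan("M1", grid, defP, settleTime = 120)
  expect_false(is.null(hy$bistableInterval))
  ## branches coincide outside the reported interval
  outside <- hy$up$dose < hy$bistableInterval[1] |
    hy$up$dose > hy$bistableInterval[2]
  expect_true(all(abs(hy$up$readout[outside] - hy$down$readout[outside]) <
                    defP[["theta_on1"]]))
  ## weak non-cooperative feedback is monostable: empty interval
  pWeak <- circuitParams(n1 = 1, alpha1 = 40)
  hyW <- hysteresisScan("M1", grid, pWeak, settleTime = 120)
  expect_null(hyW$bistableInterval)
})

test_that("phase diagram is mode-independent when dCas9 is absent", {
  pz <- circuitParams(d_basal = 0)
  lg <- c(1e-4, 1e-3, 1e-2)
  cg <- c(1, 20, 200)
  pd <- phaseDiagram("DSA", c("targeting", "non_targeting"), lg, cg,
                     atc = 0, pz)
  expect_identical(labelMatrix(pd$targeting),
                   labelMatrix(pd$non_targeting))
  expect_equal(coactivationCount(pd$targeting),
               sum(labelMatrix(pd$targeting) == "coactivation"))
})
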
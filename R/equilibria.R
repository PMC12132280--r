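#' @include circuit-model.R
NULL

## deSolve-compatible RHS; clamps tiny solver undershoots below zero.
.odeFunc <- function(topo, ind, params) {
  pm <- .paramsAsVectors(params)
  kind <- topo@kind
  targeting <- topo@controller == "targeting"
  lAra <- ind@lAra; c6 <- ind@c6; atc <- ind@atc
  function(t, y, parms) {
    y <- pmax(y, 0)
    d <- .rhsCore(y[[1]], y[[2]], y[[3]], y[[4]], pm, kind, targeting,
                  lAra, c6, atc)
    list(c(d$dx1, d$dx2, d$dg1, d$dg2))
  }
}

#' Integrate the circuit ODE model
#'
#' Stiff-safe time integration with \code{deSolve::lsoda}.  Integration
#' failures are raised as errors with diagnostics, never returned as silent
#' NaNs.
#'
#' @param state0 named numeric of length 4 (x1, x2, g1, g2), the initial
#'   state; non-negative.
#' @param horizon integration horizon (h), positive.
#' @param topo a \linkS4class{Topology}.
#' @param ind an \linkS4class{Inducers}.
#' @param params a \linkS4class{CircuitParams}.
#' @param rtol,atol solver tolerances.
#' @param nOut number of output time points (including t = 0).
#' @return a data.frame with columns time, x1, x2, g1, g2; attribute
#'   \code{finalRhsNorm} carries the relative RHS norm at the final state.
#' @export
integrateCircuit <- function(state0, horizon, topo, ind, params,
                             rtol = 1e-8, atol = 1e-10, nOut = 101L) {
  if (!is.numeric(horizon) || horizon <= 0)
    stop("horizon must be positive", call. = FALSE)
  if (any(state0 < 0)) stop("state0 must be non-negative", call. = FALSE)
  times <- seq(0, horizon, length.out = max(2L, nOut))
  fn <- .odeFunc(topo, ind, params)
  out <- deSolve::lsoda(y = stats::setNames(as.numeric(state0), .STATE_NAMES),
                        times = times, func = fn, parms = NULL,
                        rtol = rtol, atol = atol)
  diagn <- attributes(out)$istate
  if (!is.null(diagn) && diagn[1] < 0)
    stop(sprintf("ODE integration failed (lsoda istate = %d)", diagn[1]),
         call. = FALSE)
  out <- as.data.frame(out)
  if (any(!is.finite(as.matrix(out))))
    stop("ODE integration produced non-finite values", call. = FALSE)
  fin <- as.numeric(out[nrow(out), .STATE_NAMES])
  f <- circuitRHS(stats::setNames(pmax(fin, 0), .STATE_NAMES), topo, ind, params)
  attr(out, "finalRhsNorm") <- .rhsNorm(f, fin)
  out
}

#' Classify a circuit state by the ON thresholds
#'
#' @param state named numeric (x1, x2, g1, g2) or any vector whose first two
#'   entries are x1, x2.
#' @param params a \linkS4class{CircuitParams} (uses theta_on1, theta_on2).
#' @return one of "OFF", "M1_only", "M2_only", "coactivation".
#' @export
classifyState <- function(state, params) {
  on1 <- state[[1]] >= params[["theta_on1"]]
  on2 <- state[[2]] >= params[["theta_on2"]]
  if (on1 && on2) "coactivation"
  else if (on1) "M1_only"
  else if (on2) "M2_only"
  else "OFF"
}

#' The OFF (uninduced basal) steady state
#'
#' Computes the basal equilibrium at zero L-ara and zero C6 (aTc as given),
#' the state experimental cultures are in before induction: integrate from
#' the origin, then polish by Newton iteration.
#'
#' @param topo a \linkS4class{Topology}.
#' @param params a \linkS4class{CircuitParams}.
#' @param atc aTc dose carried by the uninduced culture (ng/mL); dCas9 is
#'   induced together with the modules, so the pre-induction state uses 0
#'   by default.
#' @return named numeric of length 4.
#' @export
offState <- function(topo, params, atc = 0) {
  ind0 <- inducers(lAra = 0, c6 = 0, atc = atc)
  tr <- integrateCircuit(stats::setNames(rep(0, 4), .STATE_NAMES), 100,
                         topo, ind0, params)
  s <- as.numeric(tr[nrow(tr), .STATE_NAMES])
  fn <- function(y) circuitRHS(stats::setNames(pmax(y, 0), .STATE_NAMES),
                               topo, ind0, params)
  res <- .newtonRoot(fn, s)
  stats::setNames(res$root, .STATE_NAMES)
}

.jacobianAt <- function(fn, x, relStep = 1e-6) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- relStep * max(abs(x[j]), 1)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- max(x[j] - h, 0)
    J[, j] <- (fn(xp) - fn(xm)) / (xp[j] - xm[j])
  }
  J
}

#' The attractor reached from the uninduced state
#'
#' Mirrors the induction protocol: start at the OFF basal state, apply the
#' inducers, integrate over the induction horizon (default 16 h), and
#' extend the horizon in doublings until the right-hand side has relaxed
#' below tolerance.  The reached state is classified by the ON thresholds.
#'
#' @param topo a \linkS4class{Topology}.
#' @param ind an \linkS4class{Inducers}.
#' @param params a \linkS4class{CircuitParams}.
#' @param horizon initial induction horizon (h).
#' @param tol relative RHS norm below which the state counts as settled.
#' @param maxExtensions maximum number of horizon doublings.
#' @param state0 optional explicit initial state (defaults to the OFF state).
#' @return a \linkS4class{SteadyState}; label "unclassified" with
#'   \code{stable = NA} if the trajectory has not settled after all
#'   extensions (slow or oscillatory dynamics).
#' @export
attractorFromOff <- function(topo, ind, params, horizon = 16,
                             tol = 1e-8, maxExtensions = 6L,
                             state0 = NULL) {
  s <- if (is.null(state0)) offState(topo, params) else
    stats::setNames(as.numeric(state0), .STATE_NAMES)
  h <- horizon
  for (k in 0:maxExtensions) {
    tr <- integrateCircuit(s, h, topo, ind, params, nOut = 33L)
    s <- stats::setNames(pmax(as.numeric(tr[nrow(tr), .STATE_NAMES]), 0),
                         .STATE_NAMES)
    if (attr(tr, "finalRhsNorm") < sqrt(tol)) break
    h <- h * 2
  }
  fn <- function(y) circuitRHS(stats::setNames(pmax(y, 0), .STATE_NAMES),
                               topo, ind, params)
  res <- .newtonRoot(fn, s, tol = tol)
  if (!res$converged) {
    return(new("SteadyState", state = stats::setNames(res$root, .STATE_NAMES),
               stable = NA, label = "unclassified", rhsNorm = res$norm))
  }
  st <- stats::setNames(res$root, .STATE_NAMES)
  ev <- eigen(.jacobianAt(fn, st), only.values = TRUE)$values
  new("SteadyState", state = st, stable = all(Re(ev) < 1e-6),
      label = classifyState(st, params), rhsNorm = res$norm)
}

#' Find all steady states by multi-start root finding
#'
#' Newton-refines roots of the RHS from log-uniform random starts plus
#' heuristic starts (the OFF state and single/double-module-ON guesses),
#' deduplicates them by relative distance, verifies each root against the
#' tolerance, and assesses stability from finite-difference Jacobian
#' eigenvalues.
#'
#' @param topo a \linkS4class{Topology}.
#' @param ind an \linkS4class{Inducers}.
#' @param params a \linkS4class{CircuitParams}.
#' @param nStarts number of random starts (>= 8).
#' @param seed integer seed for the random starts.
#' @param rootTol relative RHS norm tolerance for an accepted root.
#' @param dedupTol relative distance below which two roots are the same.
#' @param preIntegrate hours of integration applied to each start before
#'   Newton refinement (stabilises convergence toward attractors while the
#'   Newton step can still land on unstable saddles from nearby starts).
#' @return a list of \linkS4class{SteadyState} objects (possibly empty,
#'   with a warning, if no start converged).
#' @export
findSteadyStates <- function(topo, ind, params, nStarts = 64L, seed = 1L,
                             rootTol = 1e-8, dedupTol = 1e-4,
                             preIntegrate = 2) {
  if (nStarts < 8L) stop("nStarts must be >= 8", call. = FALSE)
  fn <- function(y) circuitRHS(stats::setNames(pmax(y, 0), .STATE_NAMES),
                               topo, ind, params)
  xmax <- max(params[["alpha1"]], params[["alpha2"]]) / params[["delta"]]
  gmax <- params[["kappa_g"]] *
    max(params[["alpha1"]], params[["alpha2"]]) / params[["gamma_g"]]
  xon1 <- params[["alpha1"]] / params[["delta"]]
  xon2 <- params[["alpha2"]] / params[["delta"]]
  starts <- list(
    offState(topo, params),
    c(xon1, 0.01, params[["kappa_g"]] * params[["alpha1"]] / params[["gamma_g"]], 0.01),
    c(0.01, xon2, 0.01, params[["kappa_g"]] * params[["alpha2"]] / params[["gamma_g"]]),
    c(xon1 / 2, xon2 / 2, gmax / 2, gmax / 2))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  rnd <- lapply(seq_len(nStarts), function(i) {
    c(exp(stats::runif(2, log(1e-2), log(xmax))),
      exp(stats::runif(2, log(1e-2), log(max(gmax, 1)))))
  })
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  starts <- c(starts, rnd)
  roots <- list()
  for (s0 in starts) {
    s0 <- stats::setNames(pmax(as.numeric(s0), 0), .STATE_NAMES)
    s1 <- s0
    if (preIntegrate > 0) {
      tr <- tryCatch(integrateCircuit(s0, preIntegrate, topo, ind, params,
                                      nOut = 5L), error = function(e) NULL)
      if (!is.null(tr))
        s1 <- stats::setNames(pmax(as.numeric(tr[nrow(tr), .STATE_NAMES]), 0),
                              .STATE_NAMES)
    }
    for (cand in unique(list(s1, s0))) {
      res <- .newtonRoot(fn, cand, tol = rootTol)
      if (res$converged && res$norm < rootTol) {
        dup <- any(vapply(roots, function(r)
          sqrt(sum((r - res$root)^2)) / (1 + sqrt(sum(r^2))) < dedupTol,
          logical(1)))
        if (!dup) roots[[length(roots) + 1L]] <- res$root
      }
    }
  }
  if (!length(roots)) {
    warning("no steady state found from any start")
    return(list())
  }
  lapply(roots, function(r) {
    st <- stats::setNames(r, .STATE_NAMES)
    f <- fn(st)
    ev <- eigen(.jacobianAt(fn, st), only.values = TRUE)$values
    new("SteadyState", state = st, stable = all(Re(ev) < 1e-6),
        label = classifyState(st, params), rhsNorm = .rhsNorm(f, st))
  })
}

.setInducer <- function(ind, axis, value) {
  switch(axis,
         l_ara = inducers(lAra = value, c6 = ind@c6, atc = ind@atc),
         c6 = inducers(lAra = ind@lAra, c6 = value, atc = ind@atc),
         atc = inducers(lAra = ind@lAra, c6 = ind@c6, atc = value),
         stop("scan axis must be one of l_ara, c6, atc", call. = FALSE))
}

#' Deterministic dose-response scan
#'
#' Sweeps one inducer over a grid; at each dose the reported state is the
#' attractor reached from OFF (steady-state dose-response as measured after
#' a fixed induction window).
#'
#' @param topo a \linkS4class{Topology}.
#' @param ind an \linkS4class{Inducers} giving the fixed doses of the
#'   non-scanned inducers.
#' @param scanAxis one of "l_ara", "c6", "atc".
#' @param grid strictly increasing dose grid (>= 5 points).
#' @param params a \linkS4class{CircuitParams}.
#' @param horizon induction horizon (h) passed to
#'   \code{\link{attractorFromOff}}.
#' @return a data.frame with columns dose, x1, x2, g1, g2, label; per-point
#'   integration failures are recorded as NA rows and the scan continues.
#' @export
doseResponse <- function(topo, ind, scanAxis, grid, params, horizon = 16) {
  if (length(grid) < 5L || is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing with >= 5 points", call. = FALSE)
  rows <- lapply(grid, function(d) {
    ss <- tryCatch(
      attractorFromOff(topo, .setInducer(ind, scanAxis, d), params,
                       horizon = horizon),
      error = function(e) NULL)
    if (is.null(ss))
      data.frame(dose = d, x1 = NA_real_, x2 = NA_real_, g1 = NA_real_,
                 g2 = NA_real_, label = NA_character_)
    else
      data.frame(dose = d, x1 = ss@state[["x1"]], x2 = ss@state[["x2"]],
                 g1 = ss@state[["g1"]], g2 = ss@state[["g2"]],
                 label = ss@label)
  })
  do.call(rbind, rows)
}

#' Quasi-static hysteresis scan of one self-activation module
#'
#' Sweeps the module's own inducer up from the OFF state and back down from
#' the induced state, carrying the equilibrium forward between consecutive
#' doses (quasi-static continuation).  The bistable interval is where the
#' two branches disagree by more than the module's ON threshold.
#'
#' @param module "M1" (scan L-ara, C6 = 0) or "M2" (scan C6, L-ara = 0).
#' @param grid strictly increasing inducer grid.
#' @param params a \linkS4class{CircuitParams}.
#' @param topo a \linkS4class{Topology}; default DSA non-targeting (the
#'   isolated self-activation switch).
#' @param atc fixed aTc dose (relevant in targeting mode).
#' @param settleTime hours integrated at each dose before reading the
#'   branch state.
#' @return a list with data.frames \code{up} and \code{down} (columns dose,
#'   readout), and \code{bistableInterval} (length-2 numeric or NULL).
#' @export
hysteresisScan <- function(module = c("M1", "M2"), grid, params,
                           topo = topology("DSA", "non_targeting"),
                           atc = 0, settleTime = 200) {
  module <- match.arg(module)
  axis <- if (module == "M1") "l_ara" else "c6"
  comp <- if (module == "M1") "x1" else "x2"
  base <- inducers(atc = atc)
  runBranch <- function(doses, s) {
    readout <- numeric(length(doses))
    for (i in seq_along(doses)) {
      tr <- integrateCircuit(s, settleTime, topo,
                             .setInducer(base, axis, doses[i]), params,
                             nOut = 9L)
      s <- stats::setNames(pmax(as.numeric(tr[nrow(tr), .STATE_NAMES]), 0),
                           .STATE_NAMES)
      readout[i] <- s[[comp]]
    }
    list(readout = readout, final = s)
  }
  up <- runBranch(grid, offState(topo, params))
  down <- runBranch(rev(grid), up$final)
  downReadout <- rev(down$readout)
  thr <- params[[if (module == "M1") "theta_on1" else "theta_on2"]]
  bist <- which(abs(up$readout - downReadout) > thr)
  list(up = data.frame(dose = grid, readout = up$readout),
       down = data.frame(dose = grid, readout = downReadout),
       bistableInterval = if (length(bist))
         range(grid[bist]) else NULL)
}

#' Two-inducer phase diagram of attractors from OFF
#'
#' Labels every (L-ara, C6) grid cell with the fate reached from the OFF
#' state at fixed aTc, for one or both controller modes.
#'
#' @param kind "DSA" or "CBS".
#' @param modes character vector of controller modes to evaluate.
#' @param lAraGrid,c6Grid strictly increasing dose grids (>= 8 points each
#'   recommended; log-spaced with an explicit zero allowed via c(0, ...)).
#' @param atc fixed aTc dose (ng/mL).
#' @param params a \linkS4class{CircuitParams}.
#' @param horizon induction horizon (h).
#' @return a named list of \linkS4class{PhaseDiagram}, one per mode.
#' @export
phaseDiagram <- function(kind, modes = c("targeting", "non_targeting"),
                         lAraGrid, c6Grid, atc, params, horizon = 16) {
  out <- list()
  for (mode in modes) {
    topo <- topology(kind, mode)
    off <- offState(topo, params)
    lab <- matrix(NA_character_, length(lAraGrid), length(c6Grid))
    m1 <- m2 <- matrix(NA_real_, length(lAraGrid), length(c6Grid))
    for (i in seq_along(lAraGrid)) for (j in seq_along(c6Grid)) {
      ss <- attractorFromOff(topo,
                             inducers(lAra = lAraGrid[i], c6 = c6Grid[j],
                                      atc = atc),
                             params, horizon = horizon, state0 = off)
      lab[i, j] <- ss@label
      m1[i, j] <- ss@state[["x1"]]
      m2[i, j] <- ss@state[["x2"]]
    }
    out[[mode]] <- new("PhaseDiagram", lAraGrid = lAraGrid, c6Grid = c6Grid,
                       labels = lab, x1 = m1, x2 = m2,
                       coactivationCount = sum(lab == "coactivation"),
                       condition = list(topology = kind, mode = mode,
                                        atc = atc))
  }
  out
}

#' Write a phase/dose scan as tidy CSV
#'
#' One row per condition with columns topology, mode, l_ara, c6, atc,
#' label, x1, x2.
#'
#' @param diagrams named list of \linkS4class{PhaseDiagram} (per mode).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeScanCSV <- function(diagrams, path) {
  rows <- list()
  for (mode in names(diagrams)) {
    pd <- diagrams[[mode]]
    for (i in seq_along(pd@lAraGrid)) for (j in seq_along(pd@c6Grid)) {
      rows[[length(rows) + 1L]] <- data.frame(
        topology = pd@condition$topology, mode = mode,
        l_ara = pd@lAraGrid[i], c6 = pd@c6Grid[j],
        atc = pd@condition$atc, label = pd@labels[i, j],
        x1 = pd@x1[i, j], x2 = pd@x2[i, j])
    }
  }
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
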
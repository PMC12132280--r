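#' @include circuit-model.R equilibria.R
NULL

.NOISE_FIELDS <- c("alpha1", "alpha2", "K1", "K2")

#' Draw per-cell kinetic parameters (extrinsic noise)
#'
#' Cell-to-cell variability is modelled as extrinsic noise: each cell gets
#' its own copy of the designated kinetic parameters, multiplied by
#' independent lognormal factors with mean 1 and coefficient of variation
#' \code{cvExtrinsic}.  All other parameters are shared.
#'
#' @param params base \linkS4class{CircuitParams}.
#' @param noise a \linkS4class{NoiseModel}.
#' @param n number of cells (>= 1).
#' @param seed integer seed; the draw is fully reproducible.
#' @param fields parameter names to perturb.
#' @return a data.frame with one row per cell and one column per perturbed
#'   field; the base parameter set is attached as attribute \code{"base"}.
#' @export
sampleCellParams <- function(params, noise, n, seed,
                             fields = .NOISE_FIELDS) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  stopifnot(all(fields %in% names(params)))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  out <- as.data.frame(lapply(fields, function(f)
    params[[f]] * .lognormMult(n, noise@cvExtrinsic)))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  names(out) <- fields
  attr(out, "base") <- params
  out
}

## Fixed-step RK4 for an ensemble of independent cells (vectorised across
## cells).  The system is non-stiff at the default rates (fastest mode is
## sgRNA decay, gamma_g = 2/h), so dt = 0.02 h is comfortably stable.
.integrateCellsRK4 <- function(state, pm, kind, targeting, lAra, c6, atc,
                               horizon, dt = 0.02) {
  x1 <- state$x1; x2 <- state$x2; g1 <- state$g1; g2 <- state$g2
  nStep <- ceiling(horizon / dt)
  h <- horizon / nStep
  deriv <- function(x1, x2, g1, g2)
    .rhsCore(pmax(x1, 0), pmax(x2, 0), pmax(g1, 0), pmax(g2, 0),
             pm, kind, targeting, lAra, c6, atc)
  for (s in seq_len(nStep)) {
    k1 <- deriv(x1, x2, g1, g2)
    k2 <- deriv(x1 + h / 2 * k1$dx1, x2 + h / 2 * k1$dx2,
                g1 + h / 2 * k1$dg1, g2 + h / 2 * k1$dg2)
    k3 <- deriv(x1 + h / 2 * k2$dx1, x2 + h / 2 * k2$dx2,
                g1 + h / 2 * k2$dg1, g2 + h / 2 * k2$dg2)
    k4 <- deriv(x1 + h * k3$dx1, x2 + h * k3$dx2,
                g1 + h * k3$dg1, g2 + h * k3$dg2)
    x1 <- pmax(x1 + h / 6 * (k1$dx1 + 2 * k2$dx1 + 2 * k3$dx1 + k4$dx1), 0)
    x2 <- pmax(x2 + h / 6 * (k1$dx2 + 2 * k2$dx2 + 2 * k3$dx2 + k4$dx2), 0)
    g1 <- pmax(g1 + h / 6 * (k1$dg1 + 2 * k2$dg1 + 2 * k3$dg1 + k4$dg1), 0)
    g2 <- pmax(g2 + h / 6 * (k1$dg2 + 2 * k2$dg2 + 2 * k3$dg2 + k4$dg2), 0)
  }
  list(x1 = x1, x2 = x2, g1 = g1, g2 = g2)
}

#' Simulate a flow-cytometry sample from the mechanistic model
#'
#' Draws \code{nEvents} cells with extrinsic parameter noise, integrates
#' each from the uninduced basal state over the induction horizon (16 h by
#' default, matching the bench protocol), and converts the reached protein
#' levels to cytometer channels: \code{gfp = scale * x1 + autofluorescence}
#' (similarly rfp), times multiplicative lognormal measurement noise.
#' Forward scatter height is drawn from a fixed lognormal size
#' distribution; singlets have \code{fsc_a} close to \code{fsc_h}, while a
#' \code{doubletFrac} subset of events is replaced by doublets carrying the
#' summed fluorescence of two cells and \code{fsc_a} near twice
#' \code{fsc_h}.
#'
#' @param topo a \linkS4class{Topology}.
#' @param ind an \linkS4class{Inducers}.
#' @param params base \linkS4class{CircuitParams}.
#' @param noise a \linkS4class{NoiseModel}.
#' @param nEvents number of events (>= 100).
#' @param seed integer seed.
#' @param horizon induction time (h) each cell is integrated for.
#' @param dt RK4 step (h).
#' @param scale fluorescence units per protein au.
#' @param replicate replicate identifier stored in the metadata.
#' @return an \linkS4class{EventTable}.
#' @export
simulatePopulation <- function(topo, ind, params, noise, nEvents = 10000L,
                               seed = 1L, horizon = 16, dt = 0.02,
                               scale = 10, replicate = 1L) {
  if (nEvents < 100) stop("nEvents must be >= 100", call. = FALSE)
  cp <- sampleCellParams(params, noise, nEvents, seed)
  pm <- .paramsAsVectors(params)
  for (f in names(cp)) pm[[f]] <- cp[[f]]
  off <- offState(topo, params)
  st0 <- list(x1 = rep(off[["x1"]], nEvents), x2 = rep(off[["x2"]], nEvents),
              g1 = rep(off[["g1"]], nEvents), g2 = rep(off[["g2"]], nEvents))
  fin <- .integrateCellsRK4(st0, pm, topo@kind,
                            topo@controller == "targeting",
                            ind@lAra, ind@c6, ind@atc, horizon, dt)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(.childSeed(seed, 2L))
  gfp0 <- scale * fin$x1 + noise@autofluorGfp
  rfp0 <- scale * fin$x2 + noise@autofluorRfp
  fscH <- stats::rlnorm(nEvents, meanlog = log(5e4), sdlog = 0.18)
  ratio <- pmax(1 + stats::rnorm(nEvents, 0, 0.03), 0.5)
  gfp <- gfp0; rfp <- rfp0
  nDbl <- round(noise@doubletFrac * nEvents)
  if (nDbl > 0) {
    idx <- sample.int(nEvents, nDbl)
    partner <- sample.int(nEvents, nDbl, replace = TRUE)
    gfp[idx] <- gfp0[idx] + gfp0[partner]
    rfp[idx] <- rfp0[idx] + rfp0[partner]
    ratio[idx] <- pmax(2 + stats::rnorm(nDbl, 0, 0.1), 1.5)
  }
  mg <- exp(stats::rnorm(nEvents, 0, noise@sigmaMeas))
  mr <- exp(stats::rnorm(nEvents, 0, noise@sigmaMeas))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  ev <- data.frame(fsc_a = fscH * ratio, fsc_h = fscH,
                   gfp = gfp * mg, rfp = rfp * mr)
  eventTable(ev, metadata = list(
    l_ara = ind@lAra, c6 = ind@c6, atc = ind@atc,
    topology = topo@kind, mode = topo@controller,
    replicate = replicate, n_events = nEvents, seed = seed,
    horizon = horizon, scale = scale, dropped = 0L))
}

#' Simulate a plate-reader growth/fluorescence time series
#'
#' OD600 follows logistic growth from the noise model's inoculum to its
#' carrying capacity; bulk fluorescence is the per-cell mean model readout
#' along the deterministic trajectory times the OD, with multiplicative
#' measurement noise.  The fluorescence/OD ratio is therefore recoverable
#' by the analysis stage.
#'
#' @param topo a \linkS4class{Topology}.
#' @param ind an \linkS4class{Inducers}.
#' @param params a \linkS4class{CircuitParams}.
#' @param noise a \linkS4class{NoiseModel}.
#' @param horizon total measurement time (h), >= 4.
#' @param dt sampling interval (h).
#' @param seed integer seed.
#' @param scale fluorescence units per protein au.
#' @param blank if TRUE the well contains medium only (flat OD at the
#'   inoculum level, fluorescence around zero).
#' @param well well identifier for the metadata.
#' @return a \linkS4class{PlateSeries}.
#' @export
simulatePlate <- function(topo, ind, params, noise, horizon = 16,
                          dt = 0.25, seed = 1L, scale = 10,
                          blank = FALSE, well = "A1") {
  if (horizon < 4) stop("horizon must be >= 4 h", call. = FALSE)
  times <- seq(0, horizon, by = dt)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  if (blank) {
    od <- rep(0.04, length(times)) * exp(stats::rnorm(length(times), 0,
                                                      noise@sigmaMeas / 4))
    gfp <- abs(stats::rnorm(length(times), 0, 0.5))
    rfp <- abs(stats::rnorm(length(times), 0, 0.5))
  } else {
    K <- noise@odCapacity; o0 <- noise@od0; r <- noise@odRate
    od <- K * o0 / (o0 + (K - o0) * exp(-r * times))
    od <- od * exp(stats::rnorm(length(times), 0, noise@sigmaMeas / 4))
    off <- offState(topo, params)
    tr <- integrateCircuit(off, horizon, topo, ind, params,
                           nOut = length(times))
    gfp <- (scale * tr$x1 + noise@autofluorGfp) * od *
      exp(stats::rnorm(length(times), 0, noise@sigmaMeas))
    rfp <- (scale * tr$x2 + noise@autofluorRfp) * od *
      exp(stats::rnorm(length(times), 0, noise@sigmaMeas))
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  plateSeries(data.frame(time_h = times, od600 = od, gfp = gfp, rfp = rfp),
              metadata = list(well = well, blank = blank,
                              l_ara = ind@lAra, c6 = ind@c6, atc = ind@atc,
                              topology = topo@kind, mode = topo@controller,
                              seed = seed, scale = scale))
}
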
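#' @import methods
NULL

.VALID_KINDS <- c("DSA", "CBS")
.VALID_CONTROLLERS <- c("targeting", "non_targeting")
.FATE_LABELS <- c("OFF", "M1_only", "M2_only", "coactivation")
.STATE_NAMES <- c("x1", "x2", "g1", "g2")

## Parameter fields that must be strictly positive vs merely non-negative.
.PARAM_POSITIVE <- c(
  "alpha1", "alpha2", "K1", "K2", "n1", "n2",
  "theta_ara", "n_ara", "theta_c6", "n_c6",
  "J1", "J2", "delta", "kappa_g", "gamma_g", "Kd",
  "Kc1", "Kc2", "m", "d_max", "theta_atc", "h_atc",
  "Ka_overlap", "theta_on1", "theta_on2")
.PARAM_NONNEG <- c("basal1", "basal2", "d_basal", "k_syn", "w_cross")
.PARAM_FLAGS <- c("lux_overlap")
.PARAM_FIELDS <- c(.PARAM_POSITIVE, .PARAM_NONNEG, .PARAM_FLAGS)

#' Circuit topology and controller mode
#'
#' Identifies which two-module architecture is simulated (dual
#' self-activation, \code{"DSA"}, or cascading bistable switch,
#' \code{"CBS"}) and whether the sgRNAs target their own promoters
#' (\code{"targeting"}, the NCR controller) or are non-targeting controls
#' (\code{"non_targeting"}, repression pathway inert).
#'
#' @slot kind character, \code{"DSA"} or \code{"CBS"}.
#' @slot controller character, \code{"targeting"} or \code{"non_targeting"}.
#' @export
setClass("Topology", representation(kind = "character",
                                    controller = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@kind) != 1L || !object@kind %in% .VALID_KINDS)
      msg <- c(msg, sprintf("kind must be one of %s",
                            paste(.VALID_KINDS, collapse = ", ")))
    if (length(object@controller) != 1L ||
        !object@controller %in% .VALID_CONTROLLERS)
      msg <- c(msg, sprintf("controller must be one of %s",
                            paste(.VALID_CONTROLLERS, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' Inducer concentrations
#'
#' The three externally supplied small molecules, carried in the units
#' used at the bench: L-arabinose (\code{lAra}, percent w/v) induces module
#' M1, 3-oxo-C6-HSL (\code{c6}, nM) induces module M2, and
#' anhydrotetracycline (\code{atc}, ng/mL) induces dCas9 from the pTet
#' promoter.
#'
#' @slot lAra numeric, L-arabinose (\% w/v), non-negative.
#' @slot c6 numeric, 3-oxo-C6-HSL (nM), non-negative.
#' @slot atc numeric, anhydrotetracycline (ng/mL), non-negative.
#' @export
setClass("Inducers",
  representation(lAra = "numeric", c6 = "numeric", atc = "numeric"),
  validity = function(object) {
    v <- c(lAra = object@lAra, c6 = object@c6, atc = object@atc)
    if (length(v) != 3L || any(!is.finite(v)) || any(v < 0))
      "all inducer concentrations must be finite and non-negative"
    else TRUE
  })

#' Kinetic and transfer-function parameters of the circuit model
#'
#' A validated named list holding every constant of the mechanistic model:
#' promoter strengths and leaks (au/h), self-activation thresholds and Hill
#' coefficients, inducer transfer functions, shared-resource capacities,
#' dilution, sgRNA synthesis/decay, dCas9 induction and competitive-binding
#' scales, CRISPRi repression thresholds, CBS cross-activation weights, the
#' Lux-box overlap flag, and ON-classification thresholds.  Use
#' \code{\link{circuitParams}} or \code{\link{defaultCircuitParams}} to
#' construct; fields are read with \code{[[}.
#'
#' @export
setClass("CircuitParams", contains = "list",
  validity = function(object) {
    p <- object@.Data
    names(p) <- names(object)
    msg <- character()
    missing <- setdiff(.PARAM_FIELDS, names(p))
    if (length(missing))
      return(sprintf("missing parameter fields: %s",
                     paste(missing, collapse = ", ")))
    extra <- setdiff(names(p), .PARAM_FIELDS)
    if (length(extra))
      msg <- c(msg, sprintf("unknown parameter fields: %s",
                            paste(extra, collapse = ", ")))
    num <- p[c(.PARAM_POSITIVE, .PARAM_NONNEG)]
    bad <- !vapply(num, function(x)
      is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))
    if (any(bad))
      return(sprintf("non-finite or non-scalar fields: %s",
                     paste(names(num)[bad], collapse = ", ")))
    pos <- unlist(p[.PARAM_POSITIVE])
    if (any(pos <= 0))
      msg <- c(msg, sprintf("fields must be strictly positive: %s",
                            paste(.PARAM_POSITIVE[pos <= 0], collapse = ", ")))
    nn <- unlist(p[.PARAM_NONNEG])
    if (any(nn < 0))
      msg <- c(msg, sprintf("fields must be non-negative: %s",
                            paste(.PARAM_NONNEG[nn < 0], collapse = ", ")))
    if (!is.logical(p$lux_overlap) || length(p$lux_overlap) != 1L)
      msg <- c(msg, "lux_overlap must be a scalar logical")
    if (is.numeric(p$basal1) && p$basal1 >= p$alpha1)
      msg <- c(msg, "basal1 must be < alpha1")
    if (is.numeric(p$basal2) && p$basal2 >= p$alpha2)
      msg <- c(msg, "basal2 must be < alpha2")
    if (length(msg)) msg else TRUE
  })

#' A classified equilibrium of the circuit model
#'
#' @slot state named numeric of length 4 (x1, x2, g1, g2) at equilibrium.
#' @slot stable logical; TRUE when all Jacobian eigenvalue real parts are
#'   below the stability tolerance.
#' @slot label character; one of OFF, M1_only, M2_only, coactivation
#'   (or "unclassified" for non-converged attractor searches).
#' @slot rhsNorm numeric; relative right-hand-side norm at \code{state}.
#' @export
setClass("SteadyState",
  representation(state = "numeric", stable = "logical",
                 label = "character", rhsNorm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@state) != 4L ||
        !identical(names(object@state), .STATE_NAMES))
      msg <- c(msg, "state must be a named numeric (x1, x2, g1, g2)")
    if (!object@label %in% c(.FATE_LABELS, "unclassified"))
      msg <- c(msg, "invalid label")
    if (length(msg)) msg else TRUE
  })

#' Extrinsic and measurement noise model for population simulation
#'
#' @slot cvExtrinsic lognormal coefficient of variation applied per cell to
#'   the designated kinetic parameters (default alpha1, alpha2, K1, K2).
#' @slot sigmaMeas log-scale s.d. of multiplicative measurement noise.
#' @slot doubletFrac fraction of recorded events that are cell doublets.
#' @slot autofluorGfp,autofluorRfp additive autofluorescence background (au).
#' @slot odCapacity,odRate,od0 logistic growth parameters for plate-reader
#'   simulation: carrying capacity (OD600), rate (1/h), inoculum OD.
#' @export
setClass("NoiseModel",
  representation(cvExtrinsic = "numeric", sigmaMeas = "numeric",
                 doubletFrac = "numeric", autofluorGfp = "numeric",
                 autofluorRfp = "numeric", odCapacity = "numeric",
                 odRate = "numeric", od0 = "numeric"),
  validity = function(object) {
    v <- c(object@cvExtrinsic, object@sigmaMeas, object@doubletFrac,
           object@autofluorGfp, object@autofluorRfp, object@odCapacity,
           object@odRate, object@od0)
    msg <- character()
    if (any(!is.finite(v)) || any(v < 0))
      msg <- c(msg, "all noise-model fields must be finite and non-negative")
    if (object@doubletFrac >= 0.5)
      msg <- c(msg, "doubletFrac must be < 0.5")
    if (object@odCapacity <= 0 || object@odRate <= 0 || object@od0 <= 0)
      msg <- c(msg, "growth parameters must be strictly positive")
    if (length(msg)) msg else TRUE
  })

#' Flow-cytometry-like event table
#'
#' Per-event forward-scatter area/height and GFP/RFP intensities, with the
#' condition metadata (inducers, topology, controller mode, replicate)
#' carried alongside, mirroring one recorded cytometer sample.
#'
#' @slot events data.frame with numeric columns fsc_a, fsc_h, gfp, rfp,
#'   all non-negative.
#' @slot metadata named list; by convention holds l_ara, c6, atc, topology,
#'   mode, replicate and n_events.
#' @export
setClass("EventTable",
  representation(events = "data.frame", metadata = "list"),
  validity = function(object) {
    need <- c("fsc_a", "fsc_h", "gfp", "rfp")
    ev <- object@events
    msg <- character()
    if (!all(need %in% names(ev)))
      return(sprintf("events must have columns %s", paste(need, collapse = ", ")))
    for (col in need) {
      if (!is.numeric(ev[[col]]))
        msg <- c(msg, sprintf("column %s must be numeric", col))
      else if (any(!is.finite(ev[[col]])) || any(ev[[col]] < 0))
        msg <- c(msg, sprintf("column %s must be finite and non-negative", col))
    }
    ne <- object@metadata$n_events
    if (!is.null(ne) && ne != nrow(ev))
      msg <- c(msg, "metadata n_events does not match the record count")
    if (length(msg)) msg else TRUE
  })

#' Plate-reader time series for one well
#'
#' @slot data data.frame with columns time_h (strictly increasing), od600
#'   (positive), gfp, rfp.
#' @slot metadata named list (well id, inducers, topology, mode, blank flag).
#' @export
setClass("PlateSeries",
  representation(data = "data.frame", metadata = "list"),
  validity = function(object) {
    d <- object@data
    need <- c("time_h", "od600", "gfp", "rfp")
    if (!all(need %in% names(d)))
      return(sprintf("data must have columns %s", paste(need, collapse = ", ")))
    msg <- character()
    if (is.unsorted(d$time_h, strictly = TRUE))
      msg <- c(msg, "time_h must be strictly increasing")
    if (any(d$od600 <= 0)) msg <- c(msg, "od600 must be positive")
    if (length(msg)) msg else TRUE
  })

#' Cell-fate fractions across replicates
#'
#' Fractions of events classified OFF / M1_only / M2_only / coactivation,
#' one row per biological replicate, with across-replicate mean and sample
#' standard deviation (n - 1 denominator).
#'
#' @slot fractions numeric matrix, replicates x 4, columns OFF, M1_only,
#'   M2_only, coactivation; each row sums to 1.
#' @slot mean,sd named numeric of length 4 (sd is NA for one replicate).
#' @slot nEventsUsed integer vector, events used per replicate.
#' @slot condition named list describing the shared condition.
#' @export
setClass("FateFractions",
  representation(fractions = "matrix", mean = "numeric", sd = "numeric",
                 nEventsUsed = "integer", condition = "list"),
  validity = function(object) {
    f <- object@fractions
    msg <- character()
    if (!identical(colnames(f), .FATE_LABELS))
      return(sprintf("fraction columns must be %s",
                     paste(.FATE_LABELS, collapse = ", ")))
    if (any(f < 0) || any(f > 1))
      msg <- c(msg, "fractions must lie in [0, 1]")
    if (any(abs(rowSums(f) - 1) > 1e-12))
      msg <- c(msg, "each replicate's fractions must sum to 1")
    if (nrow(f) != length(object@nEventsUsed))
      msg <- c(msg, "one nEventsUsed entry per replicate required")
    if (length(msg)) msg else TRUE
  })

#' Singlet-gate and quadrant-threshold configuration
#'
#' @slot fscRatioBand numeric length 2; allowed interval for fsc_a/fsc_h.
#' @slot minFsc lower fsc_h cutoff removing non-cellular small particles.
#' @slot gfpThresh,rfpThresh ON-classification thresholds (au).
#' @export
setClass("GateConfig",
  representation(fscRatioBand = "numeric", minFsc = "numeric",
                 gfpThresh = "numeric", rfpThresh = "numeric"),
  validity = function(object) {
    msg <- character()
    b <- object@fscRatioBand
    if (length(b) != 2L || !(b[1] < b[2]))
      msg <- c(msg, "fscRatioBand must be a non-empty interval (lo < hi)")
    if (object@gfpThresh <= 0 || object@rfpThresh <= 0)
      msg <- c(msg, "thresholds must be strictly positive")
    if (object@minFsc < 0) msg <- c(msg, "minFsc must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Two-inducer phase diagram of attractors reached from the OFF state
#'
#' @slot lAraGrid,c6Grid inducer grids (strictly increasing).
#' @slot labels character matrix, length(lAraGrid) x length(c6Grid), each
#'   cell the fate label of the attractor reached from OFF.
#' @slot x1,x2 numeric matrices of the same shape: protein levels at the
#'   reached attractor.
#' @slot coactivationCount integer, number of cells labelled coactivation.
#' @slot condition named list (topology, mode, atc).
#' @export
setClass("PhaseDiagram",
  representation(lAraGrid = "numeric", c6Grid = "numeric",
                 labels = "matrix", x1 = "matrix", x2 = "matrix",
                 coactivationCount = "integer",
                 condition = "list"),
  validity = function(object) {
    msg <- character()
    dims <- c(length(object@lAraGrid), length(object@c6Grid))
    if (!identical(dim(object@labels), dims))
      msg <- c(msg, "label matrix dimensions must match the grids")
    if (!identical(dim(object@x1), dims) || !identical(dim(object@x2), dims))
      msg <- c(msg, "x1/x2 matrix dimensions must match the grids")
    if (object@coactivationCount !=
        sum(object@labels == "coactivation"))
      msg <- c(msg, "coactivationCount must equal the number of coactivation cells")
    if (length(msg)) msg else TRUE
  })

#' Planted four-component fluorescence mixture (model-free generator)
#'
#' Describes a ground-truth mixture of four bivariate lognormal clusters
#' (OFF, M1_only, M2_only, coactivation) in GFP x RFP space, used to
#' generate event tables whose true composition is known exactly.
#'
#' @slot meansGfp,meansRfp named numeric of length 4; linear-scale cluster
#'   medians (au), names OFF, M1_only, M2_only, coactivation.
#' @slot sdlog log-scale s.d. shared by all clusters.
#' @slot fractions simplex over the four clusters.
#' @slot nEvents number of events to draw.
#' @slot doubletFrac fraction of events replaced by doublets.
#' @slot seed integer seed making the draw fully deterministic.
#' @export
setClass("PlantedMixture",
  representation(meansGfp = "numeric", meansRfp = "numeric",
                 sdlog = "numeric", fractions = "numeric",
                 nEvents = "integer", doubletFrac = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!identical(names(object@fractions), .FATE_LABELS) ||
        !identical(names(object@meansGfp), .FATE_LABELS) ||
        !identical(names(object@meansRfp), .FATE_LABELS))
      return("meansGfp, meansRfp and fractions must be named OFF, M1_only, M2_only, coactivation")
    if (any(object@fractions < 0) ||
        abs(sum(object@fractions) - 1) > 1e-12)
      msg <- c(msg, "fractions must be non-negative and sum to 1")
    ## separability guarantee: ON means at least one decade above OFF
    if (object@meansGfp[["M1_only"]] < 10 * object@meansGfp[["OFF"]] ||
        object@meansRfp[["M2_only"]] < 10 * object@meansRfp[["OFF"]])
      msg <- c(msg, "ON cluster means must exceed OFF means by >= 1 decade")
    if (object@doubletFrac < 0 || object@doubletFrac >= 0.5)
      msg <- c(msg, "doubletFrac must be in [0, 0.5)")
    if (object@nEvents < 1L) msg <- c(msg, "nEvents must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Planted plate-reader experiment (model-free generator)
#'
#' @slot odCapacity,odRate,odLag logistic growth parameters (capacity OD600,
#'   rate 1/h, lag h) shared by all wells.
#' @slot ratios named numeric; true steady fluorescence/OD ratio per dose
#'   (names are the dose values as strings).
#' @slot noiseSd multiplicative noise s.d. (log scale).
#' @slot replicates number of replicate wells per dose.
#' @slot times numeric vector of measurement times (h), strictly increasing.
#' @slot seed integer seed.
#' @export
setClass("PlantedPlate",
  representation(odCapacity = "numeric", odRate = "numeric",
                 odLag = "numeric", ratios = "numeric",
                 noiseSd = "numeric", replicates = "integer",
                 times = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@odCapacity <= 0 || object@odRate <= 0 || object@odLag < 0)
      msg <- c(msg, "growth parameters must be positive (lag non-negative)")
    if (any(object@ratios < 0)) msg <- c(msg, "ratios must be non-negative")
    if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
    if (is.unsorted(object@times, strictly = TRUE))
      msg <- c(msg, "times must be strictly increasing")
    if (length(msg)) msg else TRUE
  })
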
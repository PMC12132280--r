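#' @include AllClasses.R
NULL

#' Extract the per-event data of an EventTable
#' @param x an object with event records.
#' @return a data.frame with columns fsc_a, fsc_h, gfp, rfp.
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' Number of events in a sample
#' @param x an EventTable.
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' Condition / sample metadata
#' @param x an object carrying metadata.
#' @export
setGeneric("meta", function(x) standardGeneric("meta"))

#' Per-replicate fraction matrix of a FateFractions object
#' @param x a FateFractions.
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))

#' Attractor label matrix of a phase diagram
#' @param x a PhaseDiagram.
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' Number of grid cells whose attractor-from-OFF is coactivation
#' @param x a PhaseDiagram.
#' @export
setGeneric("coactivationCount", function(x) standardGeneric("coactivationCount"))

#' @rdname events
#' @export
setMethod("events", "EventTable", function(x) x@events)

#' @rdname nEvents
#' @export
setMethod("nEvents", "EventTable", function(x) nrow(x@events))

#' @rdname meta
#' @export
setMethod("meta", "EventTable", function(x) x@metadata)

#' @rdname meta
#' @export
setMethod("meta", "PlateSeries", function(x) x@metadata)

#' @rdname fractions
#' @export
setMethod("fractions", "FateFractions", function(x) x@fractions)

#' @rdname labelMatrix
#' @export
setMethod("labelMatrix", "PhaseDiagram", function(x) x@labels)

#' @rdname coactivationCount
#' @export
setMethod("coactivationCount", "PhaseDiagram", function(x) x@coactivationCount)

setMethod("show", "Topology", function(object) {
  cat(sprintf("%s circuit, %s controller\n", object@kind,
              sub("_", "-", object@controller)))
})

setMethod("show", "Inducers", function(object) {
  cat(sprintf("Inducers: L-ara %.4g %% w/v, C6 %.4g nM, aTc %.4g ng/mL\n",
              object@lAra, object@c6, object@atc))
})

setMethod("show", "CircuitParams", function(object) {
  cat("CircuitParams with", length(object), "fields\n")
  v <- unlist(object@.Data)
  names(v) <- names(object)
  print(utils::head(v, 12))
  if (length(v) > 12) cat("...", length(v) - 12, "more; access with [[\n")
})

setMethod("show", "SteadyState", function(object) {
  cat(sprintf("SteadyState <%s>%s  |rhs| = %.2e\n", object@label,
              if (object@stable) " (stable)" else " (unstable)",
              object@rhsNorm))
  print(signif(object@state, 4))
})

setMethod("show", "EventTable", function(object) {
  md <- object@metadata
  cat(sprintf("EventTable: %d events", nrow(object@events)))
  if (!is.null(md$topology))
    cat(sprintf(" [%s/%s]", md$topology, md$mode))
  if (!is.null(md$replicate)) cat(sprintf(" replicate %s", md$replicate))
  cat("\n")
})

setMethod("show", "PlateSeries", function(object) {
  cat(sprintf("PlateSeries: %d time points over %.1f h (well %s)\n",
              nrow(object@data), max(object@data$time_h),
              object@metadata$well %||% "?"))
})

setMethod("show", "FateFractions", function(object) {
  cat(sprintf("FateFractions over %d replicate(s)\n", nrow(object@fractions)))
  out <- rbind(mean = object@mean, sd = object@sd)
  print(signif(out, 4))
})

setMethod("show", "PhaseDiagram", function(object) {
  cat(sprintf("PhaseDiagram %dx%d (%s/%s, aTc %.3g): %d coactivation cells\n",
              length(object@lAraGrid), length(object@c6Grid),
              object@condition$topology %||% "?",
              object@condition$mode %||% "?",
              object@condition$atc %||% NA_real_,
              object@coactivationCount))
})
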
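#' @include AllClasses.R params.R
NULL

#' Singlet gate on forward-scatter area vs height
#'
#' Keeps events whose \code{fsc_a/fsc_h} ratio lies inside the configured
#' band and whose \code{fsc_h} clears the small-particle cutoff, removing
#' cell doublets (ratio near 2) and debris, as done before any
#' fluorescence analysis.
#'
#' @param x an \linkS4class{EventTable}.
#' @param gate a \linkS4class{GateConfig}.
#' @return the filtered \linkS4class{EventTable}; the gate report (kept and
#'   dropped counts, and which events were kept) is stored in
#'   \code{meta(x)$gateReport}.
#' @export
singletGate <- function(x, gate) {
  stopifnot(is(x, "EventTable"), is(gate, "GateConfig"))
  ev <- x@events
  if (!nrow(ev)) stop("event table is empty", call. = FALSE)
  ratio <- ev$fsc_a / ev$fsc_h
  keep <- ratio >= gate@fscRatioBand[1] & ratio <= gate@fscRatioBand[2] &
    ev$fsc_h >= gate@minFsc
  if (!any(keep))
    stop("singlet gate (fsc_a/fsc_h band ", gate@fscRatioBand[1], "-",
         gate@fscRatioBand[2], ", min fsc_h ", gate@minFsc,
         ") removed all events", call. = FALSE)
  md <- x@metadata
  md$n_events <- sum(keep)
  md$gateReport <- list(kept = sum(keep), dropped = sum(!keep),
                        keptIndex = which(keep))
  new("EventTable", events = ev[keep, , drop = FALSE], metadata = md)
}

#' Estimate ON thresholds from a negative control
#'
#' Sets the GFP and RFP quadrant thresholds at an upper quantile (default
#' 0.995) of a negative-control sample (e.g. blank medium), the standard
#' blank-based gating rule.
#'
#' @param control an \linkS4class{EventTable} with >= 500 events.
#' @param quantile upper quantile used per channel.
#' @param margin additive margin applied when a channel is degenerate
#'   (constant), with a warning.
#' @return named numeric: \code{gfp_thresh}, \code{rfp_thresh}.
#' @export
estimateThresholds <- function(control, quantile = 0.995, margin = 1) {
  stopifnot(is(control, "EventTable"))
  if (nrow(control@events) < 500)
    stop("negative control must have >= 500 events", call. = FALSE)
  if (quantile < 0 || quantile > 1)
    stop("quantile must be in [0, 1]", call. = FALSE)
  one <- function(v, chan) {
    if (max(v) - min(v) < .Machine$double.eps * max(abs(v), 1)) {
      warning(sprintf("%s channel is constant in the control; threshold = constant + margin",
                      chan))
      return(v[1] + margin)
    }
    as.numeric(stats::quantile(v, quantile, type = 7))
  }
  c(gfp_thresh = one(control@events$gfp, "gfp"),
    rfp_thresh = one(control@events$rfp, "rfp"))
}

.classifyEvents <- function(ev, gate) {
  on1 <- ev$gfp >= gate@gfpThresh
  on2 <- ev$rfp >= gate@rfpThresh
  ifelse(on1 & on2, "coactivation",
         ifelse(on1, "M1_only", ifelse(on2, "M2_only", "OFF")))
}

#' Quadrant fate fractions of one sample
#'
#' Assigns every event exactly one of the four fate labels by comparing
#' GFP and RFP against the ON thresholds (GFP-high/RFP-low = M1_only,
#' GFP-high/RFP-high = coactivation, and so on) and reports the fractions.
#'
#' @param x an \linkS4class{EventTable}, ordinarily already singlet-gated.
#' @param gate a \linkS4class{GateConfig}.
#' @param applyGate apply \code{\link{singletGate}} first when the table
#'   has not been gated yet (flagged in the metadata).
#' @return a \linkS4class{FateFractions} with a single replicate row
#'   (s.d. is NA).
#' @export
quadrantFractions <- function(x, gate, applyGate = TRUE) {
  stopifnot(is(x, "EventTable"), is(gate, "GateConfig"))
  if (!nrow(x@events)) stop("no events to classify", call. = FALSE)
  if (applyGate && is.null(x@metadata$gateReport))
    x <- singletGate(x, gate)
  lab <- factor(.classifyEvents(x@events, gate), levels = .FATE_LABELS)
  fr <- as.numeric(table(lab)) / length(lab)
  frm <- matrix(fr, nrow = 1, dimnames = list(NULL, .FATE_LABELS))
  new("FateFractions", fractions = frm,
      mean = stats::setNames(fr, .FATE_LABELS),
      sd = stats::setNames(rep(NA_real_, 4), .FATE_LABELS),
      nEventsUsed = nrow(x@events),
      condition = x@metadata[intersect(names(x@metadata),
        c("l_ara", "c6", "atc", "topology", "mode"))])
}

.conditionKey <- function(md) {
  paste(md$topology %||% "", md$mode %||% "", md$l_ara %||% "",
        md$c6 %||% "", md$atc %||% "", sep = "|")
}

#' Fate fractions across replicates, per condition
#'
#' Groups replicate event tables by condition (inducers, topology,
#' controller mode), computes each replicate's quadrant fractions, and
#' aggregates as mean and sample s.d. (n - 1).  Conditions are ordered by
#' the scanned inducer (the one that varies).
#'
#' @param tables list of \linkS4class{EventTable}, >= 2 replicates per
#'   condition.
#' @param gate a \linkS4class{GateConfig}.
#' @param applyGate forwarded to \code{\link{quadrantFractions}}.
#' @return a named list of \linkS4class{FateFractions}, one per condition,
#'   ordered by the scanned dose; names are the dose values.
#' @export
fractionSeries <- function(tables, gate, applyGate = TRUE) {
  stopifnot(length(tables) >= 1,
            all(vapply(tables, is, logical(1), "EventTable")))
  keys <- vapply(tables, function(x) .conditionKey(x@metadata), character(1))
  groups <- split(tables, keys)
  if (any(lengths(groups) < 2))
    stop("each condition needs >= 2 replicates; found a condition with ",
         min(lengths(groups)), call. = FALSE)
  perCond <- lapply(groups, function(g) {
    md <- lapply(g, function(x) x@metadata[c("topology", "mode", "l_ara",
                                             "c6", "atc")])
    if (length(unique(vapply(md, .conditionKey, character(1)))) != 1)
      stop("replicates disagree on condition metadata", call. = FALSE)
    reps <- lapply(g, quadrantFractions, gate = gate, applyGate = applyGate)
    frm <- do.call(rbind, lapply(reps, slot, "fractions"))
    new("FateFractions", fractions = frm,
        mean = stats::setNames(colMeans(frm), .FATE_LABELS),
        sd = stats::setNames(apply(frm, 2, stats::sd), .FATE_LABELS),
        nEventsUsed = vapply(reps, function(r) r@nEventsUsed[1], integer(1)),
        condition = md[[1]])
  })
  ## order by the scanned (varying) inducer
  doses <- vapply(perCond, function(f) {
    cond <- f@condition
    c(cond$l_ara %||% NA_real_, cond$c6 %||% NA_real_,
      cond$atc %||% NA_real_)
  }, numeric(3))
  vary <- which(apply(doses, 1, function(v)
    length(unique(v[!is.na(v)])) > 1))
  axis <- if (length(vary)) vary[1] else 1L
  axisName <- c("l_ara", "c6", "atc")[axis]
  ord <- order(vapply(perCond, function(f)
    paste(f@condition$topology %||% "", f@condition$mode %||% ""),
    character(1)), doses[axis, ])
  out <- perCond[ord]
  names(out) <- vapply(out, function(f) {
    cond <- f@condition
    sprintf("%s_%s_%s=%g", cond$topology %||% "NA", cond$mode %||% "NA",
            axisName, c(cond$l_ara %||% NA, cond$c6 %||% NA,
                        cond$atc %||% NA)[axis])
  }, character(1))
  attr(out, "scanAxis") <- axisName
  out
}

#' Plate-reader dose-response extraction
#'
#' Per well, the readout is the mean over a terminal time window of
#' \code{(fluorescence - blank) / OD600}; wells whose OD never clears the
#' floor inside the window are excluded with a warning.  The blank level is
#' taken from blank wells when present (flagged in metadata), else from the
#' configured constant.
#'
#' @param series list of \linkS4class{PlateSeries} (replicate wells across
#'   doses); each non-blank well's metadata must carry a \code{dose}.
#' @param window length of the terminal time window (h), or a length-2
#'   interval of times.
#' @param channel "gfp" or "rfp".
#' @param odFloor minimum OD600 for a usable measurement.
#' @param blankValue fallback blank fluorescence when no blank well exists.
#' @return a data.frame with columns dose, mean, sd, n (replicates used),
#'   ordered by dose.
#' @export
plateDoseResponse <- function(series, window = 4, channel = c("gfp", "rfp"),
                              odFloor = 0.05, blankValue = 0) {
  channel <- match.arg(channel)
  stopifnot(all(vapply(series, is, logical(1), "PlateSeries")))
  isBlank <- vapply(series, function(s) isTRUE(s@metadata$blank), logical(1))
  tmax <- max(vapply(series, function(s) max(s@data$time_h), numeric(1)))
  win <- if (length(window) == 2) window else c(tmax - window, tmax)
  inWin <- function(s) s@data$time_h >= win[1] & s@data$time_h <= win[2]
  blank <- if (any(isBlank)) {
    ## the blank well: lowest terminal OD among flagged wells
    bw <- series[isBlank]
    odEnd <- vapply(bw, function(s) mean(s@data$od600[inWin(s)]), numeric(1))
    b <- bw[[which.min(odEnd)]]
    mean(b@data[[channel]][inWin(b)])
  } else blankValue
  rows <- list()
  for (s in series[!isBlank]) {
    sel <- inWin(s)
    if (!any(sel)) stop("window lies outside the series time span",
                        call. = FALSE)
    od <- s@data$od600[sel]
    if (all(od < odFloor)) {
      warning(sprintf("well %s excluded: OD below %.3g throughout the window",
                      s@metadata$well %||% "?", odFloor))
      next
    }
    use <- od >= odFloor
    val <- mean((s@data[[channel]][sel][use] - blank) / od[use])
    dose <- s@metadata$dose
    if (is.null(dose))
      dose <- s@metadata$l_ara %||% s@metadata$c6 %||% NA_real_
    rows[[length(rows) + 1L]] <- data.frame(dose = dose, value = val)
  }
  if (!length(rows)) stop("no usable wells", call. = FALSE)
  df <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(df, df$dose), function(d)
    data.frame(dose = d$dose[1], mean = mean(d$value),
               sd = if (nrow(d) > 1) stats::sd(d$value) else NA_real_,
               n = nrow(d))))
  agg[order(agg$dose), , drop = FALSE]
}

#' Write fate fractions as tidy CSV
#'
#' @param fractionList named list of \linkS4class{FateFractions} (as from
#'   \code{\link{fractionSeries}}).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeFractionsCSV <- function(fractionList, path) {
  rows <- list()
  for (nm in names(fractionList)) {
    f <- fractionList[[nm]]
    for (r in seq_len(nrow(f@fractions))) for (lab in .FATE_LABELS) {
      rows[[length(rows) + 1L]] <- data.frame(
        condition = nm, replicate = r, label = lab,
        fraction = f@fractions[r, lab])
    }
  }
  df <- do.call(rbind, rows)
  df$fraction <- .fmtNum(df$fraction)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Quadrant scatter plot of an event table
#'
#' Log-log scatter of GFP vs RFP with the quadrant thresholds, for visual
#' inspection of fate clouds.
#'
#' @param x an \linkS4class{EventTable}.
#' @param gate a \linkS4class{GateConfig}.
#' @param ... passed to \code{plot}.
#' @return invisibly, the classification table.
#' @export
plotQuadrants <- function(x, gate, ...) {
  ev <- x@events
  graphics::plot(pmax(ev$gfp, 0.1), pmax(ev$rfp, 0.1), log = "xy",
                 pch = ".", xlab = "GFP (au)", ylab = "RFP (au)", ...)
  graphics::abline(v = gate@gfpThresh, h = gate@rfpThresh, lty = 2,
                   col = "grey40")
  invisible(table(.classifyEvents(ev, gate)))
}
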
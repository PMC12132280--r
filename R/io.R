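#' @include AllClasses.R params.R
NULL

#' Write an event table as CSV with a JSON metadata sidecar
#'
#' The CSV carries only the measurement columns (header
#' \code{fsc_a,fsc_h,gfp,rfp}); condition metadata goes to
#' \code{<path>.json}.  Output is byte-deterministic for identical input.
#'
#' @param x an \linkS4class{EventTable}.
#' @param path output CSV path (sidecar written next to it).
#' @return the path, invisibly.
#' @export
writeEventTable <- function(x, path) {
  stopifnot(is(x, "EventTable"))
  ev <- x@events[, c("fsc_a", "fsc_h", "gfp", "rfp")]
  out <- data.frame(lapply(ev, .fmtNum))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  md <- x@metadata
  md$gateReport <- NULL
  jsonlite::write_json(md, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an event table written by \code{\link{writeEventTable}}
#'
#' @param path CSV path; the \code{<path>.json} sidecar is read when
#'   present.
#' @return an \linkS4class{EventTable}.
#' @export
readEventTable <- function(path) {
  ev <- utils::read.csv(path)
  need <- c("fsc_a", "fsc_h", "gfp", "rfp")
  if (!all(need %in% names(ev)))
    stop(path, " lacks the event columns ", paste(need, collapse = ", "),
         call. = FALSE)
  side <- paste0(path, ".json")
  md <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
        else list()
  md$n_events <- nrow(ev)
  eventTable(ev[, need], metadata = as.list(md))
}

.PLATE_META_COLS <- c("well", "blank", "dose", "replicate", "l_ara", "c6",
                      "atc", "topology", "mode")

#' Write plate series as one tidy CSV
#'
#' One row per (well, time point) with columns time_h, od600, gfp, rfp,
#' well plus any condition metadata fields present.
#'
#' @param series a \linkS4class{PlateSeries} or list of them.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writePlateSeries <- function(series, path) {
  if (is(series, "PlateSeries")) series <- list(series)
  rows <- lapply(series, function(s) {
    d <- s@data
    for (f in .PLATE_META_COLS) {
      v <- s@metadata[[f]]
      d[[f]] <- if (is.null(v)) NA else v
    }
    d
  })
  df <- do.call(rbind, rows)
  for (col in c("time_h", "od600", "gfp", "rfp", "dose", "l_ara", "c6", "atc"))
    if (is.numeric(df[[col]])) df[[col]] <- .fmtNum(df[[col]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read plate series from a tidy CSV
#'
#' @param path CSV path as written by \code{\link{writePlateSeries}}.
#' @return a list of \linkS4class{PlateSeries}, one per well.
#' @export
readPlateSeries <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_h", "od600", "gfp", "rfp", "well")
  if (!all(need %in% names(df)))
    stop(path, " lacks the plate columns ", paste(need, collapse = ", "),
         call. = FALSE)
  lapply(split(df, df$well), function(d) {
    d <- d[order(d$time_h), , drop = FALSE]
    md <- lapply(intersect(.PLATE_META_COLS, names(d)), function(f) d[[f]][1])
    names(md) <- intersect(.PLATE_META_COLS, names(d))
    md <- Filter(function(v) !is.na(v), md)
    if (!is.null(md$blank)) md$blank <- as.logical(md$blank)
    plateSeries(d[, c("time_h", "od600", "gfp", "rfp")], metadata = md)
  })
}

.CONFIG_SECTIONS <- list(
  topology = c("kind", "controller"),
  inducers = c("l_ara", "c6", "atc"),
  params = NULL,                    # validated against CircuitParams fields
  simulation = c("horizon", "n_events", "replicates", "seed", "scan_axis",
                 "grid", "l_ara_grid", "c6_grid", "dt", "scan_type",
                 "module"),
  noise = c("cv_extrinsic", "sigma_meas", "doublet_frac", "autofluor_gfp",
            "autofluor_rfp", "od_capacity", "od_rate", "od0"),
  gate = c("fsc_ratio_band", "min_fsc", "gfp_thresh", "rfp_thresh",
           "quantile"),
  flow = c("dir", "pattern"),
  plate = c("file", "window", "channel", "od_floor", "blank_value"),
  generate = c("n_events", "replicates", "dry_run"))

#' Read and validate a YAML run configuration
#'
#' Sections: \code{topology}, \code{inducers}, \code{params},
#' \code{simulation}, \code{noise}, \code{gate}, \code{flow}, \code{plate},
#' \code{generate}.  Every \linkS4class{CircuitParams} field is addressable
#' by name under \code{params}; unknown sections or keys are rejected with
#' the offending name.
#'
#' @param path YAML file path.
#' @return a named list with validated sections and parsed objects in
#'   \code{$topologyObj}, \code{$inducersObj}, \code{$paramsObj},
#'   \code{$noiseObj}, \code{$gateObj}.
#' @export
readCircuitConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  bad <- setdiff(names(cfg), names(.CONFIG_SECTIONS))
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (sec in names(cfg)) {
    allowed <- .CONFIG_SECTIONS[[sec]]
    if (sec == "params") allowed <- .PARAM_FIELDS
    extra <- setdiff(names(cfg[[sec]]), allowed)
    if (length(extra))
      stop(sprintf("unknown key(s) in [%s]: %s", sec,
                   paste(extra, collapse = ", ")), call. = FALSE)
  }
  cfg$paramsObj <- do.call(circuitParams, cfg$params %||% list())
  topo <- cfg$topology %||% list()
  cfg$topologyObj <- topology(topo$kind %||% "DSA",
                              topo$controller %||% "non_targeting")
  ind <- cfg$inducers %||% list()
  cfg$inducersObj <- inducers(lAra = ind$l_ara %||% 0, c6 = ind$c6 %||% 0,
                              atc = ind$atc %||% 0)
  nz <- cfg$noise %||% list()
  cfg$noiseObj <- noiseModel(
    cvExtrinsic = nz$cv_extrinsic %||% 0.25,
    sigmaMeas = nz$sigma_meas %||% 0.1,
    doubletFrac = nz$doublet_frac %||% 0.05,
    autofluorGfp = nz$autofluor_gfp %||% 1,
    autofluorRfp = nz$autofluor_rfp %||% 1,
    odCapacity = nz$od_capacity %||% 1.2,
    odRate = nz$od_rate %||% 0.8,
    od0 = nz$od0 %||% 0.02)
  gt <- cfg$gate %||% list()
  cfg$gateObj <- gateConfig(
    fscRatioBand = unlist(gt$fsc_ratio_band %||% c(0.7, 1.4)),
    minFsc = gt$min_fsc %||% 5e3,
    gfpThresh = gt$gfp_thresh %||% 50,
    rfpThresh = gt$rfp_thresh %||% 50)
  cfg
}
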
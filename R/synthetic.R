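#' @include AllClasses.R params.R cytometry.R population.R
NULL

#' Construct a PlantedMixture
#'
#' Model-free ground truth for generator-based pipeline tests: four
#' decade-separated bivariate lognormal clusters in GFP x RFP space with
#' known fractions and doublet contamination.
#'
#' @param fractions simplex over OFF, M1_only, M2_only, coactivation (in
#'   that order, or named).
#' @param nEvents events to draw.
#' @param doubletFrac fraction of events replaced by doublets.
#' @param seed integer seed.
#' @param meansGfp,meansRfp linear-scale cluster medians (au); defaults put
#'   ON clusters two decades above OFF.
#' @param sdlog shared log-scale cluster s.d.
#' @return a \linkS4class{PlantedMixture}.
#' @export
plantedMixture <- function(fractions = c(0.25, 0.25, 0.25, 0.25),
                           nEvents = 10000L, doubletFrac = 0.05,
                           seed = 1L,
                           meansGfp = c(OFF = 10, M1_only = 1000,
                                        M2_only = 10, coactivation = 1000),
                           meansRfp = c(OFF = 10, M1_only = 10,
                                        M2_only = 1000, coactivation = 1000),
                           sdlog = 0.25) {
  if (is.null(names(fractions))) names(fractions) <- .FATE_LABELS
  fractions <- fractions[.FATE_LABELS]
  new("PlantedMixture", meansGfp = meansGfp[.FATE_LABELS],
      meansRfp = meansRfp[.FATE_LABELS], sdlog = sdlog,
      fractions = fractions, nEvents = as.integer(nEvents),
      doubletFrac = doubletFrac, seed = as.integer(seed))
}

#' Generate a flow-like event table from a planted mixture
#'
#' Pure function of the mixture specification and its seed.  Events are
#' drawn per component from bivariate lognormals; a \code{doubletFrac}
#' subset is replaced by doublets (summed fluorescence of two events,
#' \code{fsc_a} near twice \code{fsc_h}).  The per-event ground truth
#' travels separately from the measurement table, so the analysis pipeline
#' cannot see it.
#'
#' @param mixture a \linkS4class{PlantedMixture}.
#' @param metadata extra condition metadata stored in the event table.
#' @return a list with \code{events} (an \linkS4class{EventTable}) and
#'   \code{truth} (data.frame: per-event component label and doublet flag).
#' @export
generateFlow <- function(mixture, metadata = list()) {
  stopifnot(is(mixture, "PlantedMixture"))
  n <- mixture@nEvents
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(mixture@seed)
  comp <- sample(.FATE_LABELS, n, replace = TRUE, prob = mixture@fractions)
  gfp <- stats::rlnorm(n, log(mixture@meansGfp[comp]), mixture@sdlog)
  rfp <- stats::rlnorm(n, log(mixture@meansRfp[comp]), mixture@sdlog)
  fscH <- stats::rlnorm(n, log(5e4), 0.18)
  ratio <- pmax(1 + stats::rnorm(n, 0, 0.03), 0.5)
  doublet <- rep(FALSE, n)
  nDbl <- round(mixture@doubletFrac * n)
  if (nDbl > 0) {
    idx <- sample.int(n, nDbl)
    partner <- sample.int(n, nDbl, replace = TRUE)
    gfp[idx] <- gfp[idx] + gfp[partner]
    rfp[idx] <- rfp[idx] + rfp[partner]
    ratio[idx] <- pmax(2 + stats::rnorm(nDbl, 0, 0.1), 1.5)
    doublet[idx] <- TRUE
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  md <- c(metadata, list(n_events = n, seed = mixture@seed))
  list(events = eventTable(data.frame(fsc_a = fscH * ratio, fsc_h = fscH,
                                      gfp = gfp, rfp = rfp), md),
       truth = data.frame(label = comp, doublet = doublet))
}

#' Construct a PlantedPlate
#'
#' @param ratios named numeric of true steady fluorescence/OD ratios, one
#'   per dose (names are dose values).
#' @param replicates wells per dose.
#' @param noiseSd multiplicative noise s.d. (log scale).
#' @param seed integer seed.
#' @param odCapacity,odRate,odLag logistic growth parameters.
#' @param times measurement times (h).
#' @return a \linkS4class{PlantedPlate}.
#' @export
plantedPlate <- function(ratios = c("0" = 5, "0.001" = 120, "0.01" = 400),
                         replicates = 3L, noiseSd = 0.02, seed = 1L,
                         odCapacity = 1.2, odRate = 0.8, odLag = 1,
                         times = seq(0, 16, by = 0.5)) {
  new("PlantedPlate", odCapacity = odCapacity, odRate = odRate,
      odLag = odLag, ratios = ratios, noiseSd = noiseSd,
      replicates = as.integer(replicates), times = times,
      seed = as.integer(seed))
}

#' Generate plate-reader series from a planted plate experiment
#'
#' OD600 follows the planted logistic curve with multiplicative noise;
#' fluorescence is the planted ratio times the OD with its own noise.  One
#' blank (medium-only) well is appended.
#'
#' @param plate a \linkS4class{PlantedPlate}.
#' @return a list with \code{series} (list of \linkS4class{PlateSeries},
#'   one per well) and \code{truth} (the planted ratios).
#' @export
generatePlate <- function(plate) {
  stopifnot(is(plate, "PlantedPlate"))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(plate@seed)
  t <- plate@times
  o0 <- 0.02; K <- plate@odCapacity; r <- plate@odRate
  base <- K * o0 / (o0 + (K - o0) * exp(-r * pmax(t - plate@odLag, 0)))
  series <- list()
  for (di in seq_along(plate@ratios)) {
    dose <- as.numeric(names(plate@ratios)[di])
    for (rep in seq_len(plate@replicates)) {
      od <- base * exp(stats::rnorm(length(t), 0, plate@noiseSd))
      fl <- plate@ratios[di] * od * exp(stats::rnorm(length(t), 0,
                                                     plate@noiseSd))
      series[[length(series) + 1L]] <- plateSeries(
        data.frame(time_h = t, od600 = od, gfp = fl, rfp = fl),
        metadata = list(well = sprintf("D%dR%d", di, rep), dose = dose,
                        replicate = rep, blank = FALSE))
    }
  }
  odb <- rep(0.04, length(t)) * exp(stats::rnorm(length(t), 0,
                                                 plate@noiseSd))
  series[[length(series) + 1L]] <- plateSeries(
    data.frame(time_h = t, od600 = odb,
               gfp = abs(stats::rnorm(length(t), 0, 1e-9)),
               rfp = abs(stats::rnorm(length(t), 0, 1e-9))),
    metadata = list(well = "BLK", blank = TRUE))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  list(series = series, truth = plate@ratios)
}

#' Write a deterministic fixture suite with ground-truth manifest
#'
#' Produces a small set of measurement files for pipeline tests and
#' documentation: a WTA-like C6 scan (coactivation rising then collapsing
#' into M2-only), a rescue-like scan (coactivation rising and saturating),
#' a blank negative control, and a plate dose scan.  Ground truth travels
#' in sidecar JSON; the manifest lists every file with its md5 hash, seed
#' and planted truth.
#'
#' @param outDir writable output directory (created if missing).
#' @param seed integer master seed.
#' @param nEvents events per flow sample.
#' @param replicates replicates per condition.
#' @param dryRun if TRUE, write only the manifest (no data files).
#' @return the manifest, invisibly; written as \code{manifest.json}.
#' @export
makeFixtureSuite <- function(outDir, seed = 1L, nEvents = 2000L,
                             replicates = 3L, dryRun = FALSE) {
  if (!dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  wtaFracs <- list(                      # C6-scan analogue, control circuit
    c(0.05, 0.85, 0.05, 0.05),
    c(0.05, 0.55, 0.15, 0.25),
    c(0.05, 0.15, 0.45, 0.35),
    c(0.05, 0.05, 0.80, 0.10))
  rescueFracs <- list(                   # same scan, NCR controller
    c(0.15, 0.60, 0.05, 0.20),
    c(0.10, 0.35, 0.10, 0.45),
    c(0.05, 0.15, 0.15, 0.65),
    c(0.05, 0.10, 0.15, 0.70))
  doses <- c(1, 10, 100, 1000)
  files <- list()
  k <- 0L
  emitScan <- function(fracs, mode, files) {
    for (i in seq_along(doses)) for (rep in seq_len(replicates)) {
      k <<- k + 1L
      fr <- stats::setNames(fracs[[i]], NULL)  # (OFF, M1, M2, coactivation)
      mix <- plantedMixture(
        fractions = c(OFF = fr[1], M1_only = fr[2], M2_only = fr[3],
                      coactivation = fr[4]),
        nEvents = nEvents, seed = .childSeed(seed, k))
      fn <- sprintf("flow_%s_c6-%g_rep%d.csv", mode, doses[i], rep)
      if (!dryRun) {
        gen <- generateFlow(mix, metadata = list(
          l_ara = 1.25e-3, c6 = doses[i], atc = 15, topology = "DSA",
          mode = mode, replicate = rep))
        writeEventTable(gen$events, file.path(outDir, fn))
      }
      files[[fn]] <- list(file = fn, type = "flow", mode = mode,
                          c6 = doses[i], replicate = rep,
                          seed = .childSeed(seed, k),
                          fractions = as.list(stats::setNames(fr,
                            .FATE_LABELS)))
    }
    files
  }
  files <- emitScan(wtaFracs, "non_targeting", files)
  files <- emitScan(rescueFracs, "targeting", files)
  ## blank negative control
  k <- k + 1L
  blankMix <- plantedMixture(fractions = c(1, 0, 0, 0), nEvents = nEvents,
                             doubletFrac = 0, seed = .childSeed(seed, k))
  if (!dryRun) {
    gen <- generateFlow(blankMix, metadata = list(mode = "blank",
                                                  replicate = 1))
    writeEventTable(gen$events, file.path(outDir, "flow_blank.csv"))
  }
  files[["flow_blank.csv"]] <- list(file = "flow_blank.csv", type = "flow",
                                    mode = "blank",
                                    seed = .childSeed(seed, k),
                                    fractions = list(OFF = 1, M1_only = 0,
                                                     M2_only = 0,
                                                     coactivation = 0))
  ## plate scan
  k <- k + 1L
  pl <- plantedPlate(seed = .childSeed(seed, k), replicates = replicates)
  if (!dryRun) {
    gen <- generatePlate(pl)
    writePlateSeries(gen$series, file.path(outDir, "plate_scan.csv"))
  }
  files[["plate_scan.csv"]] <- list(file = "plate_scan.csv", type = "plate",
                                    seed = .childSeed(seed, k),
                                    ratios = as.list(pl@ratios))
  manifest <- list(seed = seed, n_events = nEvents,
                   replicates = replicates, files = unname(files))
  if (!dryRun) {
    paths <- file.path(outDir, vapply(files, `[[`, "", "file"))
    hashes <- tools::md5sum(paths[file.exists(paths)])
    manifest$md5 <- as.list(stats::setNames(unname(hashes),
                                            basename(names(hashes))))
  }
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
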
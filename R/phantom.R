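## Synthetic tissue phantom: a two-region stained-tissue micrograph
## (eosin-pink tumor inside purple normal liver), exponential 211At decay,
## isotropic alpha emission with angular acceptance, and forward-modelled
## etch pits that invert exactly through the pit-geometry equations. The
## phantom provides full ground truth so the entire pipeline can be
## validated end to end.

.PINK_FILL <- c(150L, 60L, 120L)
.PURPLE_FILL <- c(120L, 80L, 160L)
.BACKGROUND <- c(255L, 255L, 255L)

#' Phantom configuration
#'
#' Ground-truth layout and source terms for the synthetic phantom. The
#' default is a desk-scale 2 x 2 mm field at 2 um/pixel: a purple tissue
#' ellipse containing two pink tumor ellipses, a 6:1 tumor-to-normal
#' activity contrast, 211At decay (half-life 7.2 h) recorded over the
#' 12-43 h window, and an alpha LET distribution peaked at 130 keV/um
#' (normal, sd 20, truncated to the detectable 3.5-600 keV/um range).
#' Activities are expected decays per mm^2 over all time from injection;
#' the defaults are chosen so the default field yields on the order of
#' 2 x 10^4 registered tracks.
#'
#' @slot imageSizePx image size (rows, cols).
#' @slot pixelSizeUm pixel size (um).
#' @slot tissueEllipses,tumorEllipses matrices with columns cx, cy
#'   (center, um) and a, b (semi-axes, um); tumor ellipses must lie inside
#'   the image.
#' @slot activityTumorPerMm2 expected tumor decays per mm^2 over [0, Inf).
#' @slot contrast tumor-to-normal activity ratio.
#' @slot decay a \code{DecayModel}.
#' @slot etch an \code{EtchConfig}.
#' @slot letMeanKeVUm,letSdKeVUm,letRangeKeVUm LET source distribution
#'   (truncated normal).
#' @slot seed integer RNG seed recorded in all outputs.
#' @exportClass PhantomConfig
setClass("PhantomConfig",
  slots = c(imageSizePx = "integer", pixelSizeUm = "numeric",
            tissueEllipses = "matrix", tumorEllipses = "matrix",
            activityTumorPerMm2 = "numeric", contrast = "numeric",
            decay = "DecayModel", etch = "EtchConfig",
            letMeanKeVUm = "numeric", letSdKeVUm = "numeric",
            letRangeKeVUm = "numeric", seed = "integer"))

setValidity("PhantomConfig", function(object) {
  if (length(object@imageSizePx) != 2L || any(object@imageSizePx < 1L))
    return("imageSizePx must be two positive integers (rows, cols)")
  if (object@pixelSizeUm <= 0) return("pixelSizeUm must be positive")
  if (object@activityTumorPerMm2 < 0) return("activity must be >= 0")
  if (object@contrast <= 0) return("contrast must be positive")
  if (object@letSdKeVUm <= 0) return("letSdKeVUm must be positive")
  for (nm in c("tissueEllipses", "tumorEllipses")) {
    e <- slot(object, nm)
    if (nrow(e) == 0L) next
    if (ncol(e) != 4L) return(paste(nm, "must have columns cx, cy, a, b"))
    w <- object@imageSizePx[2] * object@pixelSizeUm
    h <- object@imageSizePx[1] * object@pixelSizeUm
    if (any(e[, 1] - e[, 3] < 0) || any(e[, 1] + e[, 3] > w) ||
        any(e[, 2] - e[, 4] < 0) || any(e[, 2] + e[, 4] > h))
      return(paste(nm, "extend outside the image"))
  }
  TRUE
})

#' @param imageSizePx image size (rows, cols), default c(1000, 1000).
#' @param pixelSizeUm pixel size in um, default 2 (desk scale; a real
#'   wide-area micrograph is ~0.28 um/px and is supported, just slower).
#' @param tissueEllipses,tumorEllipses ellipse matrices (cx, cy, a, b in
#'   um); defaults: one tissue ellipse with two tumor foci.
#' @param activityTumorPerMm2 expected tumor decays/mm^2 over [0, Inf),
#'   default 120000.
#' @param contrast tumor:normal activity ratio, default 6.
#' @param decay a \code{\link{decayModel}}.
#' @param etch an \code{\link{etchConfig}}.
#' @param letMeanKeVUm,letSdKeVUm,letRangeKeVUm LET source model, defaults
#'   130, 20, c(3.5, 600).
#' @param seed integer RNG seed.
#' @return A \code{PhantomConfig}.
#' @rdname PhantomConfig-class
#' @export
phantomConfig <- function(imageSizePx = c(1000L, 1000L), pixelSizeUm = 2,
                          tissueEllipses = NULL, tumorEllipses = NULL,
                          activityTumorPerMm2 = 120000, contrast = 6,
                          decay = decayModel(), etch = etchConfig(),
                          letMeanKeVUm = 130, letSdKeVUm = 20,
                          letRangeKeVUm = c(3.5, 600), seed = 1L) {
  w <- imageSizePx[2] * pixelSizeUm
  h <- imageSizePx[1] * pixelSizeUm
  if (is.null(tissueEllipses))
    tissueEllipses <- matrix(c(w / 2, h / 2, 0.475 * w, 0.375 * h),
                             1, 4, dimnames = list(NULL, c("cx", "cy", "a", "b")))
  if (is.null(tumorEllipses))
    tumorEllipses <- matrix(c(0.325 * w, 0.40 * h, 0.16 * w, 0.12 * h,
                              0.675 * w, 0.60 * h, 0.15 * w, 0.11 * h),
                            2, 4, byrow = TRUE,
                            dimnames = list(NULL, c("cx", "cy", "a", "b")))
  new("PhantomConfig", imageSizePx = as.integer(imageSizePx),
      pixelSizeUm = pixelSizeUm, tissueEllipses = tissueEllipses,
      tumorEllipses = tumorEllipses,
      activityTumorPerMm2 = activityTumorPerMm2, contrast = contrast,
      decay = decay, etch = etch, letMeanKeVUm = letMeanKeVUm,
      letSdKeVUm = letSdKeVUm, letRangeKeVUm = letRangeKeVUm,
      seed = as.integer(seed))
}

#' @param object a \code{PhantomConfig}.
#' @rdname PhantomConfig-class
#' @export
setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf(
    "PhantomConfig: %d x %d px at %g um/px, %d tumor focus/foci\n",
    object@imageSizePx[1], object@imageSizePx[2], object@pixelSizeUm,
    nrow(object@tumorEllipses)))
  cat(sprintf(
    " activity %g /mm^2 (contrast %g:1), LET ~ N(%g, %g) on [%g, %g], seed %d\n",
    object@activityTumorPerMm2, object@contrast, object@letMeanKeVUm,
    object@letSdKeVUm, object@letRangeKeVUm[1], object@letRangeKeVUm[2],
    object@seed))
})

## pixel centers inside any of the ellipses (rows = y, cols = x)
.insideEllipses <- function(ellipses, nrowPx, ncolPx, pixelSizeUm) {
  out <- matrix(FALSE, nrowPx, ncolPx)
  if (nrow(ellipses) == 0L) return(out)
  x <- (seq_len(ncolPx) - 1) * pixelSizeUm
  y <- (seq_len(nrowPx) - 1) * pixelSizeUm
  for (i in seq_len(nrow(ellipses))) {
    e <- ellipses[i, ]
    dy2 <- ((y - e[2]) / e[4])^2
    dx2 <- ((x - e[1]) / e[3])^2
    out <- out | (outer(dy2, dx2, "+") <= 1)
  }
  out
}

#' Generate the phantom micrograph and ground-truth masks
#'
#' Renders the RGB micrograph (background white, normal tissue purple
#' (120, 80, 160), tumor pink (150, 60, 120)) and returns the ground-truth
#' masks. The fill colors are verified against the default segmentation
#' thresholds at build time, so \code{\link{segmentTissue}} recovers the
#' truth masks pixel-exactly by construction.
#'
#' @param config a \code{\link{phantomConfig}}.
#' @return list with \code{image} (integer \code{[rows, cols, 3]} array)
#'   and \code{masks} (list of tissue/pink/purple \code{RegionMask}).
#' @export
generatePhantom <- function(config) {
  validObject(config)
  thr <- segThresholds()
  stopifnot(
    ## pink fill must pass the band-pass and the tissue threshold
    all(.PINK_FILL >= c(thr@pinkRed[1], thr@pinkGreen[1], thr@pinkBlue[1])),
    all(.PINK_FILL <= c(thr@pinkRed[2], thr@pinkGreen[2], thr@pinkBlue[2])),
    floor(mean(.PINK_FILL) + 0.5) < thr@grayThreshold,
    ## purple fill must be tissue but fail the band-pass
    floor(mean(.PURPLE_FILL) + 0.5) < thr@grayThreshold,
    .PURPLE_FILL[1] < thr@pinkRed[1],
    ## background must not be tissue
    floor(mean(.BACKGROUND) + 0.5) >= thr@grayThreshold)
  nr <- config@imageSizePx[1]; nc <- config@imageSizePx[2]
  px <- config@pixelSizeUm
  tissue <- .insideEllipses(config@tissueEllipses, nr, nc, px)
  tumor <- .insideEllipses(config@tumorEllipses, nr, nc, px)
  pink <- tissue & tumor
  purple <- tissue & !pink
  img <- array(0L, c(nr, nc, 3))
  for (ch in 1:3) {
    plane <- matrix(.BACKGROUND[ch], nr, nc)
    plane[purple] <- .PURPLE_FILL[ch]
    plane[pink] <- .PINK_FILL[ch]
    img[, , ch] <- plane
  }
  list(image = img,
       masks = list(tissue = regionMask(tissue, px, "tissue"),
                    pink = regionMask(pink, px, "pink"),
                    purple = regionMask(purple, px, "purple")))
}

## truncated-normal LET sampler (inverse CDF)
.sampleLet <- function(n, mean, sd, range) {
  lo <- stats::pnorm((range[1] - mean) / sd)
  hi <- stats::pnorm((range[2] - mean) / sd)
  mean + sd * stats::qnorm(stats::runif(n, lo, hi))
}

## exponential decay times truncated to [w1, w2] (inverse CDF)
.sampleDecayTimes <- function(n, lambda, w1, w2) {
  e1 <- exp(-lambda * w1)
  e2 <- if (is.infinite(w2)) 0 else exp(-lambda * w2)
  -log(e1 - stats::runif(n) * (e1 - e2)) / lambda
}

#' Simulate decay-and-emission events in the phantom
#'
#' Per-region event counts are Poisson with mean
#' \code{activity * area * window fraction}, the window fraction being the
#' share of all decays falling in the simulation window under exponential
#' decay. Decay times follow the truncated exponential; positions are
#' uniform over the region mask; the dip angle theta has density
#' \code{2 sin(theta) cos(theta)} on (0, pi/2] (isotropic flux through the
#' detector plane); LET is drawn from the truncated-normal source model.
#' An event is \code{registered} iff its dip angle exceeds the critical
#' angle for its LET, so registered fractions reproduce the detection
#' efficiency by construction.
#'
#' All randomness flows from \code{config@seed}.
#'
#' @param config a \code{\link{phantomConfig}}.
#' @param masks ground-truth masks from \code{\link{generatePhantom}}.
#' @param windowH simulation window in hours (default \code{c(0, t2)}).
#' @param curve calibration curve used for the angular-acceptance test.
#' @return data.frame with columns \code{x_um}, \code{y_um},
#'   \code{decay_time_h}, \code{let_keV_um}, \code{dip_angle_rad},
#'   \code{region}, \code{registered}.
#' @export
simulateDecays <- function(config, masks, windowH = NULL,
                           curve = defaultCalibration()) {
  validObject(config)
  if (is.null(windowH)) windowH <- c(0, config@decay@t2H)
  lam <- decayConstant(config@decay)
  e1 <- exp(-lam * windowH[1])
  e2 <- if (is.infinite(windowH[2])) 0 else exp(-lam * windowH[2])
  frac <- e1 - e2
  set.seed(config@seed)
  acts <- c(pink = config@activityTumorPerMm2,
            purple = config@activityTumorPerMm2 / config@contrast)
  px <- config@pixelSizeUm
  pieces <- lapply(names(acts), function(region) {
    mk <- masks[[region]]
    n <- stats::rpois(1, acts[[region]] * maskAreaMm2(mk) * frac)
    if (n == 0L) return(NULL)
    truePx <- which(maskValues(mk))
    sel <- sample(truePx, n, replace = TRUE)
    nr <- nrow(maskValues(mk))
    row <- (sel - 1L) %% nr + 1L
    col <- (sel - 1L) %/% nr + 1L
    data.frame(
      x_um = (col - 1) * px + (stats::runif(n) - 0.5) * px,
      y_um = (row - 1) * px + (stats::runif(n) - 0.5) * px,
      decay_time_h = .sampleDecayTimes(n, lam, windowH[1], windowH[2]),
      let_keV_um = .sampleLet(n, config@letMeanKeVUm, config@letSdKeVUm,
                              config@letRangeKeVUm),
      dip_angle_rad = asin(sqrt(stats::runif(n))),
      region = region)
  })
  ev <- do.call(rbind, pieces)
  if (is.null(ev))
    ev <- data.frame(x_um = numeric(0), y_um = numeric(0),
                     decay_time_h = numeric(0), let_keV_um = numeric(0),
                     dip_angle_rad = numeric(0), region = character(0))
  thetaC <- criticalAngle(responseFromLet(ev$let_keV_um, curve))
  ev$registered <- ev$dip_angle_rad > thetaC
  rownames(ev) <- NULL
  ev
}

#' Forward etch-pit model: aperture axes from LET and dip angle
#'
#' Inverts the pit-aperture geometry: given the detector response
#' \eqn{S} implied by the LET (via the calibration curve) and the dip
#' angle \eqn{\theta \ge \theta_c}, the elliptical aperture axes are, with
#' \eqn{V = S + 1},
#' \deqn{D_B = 2B\sqrt{\frac{V\sin\theta - 1}{V\sin\theta + 1}}, \qquad
#'       D_A = \frac{(4B^2 - D_B^2)\sqrt{V^2 - 1}}{4B},}
#' which guarantees \code{detectorResponse(D_A, D_B, B) == S} identically
#' (the minor axis carries the angle, the response survives exactly). At
#' normal incidence (\eqn{\theta = \pi/2}) the pit is circular with
#' \eqn{d = 2B\sqrt{S/(S+2)}}; just above the critical angle the minor
#' axis vanishes (grazing limit).
#'
#' @param letKeVUm LET in keV/um, vectorised.
#' @param thetaRad dip angle in radians, same length.
#' @param etch an \code{\link{etchConfig}}.
#' @param curve calibration curve.
#' @return data.frame with \code{major_axis_um}, \code{minor_axis_um}.
#' @export
forwardPitModel <- function(letKeVUm, thetaRad, etch = etchConfig(),
                            curve = defaultCalibration()) {
  S <- responseFromLet(letKeVUm, curve)
  V <- S + 1
  vs <- V * sin(thetaRad)
  if (any(vs < 1 - 1e-12))
    stop("dip angle below the critical angle: no pit is formed")
  vs <- pmax(vs, 1)
  B <- removalB(etch)
  DB <- 2 * B * sqrt((vs - 1) / (vs + 1))
  DA <- (4 * B^2 - DB^2) * sqrt(V^2 - 1) / (4 * B)
  data.frame(major_axis_um = DA, minor_axis_um = DB)
}

#' Pit table of recorded events
#'
#' A pit is recorded iff the event is angularly registered \emph{and} its
#' decay time falls in the mounted window \code{[t1, t2]}. Recorded events
#' get forward-modelled aperture axes; the returned table is what a pit
#' scan of the phantom detector would yield (plus the true LET for
#' validation).
#'
#' @param events from \code{\link{simulateDecays}}.
#' @param config the \code{PhantomConfig} used.
#' @param curve calibration curve.
#' @return data.frame with \code{x_um, y_um, major_axis_um,
#'   minor_axis_um, true_let_keV_um}.
#' @export
pitTableFromEvents <- function(events, config, curve = defaultCalibration()) {
  t1 <- config@decay@t1H; t2 <- config@decay@t2H
  rec <- events$registered & events$decay_time_h >= t1 &
    events$decay_time_h <= t2
  ev <- events[rec, , drop = FALSE]
  if (nrow(ev) == 0L)
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      major_axis_um = numeric(0), minor_axis_um = numeric(0),
                      true_let_keV_um = numeric(0)))
  ax <- forwardPitModel(ev$let_keV_um, ev$dip_angle_rad, config@etch, curve)
  out <- data.frame(x_um = ev$x_um, y_um = ev$y_um,
                    major_axis_um = ax$major_axis_um,
                    minor_axis_um = ax$minor_axis_um,
                    true_let_keV_um = ev$let_keV_um)
  rownames(out) <- NULL
  out
}

#' Ground-truth summary of a simulated phantom
#'
#' Collects the truth a validation needs: per-region decay counts in the
#' pre-mount \code{[t0, t1]} and recording \code{[t1, t2]} windows, and
#' true traversal dose maps (every traversal weighted 1, no efficiency
#' thinning) for the recording window and the full \code{[t0, t2]} span.
#'
#' @param events from \code{\link{simulateDecays}}.
#' @param config the \code{PhantomConfig}.
#' @param cellSizeUm dose-map cell size (default 10).
#' @return list with \code{countsByRegion} (matrix regions x windows) and
#'   \code{doseObserved}, \code{doseTotal} (\code{DoseMap}s).
#' @export
phantomGroundTruth <- function(events, config, cellSizeUm = 10) {
  t1 <- config@decay@t1H; t2 <- config@decay@t2H
  pre <- events$decay_time_h < t1
  rec <- events$decay_time_h >= t1 & events$decay_time_h <= t2
  regions <- c("pink", "purple")
  cnt <- sapply(list(pre = pre, recording = rec), function(w)
    sapply(regions, function(r) sum(w & events$region == r)))
  ext <- c(config@imageSizePx[2], config@imageSizePx[1]) * config@pixelSizeUm
  doseObs <- localDoseMap(events[rec, , drop = FALSE], c(0, 0), ext,
                          cellSizeUm)
  doseTot <- localDoseMap(events[pre | rec, , drop = FALSE], c(0, 0), ext,
                          cellSizeUm)
  list(countsByRegion = cnt, doseObserved = doseObs, doseTotal = doseTot)
}

#' Write the phantom truth bundle to disk
#'
#' Persists everything the analysis side consumes plus the ground truth:
#' the micrograph (PNG), truth masks (PNG), identity corner markers (CSV),
#' the recorded pit table and full event table (CSV), truth dose maps
#' (text grid + JSON sidecar) and a JSON manifest embedding the full
#' configuration and seed. Rerunning with the same seed reproduces
#' byte-identical tables.
#'
#' @param config a \code{\link{phantomConfig}}.
#' @param dir output directory (created if needed).
#' @param curve calibration curve.
#' @return invisibly, a named list of file paths plus the in-memory
#'   \code{events}, \code{masks} and \code{truth}.
#' @export
writeTruthBundle <- function(config, dir, curve = defaultCalibration()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ph <- generatePhantom(config)
  events <- simulateDecays(config, ph$masks, curve = curve)
  pits <- pitTableFromEvents(events, config, curve)
  truth <- phantomGroundTruth(events, config)
  p <- function(f) file.path(dir, f)
  writeImage8(ph$image, p("micrograph.png"))
  for (nm in names(ph$masks)) writeMask(ph$masks[[nm]],
                                        p(sprintf("mask_%s.png", nm)))
  ## identity corner markers: phantom tissue and detector share coordinates
  w <- config@imageSizePx[2] * config@pixelSizeUm
  h <- config@imageSizePx[1] * config@pixelSizeUm
  corners <- cbind(c(0, w, 0, w), c(0, 0, h, h))
  writeMarkers(corners, corners, p("markers.csv"))
  writeTrackTable(pits, p("pits.csv"))
  writeTrackTable(events, p("events.csv"))
  writeGridMap(truth$doseObserved, p("truth_dose_observed"))
  writeGridMap(truth$doseTotal, p("truth_dose_total"))
  manifest <- list(seed = config@seed,
                   pixel_size_um = config@pixelSizeUm,
                   image_size_px = config@imageSizePx,
                   activity_tumor_per_mm2 = config@activityTumorPerMm2,
                   contrast = config@contrast,
                   half_life_h = config@decay@halfLifeH,
                   t1_h = config@decay@t1H, t2_h = config@decay@t2H,
                   removal_B_um = config@etch@removalBUm,
                   let_mean_keV_um = config@letMeanKeVUm,
                   let_sd_keV_um = config@letSdKeVUm,
                   let_range_keV_um = config@letRangeKeVUm,
                   tissue_ellipses = config@tissueEllipses,
                   tumor_ellipses = config@tumorEllipses,
                   n_events = nrow(events), n_pits = nrow(pits),
                   counts_by_region = truth$countsByRegion)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, matrix = "rowmajor")
  invisible(list(dir = dir, micrograph = p("micrograph.png"),
                 pits = p("pits.csv"), events_file = p("events.csv"),
                 markers = p("markers.csv"), manifest = p("manifest.json"),
                 events = events, masks = ph$masks, truth = truth))
}
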
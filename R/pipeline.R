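## End-to-end orchestration: simulate -> derive tracks -> register ->
## segment -> densities/ratio -> spectrum -> dose maps -> decay-corrected
## totals -> JSON report. Every intermediate is persisted and every
## exclusion is counted; nothing is dropped silently.

#' Which tracks fall on true pixels of a mask
#'
#' @param tracks data.frame with \code{x_um}, \code{y_um} (detector frame).
#' @param mask a \code{RegionMask}.
#' @param transform optional detector-to-image \code{AffineTransform2D}.
#' @return logical vector (FALSE for tracks outside the image).
#' @export
tracksInMask <- function(tracks, mask, transform = NULL) {
  m <- maskValues(mask)
  px <- mask@pixelSizeUm
  if (nrow(tracks) == 0L) return(logical(0))
  p <- cbind(tracks$x_um, tracks$y_um)
  if (!is.null(transform)) p <- applyAffine(p, transform)
  ic <- ceiling(p[, 1] / px - 0.5) + 1
  ir <- ceiling(p[, 2] / px - 0.5) + 1
  ok <- ir >= 1 & ir <= nrow(m) & ic >= 1 & ic <= ncol(m)
  res <- logical(nrow(tracks))
  res[ok] <- m[cbind(ir[ok], ic[ok])]
  res
}

#' Read a pipeline run configuration
#'
#' A single human-readable YAML file holding the input paths and every
#' analysis parameter. All defaults are the standard protocol values
#' (B = 3.3 um, half-life 7.2 h, window 12-43 h, gray threshold 138, pink
#' bands 123-177/42-84/94-139, 10 um dose cells, 50 um density bins), and
#' they are explicit in the returned list so any deviation is visible.
#' Referenced input files must exist; validation fails before any compute.
#'
#' @param path YAML file path.
#' @return a validated named list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(pits = NULL, micrograph = NULL, markers = NULL,
                   calibration = NULL, outdir = "cr39dose-out",
                   pixel_size_um = 0.28, removal_B_um = 3.3,
                   removal_B_sigma_um = 0.7, half_life_h = 7.2,
                   t1_h = 12, t2_h = 43, rho_g_cm3 = 1.0, rbe = 1.0,
                   gray_threshold = 138, pink_red = c(123, 177),
                   pink_green = c(42, 84), pink_blue = c(94, 139),
                   dose_cell_um = 10, density_bin_um = 50, seed = 1L)
  cfg <- utils::modifyList(defaults, cfg)
  for (f in c("pits", "micrograph", "markers", "calibration")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("configured ", f, " file not found: ", cfg[[f]])
  }
  if (is.null(cfg$pits) || is.null(cfg$micrograph))
    stop("config must name a pit table and a tissue micrograph")
  cfg
}

.analysisObjects <- function(cfg) {
  list(etch = etchConfig(cfg$removal_B_um, cfg$removal_B_sigma_um),
       decay = decayModel(cfg$half_life_h, cfg$t1_h, cfg$t2_h),
       dosim = dosimetryConfig(cfg$rho_g_cm3, cfg$rbe),
       thresholds = segThresholds(cfg$gray_threshold, cfg$pink_red,
                                  cfg$pink_green, cfg$pink_blue),
       curve = if (is.null(cfg$calibration)) defaultCalibration()
               else loadCalibration(cfg$calibration))
}

#' Run the analysis half of the pipeline
#'
#' Loads a pit table and tissue micrograph, derives per-track response,
#' efficiency and LET, registers the detector frame to the image frame
#' from the marker file, segments the tissue, counts tracks per region,
#' builds the LET spectrum and dose/density maps, applies the decay
#' correction, and writes all intermediates plus a JSON report.
#'
#' @param cfg a config list from \code{\link{readRunConfig}} (or built
#'   programmatically with the same fields).
#' @return the report, invisibly (also written as
#'   \code{<outdir>/report.json}).
#' @export
analyzeRun <- function(cfg) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  obj <- .analysisObjects(cfg)
  out <- function(f) file.path(cfg$outdir, f)

  ## stage 1: tracks
  pits <- readTrackTable(cfg$pits)
  tracks <- deriveTracks(pits, obj$etch, obj$curve)
  writeTrackTable(tracks, out("tracks_derived.csv"))

  ## stage 2: registration (detector -> image frame)
  if (!is.null(cfg$markers)) {
    mk <- readMarkers(cfg$markers)
    det2img <- fitAffine(mk$post, mk$pre)
    regRms <- rmsResidual(mk$post, mk$pre, det2img)
  } else {
    det2img <- affineTransform()
    regRms <- NA_real_
  }

  ## stage 3: segmentation
  img <- readImage8(cfg$micrograph)
  masks <- segmentTissue(img, cfg$pixel_size_um, obj$thresholds)
  for (nm in names(masks)) writeMask(masks[[nm]],
                                     out(sprintf("mask_%s.png", nm)))

  ## stage 4: per-region densities and concentration efficiency
  nPink <- countTracksInMask(tracks, masks$pink, det2img)
  nPurple <- countTracksInMask(tracks, masks$purple, det2img)
  dPink <- regionDensity(as.integer(nPink), maskAreaMm2(masks$pink))
  dPurple <- regionDensity(as.integer(nPurple), maskAreaMm2(masks$purple))
  conc <- concentrationEfficiency(dPink, dPurple)

  ## stage 5: LET spectrum over the tissue region
  inTissue <- tracksInMask(tracks, masks$tissue, det2img)
  spec <- buildLetSpectrum(tracks[inTissue, , drop = FALSE],
                           maskAreaMm2(masks$tissue) / 100)  # mm^2 -> cm^2
  writeSpectrum(spec, out("let_spectrum.csv"))

  ## stage 6: maps in the image frame
  imgXY <- applyAffine(cbind(tracks$x_um, tracks$y_um), det2img)
  tracksImg <- tracks
  tracksImg$x_um <- imgXY[, 1]; tracksImg$y_um <- imgXY[, 2]
  ext <- c(ncol(img) * cfg$pixel_size_um, nrow(img) * cfg$pixel_size_um)
  doseObs <- localDoseMap(tracksImg, c(0, 0), ext, cfg$dose_cell_um,
                          obj$dosim)
  doseTot <- totalDose(doseObs, obj$decay)
  dens <- trackDensityMap(tracksImg, c(0, 0), ext, cfg$density_bin_um)
  writeGridMap(doseObs, out("dose_observed"))
  writeGridMap(doseTot, out("dose_total"))
  writeGridMap(dens, out("track_density"))
  histObs <- doseHistogram(doseObs)
  histTot <- doseHistogram(doseTot)

  report <- list(
    n_pits_input = nrow(pits),
    n_tracks = nrow(tracks),
    warnings = list(
      n_degenerate_pits = attr(tracks, "nDegenerate"),
      n_below_let_range = attr(tracks, "nBelowRange"),
      n_clipped_high_let = attr(tracks, "nClippedHigh"),
      n_outside_grid = attr(doseObs, "nOutside"),
      n_outside_image = attr(nPink, "nOutside")),
    registration_rms_um = regRms,
    pink = list(count = as.integer(nPink),
                area_mm2 = maskAreaMm2(masks$pink),
                density_per_mm2 = trackDensity(dPink),
                sigma_per_mm2 = densitySigma(dPink)),
    purple = list(count = as.integer(nPurple),
                  area_mm2 = maskAreaMm2(masks$purple),
                  density_per_mm2 = trackDensity(dPurple),
                  sigma_per_mm2 = densitySigma(dPurple)),
    concentration_efficiency = conc$ratio,
    concentration_efficiency_sigma = conc$sigma,
    spectrum = list(mode_keV_um = spectrumMode(spec),
                    total_fluence_per_cm2 = sum(fluencePerBin(spec)),
                    n_tracks_in_tissue = sum(rawCounts(spec)),
                    mean_dose_tissue_Gy = absorbedDose(spec, obj$dosim)),
    decay_correction_factor = decayCorrectionFactor(obj$decay),
    dose_observed = list(mode_Gy = histObs$modeGy,
                         range_Gy = histObs$rangeGy,
                         n_nonzero_cells = histObs$nNonzero),
    dose_total = list(mode_Gy = histTot$modeGy,
                      range_Gy = histTot$rangeGy,
                      n_nonzero_cells = histTot$nNonzero,
                      rbe_weighted_mode_Gy = histTot$modeGy * cfg$rbe))
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(report)
}

#' Run the full simulate-and-analyze pipeline on a synthetic phantom
#'
#' Generates the phantom truth bundle under \code{<outdir>/sim}, analyzes
#' it under \code{<outdir>/analysis} exactly as real data would be
#' analyzed (the analysis sees only the persisted pit table, micrograph
#' and markers), and appends a truth-comparison block to the report.
#' Deterministic given the seed.
#'
#' @param config a \code{\link{phantomConfig}}.
#' @param outdir output directory.
#' @param seed optional seed overriding \code{config@seed}.
#' @return the report, invisibly.
#' @export
runPipeline <- function(config = phantomConfig(), outdir = tempfile("cr39"),
                        seed = NULL) {
  if (!is.null(seed)) config@seed <- as.integer(seed)
  bundle <- writeTruthBundle(config, file.path(outdir, "sim"))
  cfg <- list(pits = bundle$pits, micrograph = bundle$micrograph,
              markers = bundle$markers,
              outdir = file.path(outdir, "analysis"),
              pixel_size_um = config@pixelSizeUm,
              removal_B_um = config@etch@removalBUm,
              removal_B_sigma_um = config@etch@removalBSigmaUm,
              half_life_h = config@decay@halfLifeH,
              t1_h = config@decay@t1H, t2_h = config@decay@t2H,
              rho_g_cm3 = 1.0, rbe = 1.0, gray_threshold = 138,
              pink_red = c(123, 177), pink_green = c(42, 84),
              pink_blue = c(94, 139), dose_cell_um = 10,
              density_bin_um = 50, seed = config@seed)
  report <- analyzeRun(cfg)
  report$truth <- list(
    contrast = config@contrast,
    counts_by_region = bundle$truth$countsByRegion,
    n_events = nrow(bundle$events),
    n_recorded_pits = nrow(readTrackTable(bundle$pits)))
  jsonlite::write_json(report, file.path(outdir, "analysis", "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' One-line text summary of a pipeline report
#'
#' @param report a report list (from \code{\link{analyzeRun}} /
#'   \code{\link{runPipeline}}) or the path to a \code{report.json}.
#' @return character vector of summary lines, invisibly (also printed).
#' @export
summarizeReport <- function(report) {
  if (is.character(report))
    report <- jsonlite::read_json(report, simplifyVector = TRUE)
  lines <- c(
    sprintf("tracks: %d (of %d pits)", report$n_tracks, report$n_pits_input),
    sprintf("pink:   %.1f +/- %.1f tracks/mm^2 (%d in %.3f mm^2)",
            report$pink$density_per_mm2, report$pink$sigma_per_mm2,
            report$pink$count, report$pink$area_mm2),
    sprintf("purple: %.1f +/- %.1f tracks/mm^2 (%d in %.3f mm^2)",
            report$purple$density_per_mm2, report$purple$sigma_per_mm2,
            report$purple$count, report$purple$area_mm2),
    sprintf("concentration efficiency: %.2f +/- %.2f",
            report$concentration_efficiency,
            report$concentration_efficiency_sigma),
    sprintf("LET spectrum mode: %.0f keV/um (%d tracks in tissue)",
            report$spectrum$mode_keV_um, report$spectrum$n_tracks_in_tissue),
    sprintf("decay correction factor D0/D: %.3f",
            report$decay_correction_factor),
    sprintf("total dose: mode %.2f Gy, range %.2f-%.2f Gy",
            report$dose_total$mode_Gy, report$dose_total$range_Gy[1],
            report$dose_total$range_Gy[2]))
  cat(lines, sep = "\n")
  invisible(lines)
}
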
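## S4 containers for the CR-39 dosimetry chain. Constructors are the
## lower-camelCase functions below each class; use accessors, not @.

## ---------------------------------------------------------------- etching

#' Etch configuration
#'
#' Bulk removal thickness of the chemical etch and its uncertainty. The
#' removal thickness \eqn{B} is the thickness of detector surface dissolved
#' during etching, measured e.g. with a micrometer before and after; it sets
#' the length scale of every pit-aperture formula.
#'
#' @slot removalBUm bulk removal thickness B (um).
#' @slot removalBSigmaUm 1-sigma uncertainty on B (um).
#' @slot metadata free-text etch metadata (solution, temperature, duration).
#' @exportClass EtchConfig
setClass("EtchConfig",
  slots = c(removalBUm = "numeric", removalBSigmaUm = "numeric",
            metadata = "character"))

setValidity("EtchConfig", function(object) {
  if (length(object@removalBUm) != 1L || !is.finite(object@removalBUm) ||
      object@removalBUm <= 0)
    return("removalBUm must be a single positive number")
  if (object@removalBSigmaUm < 0)
    return("removalBSigmaUm must be non-negative")
  TRUE
})

#' @param removalBUm bulk removal thickness B in um (default 3.3).
#' @param removalBSigmaUm its 1-sigma uncertainty in um (default 0.7).
#' @param metadata free-text etch metadata.
#' @return An \code{EtchConfig} object.
#' @examples
#' etchConfig()
#' @rdname EtchConfig-class
#' @export
etchConfig <- function(removalBUm = 3.3, removalBSigmaUm = 0.7,
                       metadata = "7 M NaOH, 70 degC, 2 h") {
  new("EtchConfig", removalBUm = removalBUm,
      removalBSigmaUm = removalBSigmaUm, metadata = metadata)
}

#' @param object an \code{EtchConfig}.
#' @rdname EtchConfig-class
#' @export
setMethod("show", "EtchConfig", function(object) {
  cat(sprintf("EtchConfig: B = %.2f +/- %.2f um (%s)\n",
              object@removalBUm, object@removalBSigmaUm, object@metadata))
})

#' @rdname EtchConfig-class
#' @export
removalB <- function(object) object@removalBUm

## ------------------------------------------------------------ calibration

#' Response-to-LET calibration curve
#'
#' A strictly monotone knot table mapping detector response \eqn{S} to LET
#' in water (keV/um), interpolated log-log linearly between knots. CR-39
#' registers particles with LET of roughly 3.5 keV/um and above; the curve
#' is valid on a stated LET range and queries are clipped (high side) or
#' rejected (below threshold).
#'
#' @slot knots data.frame with columns \code{let_keV_um}, \code{response_S},
#'   strictly increasing in both.
#' @slot validLetRange length-2 numeric, LET validity range (keV/um).
#' @slot provenance free-text label describing the curve's origin.
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
  slots = c(knots = "data.frame", validLetRange = "numeric",
            provenance = "character"))

setValidity("CalibrationCurve", function(object) {
  k <- object@knots
  if (!all(c("let_keV_um", "response_S") %in% names(k)))
    return("knots must have columns let_keV_um and response_S")
  if (nrow(k) < 2L)
    return("need at least two calibration knots")
  if (any(!is.finite(k$let_keV_um)) || any(!is.finite(k$response_S)))
    return("knots must be finite")
  if (any(k$let_keV_um <= 0) || any(k$response_S <= 0))
    return("knots must be positive (log-log interpolation)")
  if (any(diff(k$let_keV_um) <= 0) || any(diff(k$response_S) <= 0))
    return("knots must be strictly increasing in both coordinates")
  r <- object@validLetRange
  if (length(r) != 2L || r[1] >= r[2])
    return("validLetRange must be an increasing length-2 numeric")
  if (k$let_keV_um[1] > r[1] || k$let_keV_um[nrow(k)] < r[2])
    return("knots must cover validLetRange")
  TRUE
})

#' @param object a \code{CalibrationCurve}.
#' @rdname CalibrationCurve-class
#' @export
setMethod("show", "CalibrationCurve", function(object) {
  k <- object@knots
  cat(sprintf("CalibrationCurve: %d knots, LET %.1f-%.1f keV/um, S %.4g-%.4g\n",
              nrow(k), object@validLetRange[1], object@validLetRange[2],
              min(k$response_S), max(k$response_S)))
  cat(" provenance:", object@provenance, "\n")
})

#' @rdname CalibrationCurve-class
#' @export
calibrationKnots <- function(object) object@knots

#' @rdname CalibrationCurve-class
#' @export
validLetRange <- function(object) object@validLetRange

## ---------------------------------------------------------------- spectra

#' Efficiency-corrected LET spectrum
#'
#' Binned fluence per LET bin over a scored area. Fluence per bin is the
#' sum of per-track efficiency weights \eqn{1/\eta} divided by the scored
#' area, so the spectrum estimates the true (incident) particle fluence,
#' not the registered-track count density. Raw counts are kept alongside
#' for Poisson error estimates. Bins are half-open \code{[low, high)} with
#' the last bin closed.
#'
#' @slot binEdges ascending LET bin edges (keV/um).
#' @slot fluence efficiency-corrected fluence per bin (cm^-2).
#' @slot counts raw registered-track counts per bin.
#' @slot areaCm2 scored area (cm^2).
#' @exportClass LETSpectrum
setClass("LETSpectrum",
  slots = c(binEdges = "numeric", fluence = "numeric", counts = "integer",
            areaCm2 = "numeric"))

setValidity("LETSpectrum", function(object) {
  nb <- length(object@binEdges) - 1L
  if (nb < 1L || any(diff(object@binEdges) <= 0))
    return("binEdges must be strictly ascending with >= 2 entries")
  if (length(object@fluence) != nb || length(object@counts) != nb)
    return("fluence and counts must have one entry per bin")
  if (any(object@fluence < 0) || any(object@counts < 0L))
    return("fluence and counts must be non-negative")
  if (object@areaCm2 <= 0) return("areaCm2 must be positive")
  ## efficiency weights are >= 1, so fluence >= counts/area
  if (any(object@fluence < object@counts / object@areaCm2 - 1e-9))
    return("fluence below counts/area: efficiency weights must be >= 1")
  TRUE
})

#' @param object a \code{LETSpectrum}.
#' @rdname LETSpectrum-class
#' @export
setMethod("show", "LETSpectrum", function(object) {
  cat(sprintf(
    "LETSpectrum: %d bins over [%.1f, %.1f] keV/um, %d tracks, area %.3g cm^2\n",
    length(object@fluence), min(object@binEdges), max(object@binEdges),
    sum(object@counts), object@areaCm2))
  if (sum(object@counts) > 0L)
    cat(sprintf(" total fluence %.4g cm^-2, mode at %.1f keV/um\n",
                sum(object@fluence), spectrumMode(object)))
})

#' @rdname LETSpectrum-class
#' @export
letBinEdges <- function(object) object@binEdges

#' @rdname LETSpectrum-class
#' @export
fluencePerBin <- function(object) object@fluence

#' @rdname LETSpectrum-class
#' @export
rawCounts <- function(object) object@counts

## ------------------------------------------------------------------ grids

#' Cell-scale absorbed-dose map
#'
#' Gridded absorbed dose (Gy) over square cells (default 10 um, comparable
#' to a mammalian cell diameter), with raw registered-track counts per cell
#' kept alongside so Poisson uncertainty maps can be derived. Grid cells
#' are half-open \code{[low, high)} in both axes; matrix rows index y,
#' columns index x.
#'
#' @slot originUm grid origin (x, y) in um (lower corner of cell [1,1]).
#' @slot cellSizeUm square cell edge length (um).
#' @slot dose matrix of absorbed dose (Gy), rows = y, cols = x.
#' @slot counts matrix of raw track counts, same shape.
#' @exportClass DoseMap
setClass("DoseMap",
  slots = c(originUm = "numeric", cellSizeUm = "numeric",
            dose = "matrix", counts = "matrix"))

setValidity("DoseMap", function(object) {
  if (length(object@originUm) != 2L) return("originUm must be length 2")
  if (object@cellSizeUm <= 0) return("cellSizeUm must be positive")
  if (!identical(dim(object@dose), dim(object@counts)))
    return("dose and counts grids must have the same shape")
  if (any(object@dose < 0)) return("doses must be non-negative")
  TRUE
})

#' @param object a \code{DoseMap}.
#' @rdname DoseMap-class
#' @export
setMethod("show", "DoseMap", function(object) {
  d <- dim(object@dose)
  cat(sprintf(
    "DoseMap: %d x %d cells of %.0f um, origin (%.0f, %.0f) um\n",
    d[1], d[2], object@cellSizeUm, object@originUm[1], object@originUm[2]))
  nz <- object@dose[object@dose > 0]
  if (length(nz))
    cat(sprintf(" %d nonzero cells, dose %.3g-%.3g Gy\n",
                length(nz), min(nz), max(nz)))
})

#' @rdname DoseMap-class
#' @export
doseValues <- function(object) object@dose

#' @rdname DoseMap-class
#' @export
cellCounts <- function(object) object@counts

#' @rdname DoseMap-class
#' @export
cellSize <- function(object) object@cellSizeUm

#' @rdname DoseMap-class
#' @export
gridOrigin <- function(object) object@originUm

#' Track-density map
#'
#' Gridded integer track counts (default 50 um bins), the digital
#' autoradiography intensity map of registered alpha tracks.
#'
#' @slot originUm grid origin (x, y) in um.
#' @slot binSizeUm square bin edge length (um).
#' @slot counts matrix of integer counts, rows = y, cols = x.
#' @exportClass DensityMap
setClass("DensityMap",
  slots = c(originUm = "numeric", binSizeUm = "numeric", counts = "matrix"))

setValidity("DensityMap", function(object) {
  if (length(object@originUm) != 2L) return("originUm must be length 2")
  if (object@binSizeUm <= 0) return("binSizeUm must be positive")
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    return("counts must be non-negative integers")
  TRUE
})

#' @param object a \code{DensityMap}.
#' @rdname DensityMap-class
#' @export
setMethod("show", "DensityMap", function(object) {
  d <- dim(object@counts)
  cat(sprintf(
    "DensityMap: %d x %d bins of %.0f um, %d tracks, origin (%.0f, %.0f) um\n",
    d[1], d[2], object@binSizeUm, sum(object@counts),
    object@originUm[1], object@originUm[2]))
})

#' @rdname DensityMap-class
#' @export
densityCounts <- function(object) object@counts

## ------------------------------------------------------------------ decay

#' Radioactive decay model for the recording window
#'
#' Exponential-decay bookkeeping for an autoradiography exposure: activity
#' is injected at \code{t0 = 0}, the tissue is sliced and mounted on the
#' detector at \code{t1} and removed at \code{t2}, so only decays in
#' \code{[t1, t2]} leave tracks. Defaults are the 211At protocol: half-life
#' 7.2 h, mount at 12 h, removal at 43 h (a 31 h exposure, about four
#' half-lives).
#'
#' @slot halfLifeH half-life (hours).
#' @slot t1H slice-and-mount time (hours after injection).
#' @slot t2H tissue-removal time (hours after injection); may be \code{Inf}.
#' @exportClass DecayModel
setClass("DecayModel",
  slots = c(halfLifeH = "numeric", t1H = "numeric", t2H = "numeric"))

setValidity("DecayModel", function(object) {
  if (object@halfLifeH <= 0) return("halfLifeH must be positive")
  if (object@t1H < 0) return("t1H must be >= 0")
  if (object@t2H <= object@t1H) return("need t0 = 0 <= t1 < t2")
  TRUE
})

#' @param halfLifeH half-life in hours (default 7.2, 211At).
#' @param t1H slice-and-mount time in hours (default 12).
#' @param t2H tissue removal time in hours (default 43).
#' @return A \code{DecayModel}.
#' @examples
#' decayModel()
#' decayConstant(decayModel())
#' @rdname DecayModel-class
#' @export
decayModel <- function(halfLifeH = 7.2, t1H = 12, t2H = 43) {
  new("DecayModel", halfLifeH = halfLifeH, t1H = t1H, t2H = t2H)
}

#' @param object a \code{DecayModel}.
#' @rdname DecayModel-class
#' @export
setMethod("show", "DecayModel", function(object) {
  cat(sprintf(
    "DecayModel: half-life %.2f h (lambda %.4f /h), window [%g, %g] h\n",
    object@halfLifeH, decayConstant(object), object@t1H, object@t2H))
})

#' @rdname DecayModel-class
#' @export
decayConstant <- function(object) log(2) / object@halfLifeH

## -------------------------------------------------------------- dosimetry

#' Dosimetry configuration
#'
#' @slot rhoGCm3 specific gravity of the scored medium (g/cm^3); 1.0 for
#'   soft tissue/water.
#' @slot rbe scalar relative biological effectiveness multiplier applied
#'   only when reporting biologically weighted dose (default 1 = physical
#'   dose; high-LET alphas are commonly quoted as 2-3).
#' @exportClass DosimetryConfig
setClass("DosimetryConfig", slots = c(rhoGCm3 = "numeric", rbe = "numeric"))

setValidity("DosimetryConfig", function(object) {
  if (object@rhoGCm3 <= 0) return("rhoGCm3 must be positive")
  if (object@rbe <= 0) return("rbe must be positive")
  TRUE
})

#' @param rhoGCm3 specific gravity (default 1.0).
#' @param rbe scalar RBE multiplier (default 1).
#' @return A \code{DosimetryConfig}.
#' @rdname DosimetryConfig-class
#' @export
dosimetryConfig <- function(rhoGCm3 = 1.0, rbe = 1.0) {
  new("DosimetryConfig", rhoGCm3 = rhoGCm3, rbe = rbe)
}

## ----------------------------------------------------------- registration

#' 2-D affine transform
#'
#' Maps \eqn{(x, y)} to \eqn{A (x, y)^T + b}: six coefficients estimated
#' from scratched marker pairs to align the pre-etch tissue frame with the
#' post-etch detector frame.
#'
#' @slot A 2x2 linear part.
#' @slot b length-2 translation (um).
#' @exportClass AffineTransform2D
setClass("AffineTransform2D", slots = c(A = "matrix", b = "numeric"))

setValidity("AffineTransform2D", function(object) {
  if (!identical(dim(object@A), c(2L, 2L))) return("A must be 2x2")
  if (length(object@b) != 2L) return("b must be length 2")
  if (abs(det(object@A)) <= 1e-12)
    return("linear part is singular (|det| <= 1e-12)")
  TRUE
})

#' @param A 2x2 linear part.
#' @param b length-2 translation.
#' @return An \code{AffineTransform2D}.
#' @examples
#' affineTransform()   # identity
#' @rdname AffineTransform2D-class
#' @export
affineTransform <- function(A = diag(2), b = c(0, 0)) {
  new("AffineTransform2D", A = A, b = as.numeric(b))
}

#' @param object an \code{AffineTransform2D}.
#' @rdname AffineTransform2D-class
#' @export
setMethod("show", "AffineTransform2D", function(object) {
  cat("AffineTransform2D:\n")
  cat(sprintf("  [%9.4f %9.4f]   [%9.3f]\n", object@A[1, 1], object@A[1, 2],
              object@b[1]))
  cat(sprintf("  [%9.4f %9.4f] + [%9.3f]\n", object@A[2, 1], object@A[2, 2],
              object@b[2]))
})

## ------------------------------------------------------------ segmentation

#' Color segmentation thresholds
#'
#' Thresholds for segmenting hematoxylin-eosin-like stained tissue
#' micrographs: a gray threshold separating tissue from blank detector and
#' an RGB band-pass selecting the eosin-pink (necrotic tumor) region.
#' Defaults are 138/256 gray and bands R 123-177, G 42-84, B 94-139
#' (inclusive, 8-bit).
#'
#' @slot grayThreshold 8-bit gray threshold; pixels with gray < threshold
#'   are tissue.
#' @slot pinkRed,pinkGreen,pinkBlue inclusive 8-bit band bounds.
#' @slot grayscaleMethod "mean" (unweighted channel mean) or "luminance"
#'   (Rec. 601 weights).
#' @exportClass SegmentationThresholds
setClass("SegmentationThresholds",
  slots = c(grayThreshold = "numeric", pinkRed = "numeric",
            pinkGreen = "numeric", pinkBlue = "numeric",
            grayscaleMethod = "character"))

setValidity("SegmentationThresholds", function(object) {
  bands <- list(object@pinkRed, object@pinkGreen, object@pinkBlue)
  for (bd in bands) {
    if (length(bd) != 2L || bd[1] > bd[2] || bd[1] < 0 || bd[2] > 255)
      return("each band must be 0 <= low <= high <= 255")
  }
  if (object@grayThreshold < 0 || object@grayThreshold > 255)
    return("grayThreshold must be in [0, 255]")
  if (!object@grayscaleMethod %in% c("mean", "luminance"))
    return("grayscaleMethod must be 'mean' or 'luminance'")
  TRUE
})

#' @param grayThreshold 8-bit gray threshold (default 138).
#' @param pinkRed,pinkGreen,pinkBlue inclusive band bounds (defaults
#'   c(123,177), c(42,84), c(94,139)).
#' @param grayscaleMethod "mean" or "luminance".
#' @return A \code{SegmentationThresholds}.
#' @rdname SegmentationThresholds-class
#' @export
segThresholds <- function(grayThreshold = 138,
                          pinkRed = c(123, 177), pinkGreen = c(42, 84),
                          pinkBlue = c(94, 139), grayscaleMethod = "mean") {
  new("SegmentationThresholds", grayThreshold = grayThreshold,
      pinkRed = pinkRed, pinkGreen = pinkGreen, pinkBlue = pinkBlue,
      grayscaleMethod = grayscaleMethod)
}

#' Binary tissue-region mask
#'
#' A binary grid aligned with the tissue micrograph. Labels follow the
#' segmentation convention: \code{tissue} (all stained pixels),
#' \code{pink} (eosin band-pass, subset of tissue) and \code{purple}
#' (tissue minus pink).
#'
#' @slot mask logical matrix, rows = y, cols = x.
#' @slot pixelSizeUm pixel edge length (um).
#' @slot label region label.
#' @exportClass RegionMask
setClass("RegionMask",
  slots = c(mask = "matrix", pixelSizeUm = "numeric", label = "character"))

setValidity("RegionMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be a logical matrix")
  if (object@pixelSizeUm <= 0) return("pixelSizeUm must be positive")
  TRUE
})

#' @param mask logical matrix (rows = y, cols = x).
#' @param pixelSizeUm pixel size in um.
#' @param label region label string.
#' @return A \code{RegionMask}.
#' @rdname RegionMask-class
#' @export
regionMask <- function(mask, pixelSizeUm, label = "region") {
  new("RegionMask", mask = mask, pixelSizeUm = pixelSizeUm, label = label)
}

#' @param object a \code{RegionMask}.
#' @rdname RegionMask-class
#' @export
setMethod("show", "RegionMask", function(object) {
  cat(sprintf(
    "RegionMask '%s': %d x %d px at %.2f um/px, %d true px (%.4f mm^2)\n",
    object@label, nrow(object@mask), ncol(object@mask), object@pixelSizeUm,
    sum(object@mask), maskAreaMm2(object)))
})

#' @rdname RegionMask-class
#' @export
maskValues <- function(object) object@mask

#' Area of a region mask in mm^2
#' @param object a \code{RegionMask}.
#' @return area in mm^2 (true pixels times pixel area).
#' @rdname RegionMask-class
#' @export
maskAreaMm2 <- function(object) {
  sum(object@mask) * (object@pixelSizeUm / 1000)^2
}

#' Track density in a region with Poisson counting error
#'
#' @slot count integer track count.
#' @slot areaMm2 region area (mm^2).
#' @slot densityPerMm2 count/area (mm^-2).
#' @slot sigmaPerMm2 1-sigma Poisson error sqrt(count)/area (mm^-2).
#' @exportClass RegionDensity
setClass("RegionDensity",
  slots = c(count = "numeric", areaMm2 = "numeric",
            densityPerMm2 = "numeric", sigmaPerMm2 = "numeric"))

setValidity("RegionDensity", function(object) {
  if (object@count < 0) return("count must be non-negative")
  if (object@areaMm2 <= 0) return("areaMm2 must be positive")
  ok1 <- abs(object@densityPerMm2 - object@count / object@areaMm2) <
    1e-9 * max(1, object@densityPerMm2)
  ok2 <- abs(object@sigmaPerMm2 - sqrt(object@count) / object@areaMm2) <
    1e-9 * max(1, object@sigmaPerMm2)
  if (!ok1 || !ok2) return("density/sigma inconsistent with count and area")
  TRUE
})

#' @param object a \code{RegionDensity}.
#' @rdname RegionDensity-class
#' @export
setMethod("show", "RegionDensity", function(object) {
  cat(sprintf("RegionDensity: %d tracks / %.4f mm^2 = %.1f +/- %.1f mm^-2\n",
              as.integer(object@count), object@areaMm2,
              object@densityPerMm2, object@sigmaPerMm2))
})

#' @rdname RegionDensity-class
#' @export
trackDensity <- function(object) object@densityPerMm2

#' @rdname RegionDensity-class
#' @export
densitySigma <- function(object) object@sigmaPerMm2

#' @rdname RegionDensity-class
#' @export
trackCount <- function(object) object@count
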
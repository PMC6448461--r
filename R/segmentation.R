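## Color-threshold segmentation of stained tissue micrographs and
## per-region track statistics. Images are integer arrays [rows, cols, 3]
## with 8-bit values 0-255; masks are logical matrices aligned with them.

#' Convert an RGB micrograph to 8-bit grayscale
#'
#' Default is the unweighted per-pixel channel mean, rounded half-up to an
#' integer; Rec. 601 luminance weights (0.299, 0.587, 0.114) are available
#' as an alternative.
#'
#' @param rgbImage integer array \code{[rows, cols, 3]} with 8-bit values.
#' @param method \code{"mean"} (default) or \code{"luminance"}.
#' @return integer matrix of gray values 0-255.
#' @examples
#' px <- array(c(150, 60, 120), c(1, 1, 3))
#' toGrayscale(px)   # 110
#' @export
toGrayscale <- function(rgbImage, method = c("mean", "luminance")) {
  method <- match.arg(method)
  if (length(dim(rgbImage)) != 3L || dim(rgbImage)[3] != 3L)
    stop("rgbImage must be a [rows, cols, 3] array")
  w <- if (method == "mean") c(1, 1, 1) / 3 else c(0.299, 0.587, 0.114)
  g <- rgbImage[, , 1] * w[1] + rgbImage[, , 2] * w[2] + rgbImage[, , 3] * w[3]
  g <- floor(g + 0.5)   # round half-up
  dim(g) <- dim(rgbImage)[1:2]   # keep matrix shape for 1-pixel-wide images
  g
}

#' Binarize tissue from blank detector background
#'
#' Stained tissue is darker than the blank detector: a pixel is tissue iff
#' its 8-bit gray value is strictly below the threshold (default 138).
#'
#' @param grayImage integer gray matrix (e.g. from
#'   \code{\link{toGrayscale}}).
#' @param pixelSizeUm pixel size in um.
#' @param thresholds a \code{\link{segThresholds}}.
#' @return A \code{\link{RegionMask-class}} labelled \code{"tissue"}.
#' @export
binarizeTissue <- function(grayImage, pixelSizeUm,
                           thresholds = segThresholds()) {
  stopifnot(is.matrix(grayImage))
  regionMask(grayImage < thresholds@grayThreshold, pixelSizeUm, "tissue")
}

#' Extract the eosin-pink region by RGB band-pass
#'
#' A pixel is pink iff all three channels fall inside their inclusive
#' bands (defaults R 123-177, G 42-84, B 94-139) \emph{and} the pixel is
#' tissue. The pink region corresponds to eosin-stained necrotic tumor.
#'
#' @param rgbImage integer array \code{[rows, cols, 3]}.
#' @param pixelSizeUm pixel size in um.
#' @param thresholds a \code{\link{segThresholds}}.
#' @param tissue optional precomputed tissue \code{RegionMask}; computed
#'   from \code{rgbImage} if missing.
#' @return A \code{RegionMask} labelled \code{"pink"}.
#' @export
bandPassMask <- function(rgbImage, pixelSizeUm,
                         thresholds = segThresholds(), tissue = NULL) {
  if (length(dim(rgbImage)) != 3L || dim(rgbImage)[3] != 3L)
    stop("rgbImage must be a [rows, cols, 3] array")
  if (is.null(tissue))
    tissue <- binarizeTissue(
      toGrayscale(rgbImage, thresholds@grayscaleMethod), pixelSizeUm,
      thresholds)
  inband <- rgbImage[, , 1] >= thresholds@pinkRed[1] &
            rgbImage[, , 1] <= thresholds@pinkRed[2] &
            rgbImage[, , 2] >= thresholds@pinkGreen[1] &
            rgbImage[, , 2] <= thresholds@pinkGreen[2] &
            rgbImage[, , 3] >= thresholds@pinkBlue[1] &
            rgbImage[, , 3] <= thresholds@pinkBlue[2]
  dim(inband) <- dim(rgbImage)[1:2]
  regionMask(inband & maskValues(tissue), pixelSizeUm, "pink")
}

#' Segment a micrograph into tissue, pink and purple regions
#'
#' Purple (normal tissue) is defined as tissue minus pink, so by
#' construction pink and purple partition the tissue mask.
#'
#' @inheritParams bandPassMask
#' @return list of \code{RegionMask}: \code{tissue}, \code{pink},
#'   \code{purple}.
#' @export
segmentTissue <- function(rgbImage, pixelSizeUm,
                          thresholds = segThresholds()) {
  gray <- toGrayscale(rgbImage, thresholds@grayscaleMethod)
  tissue <- binarizeTissue(gray, pixelSizeUm, thresholds)
  pink <- bandPassMask(rgbImage, pixelSizeUm, thresholds, tissue)
  purple <- regionMask(maskValues(tissue) & !maskValues(pink),
                       pixelSizeUm, "purple")
  list(tissue = tissue, pink = pink, purple = purple)
}

#' Count registered tracks inside a region mask
#'
#' Transforms track positions into the image frame (identity if no
#' transform is given), assigns each to its nearest pixel center (ties
#' toward the lower index) and counts those landing on true pixels.
#' Tracks outside the image are excluded and counted in the
#' \code{nOutside} attribute.
#'
#' @param tracks data.frame with \code{x_um}, \code{y_um} in the detector
#'   frame.
#' @param mask a \code{\link{RegionMask-class}}.
#' @param transform optional \code{AffineTransform2D} mapping detector
#'   frame to image frame.
#' @return integer count with attribute \code{nOutside}.
#' @export
countTracksInMask <- function(tracks, mask, transform = NULL) {
  m <- maskValues(mask)
  px <- mask@pixelSizeUm
  if (nrow(tracks) == 0L) {
    out <- 0L; attr(out, "nOutside") <- 0L; return(out)
  }
  p <- cbind(tracks$x_um, tracks$y_um)
  if (!is.null(transform)) p <- applyAffine(p, transform)
  ## nearest pixel center, ties toward the lower index
  ic <- ceiling(p[, 1] / px - 0.5) + 1
  ir <- ceiling(p[, 2] / px - 0.5) + 1
  inside <- ir >= 1 & ir <= nrow(m) & ic >= 1 & ic <= ncol(m)
  out <- sum(m[cbind(ir[inside], ic[inside])])
  out <- as.integer(out)
  attr(out, "nOutside") <- as.integer(sum(!inside))
  out
}

#' Track density with Poisson counting error
#'
#' \code{density = count / area}, \code{sigma = sqrt(count) / area}: the
#' 1-sigma error comes purely from the counting statistics of the observed
#' tracks.
#'
#' @param count integer track count.
#' @param areaMm2 region area in mm^2.
#' @return A \code{\link{RegionDensity-class}}.
#' @examples
#' regionDensity(100, 1)   # 100 +/- 10 per mm^2
#' @export
regionDensity <- function(count, areaMm2) {
  if (areaMm2 <= 0) stop("areaMm2 must be positive")
  if (count < 0 || count != round(count)) stop("count must be a non-negative integer")
  new("RegionDensity", count = as.numeric(count), areaMm2 = areaMm2,
      densityPerMm2 = count / areaMm2,
      sigmaPerMm2 = sqrt(count) / areaMm2)
}

#' Concentration efficiency (tumor-to-normal density ratio)
#'
#' The ratio of track densities in the pink (tumor) to the purple (normal)
#' region, with the 1-sigma error propagated from the independent Poisson
#' counts:
#' \deqn{\sigma_r = r \sqrt{(\sigma_p/\rho_p)^2 + (\sigma_n/\rho_n)^2}.}
#'
#' @param pink \code{RegionDensity} of the pink (tumor) region.
#' @param purple \code{RegionDensity} of the purple (normal) region.
#' @return list with \code{ratio} and \code{sigma}.
#' @export
concentrationEfficiency <- function(pink, purple) {
  rp <- trackDensity(pink); rn <- trackDensity(purple)
  if (rn <= 0) stop("purple (denominator) density must be positive")
  if (rp <= 0) stop("pink (numerator) density must be positive")
  r <- rp / rn
  sig <- r * sqrt((densitySigma(pink) / rp)^2 +
                  (densitySigma(purple) / rn)^2)
  list(ratio = r, sigma = sig)
}
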
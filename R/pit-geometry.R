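## Etch-pit geometry: detector response S, critical angle, detection
## efficiency, and a simple moment-based pit detector.

#' Detector response from etch-pit aperture axes
#'
#' The response \eqn{S = V_t/V_b - 1} (track-to-bulk etch velocity ratio
#' minus one) is recovered from the elliptical pit aperture as
#' \deqn{S = \sqrt{\frac{16 B^2 D_A^2}{(4B^2 - D_B^2)^2} + 1} - 1,}
#' with \eqn{D_A \ge D_B} the major and minor aperture axes and \eqn{B} the
#' bulk removal thickness. For circular pits (\eqn{D_A = D_B = d}) this
#' reduces to \eqn{S = 2 d^2 / (4 B^2 - d^2)}.
#'
#' Pits with \eqn{D_B \ge 2B} are over-etched: the denominator vanishes and
#' the conical-pit model does not apply; they raise an error here (bulk
#' handling with an exclusion policy is in \code{\link{deriveTracks}}).
#'
#' @param majorAxisUm major aperture axis D_A (um), vectorised.
#' @param minorAxisUm minor aperture axis D_B (um), vectorised.
#' @param etch an \code{\link{etchConfig}} or a numeric removal thickness
#'   B in um.
#' @return numeric vector of responses S (dimensionless, >= 0).
#' @examples
#' detectorResponse(3.3, 3.3, etchConfig())   # 2/3
#' @seealso \code{\link{detectionEfficiency}}, \code{\link{criticalAngle}}
#' @export
detectorResponse <- function(majorAxisUm, minorAxisUm, etch = etchConfig()) {
  B <- if (is(etch, "EtchConfig")) etch@removalBUm else as.numeric(etch)
  if (B <= 0) stop("removal thickness B must be positive")
  if (any(!is.finite(majorAxisUm)) || any(!is.finite(minorAxisUm)))
    stop("pit axes must be finite")
  if (any(minorAxisUm <= 0) || any(majorAxisUm <= 0))
    stop("pit axes must be positive")
  if (any(minorAxisUm > majorAxisUm))
    stop("minor axis exceeds major axis; order the axes first")
  if (any(minorAxisUm >= 2 * B))
    stop("degenerate (over-etched) pit: minor axis >= 2B")
  sqrt(16 * B^2 * majorAxisUm^2 / (4 * B^2 - minorAxisUm^2)^2 + 1) - 1
}

#' Detection efficiency from detector response
#'
#' For isotropic incidence only particles with dip angle above the critical
#' angle \eqn{\theta_c} register; integrating the angular distribution gives
#' \deqn{\eta = 1 - \sin^2\theta_c = \frac{(S+1)^2 - 1}{(S+1)^2},}
#' the fraction of incident particles that form observable pits
#' (track per particle). Strictly increasing in S, in \eqn{[0, 1)}.
#'
#' @param responseS detector response S (>= 0), vectorised.
#' @return efficiency eta in [0, 1).
#' @examples
#' detectionEfficiency(1)   # 0.75
#' @export
detectionEfficiency <- function(responseS) {
  if (any(!is.finite(responseS)) || any(responseS < 0))
    stop("responseS must be finite and >= 0")
  1 - 1 / (responseS + 1)^2
}

#' Critical dip angle from detector response
#'
#' The minimum dip angle (measured from the detector surface plane) below
#' which a track is not revealed: \eqn{\sin\theta_c = 1/(S+1)}. Strictly
#' decreasing in S; \eqn{\pi/2} at S = 0 (nothing registers).
#'
#' @param responseS detector response S (>= 0), vectorised.
#' @return critical angle in radians.
#' @examples
#' criticalAngle(1)   # pi/6
#' @export
criticalAngle <- function(responseS) {
  if (any(!is.finite(responseS)) || any(responseS < 0))
    stop("responseS must be finite and >= 0")
  asin(1 / (responseS + 1))
}

#' Detect etch pits in a grayscale micrograph
#'
#' A deliberately simple pit detector: pixels darker than a global
#' intensity threshold are foreground, connected components of at least
#' \code{minAreaPx} pixels are pits, each reported at its centroid with
#' aperture axes taken from the ellipse with the same second central
#' moments (a small per-pixel variance correction accounts for pixel
#' footprint). Suitable for well-separated pits on a clean background;
#' merged/overlapping pits are returned as a single component.
#'
#' @param grayImage numeric matrix of 8-bit intensities (0-255), rows = y.
#' @param pixelSizeUm pixel edge length (um).
#' @param intensityThreshold pixels with intensity strictly below this are
#'   pit candidates (default 138).
#' @param minAreaPx minimum component size in pixels (default 4).
#' @return data.frame with columns \code{x_um}, \code{y_um},
#'   \code{major_axis_um}, \code{minor_axis_um}, \code{area_px}
#'   (zero rows if no pits).
#' @export
detectPits <- function(grayImage, pixelSizeUm, intensityThreshold = 138,
                       minAreaPx = 4L) {
  stopifnot(is.matrix(grayImage), pixelSizeUm > 0)
  fg <- (grayImage < intensityThreshold) * 1L
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      major_axis_um = numeric(0), minor_axis_um = numeric(0),
                      area_px = integer(0))
  if (!any(fg > 0)) return(empty)
  labels <- EBImage::bwlabel(fg)
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  ## pixel centers in um: x from column, y from row, origin top-left center
  px <- pixelSizeUm
  xs <- (idx[, "col"] - 1) * px
  ys <- (idx[, "row"] - 1) * px
  out <- lapply(split(seq_along(lab), lab), function(ii) {
    if (length(ii) < minAreaPx) return(NULL)
    x <- xs[ii]; y <- ys[ii]
    cx <- mean(x); cy <- mean(y)
    ## second central moments + pixel-footprint variance px^2/12
    mxx <- mean((x - cx)^2) + px^2 / 12
    myy <- mean((y - cy)^2) + px^2 / 12
    mxy <- mean((x - cx) * (y - cy))
    ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2, 2), symmetric = TRUE)$values
    ev <- pmax(ev, 0)
    ## uniform filled ellipse: variance along semi-axis a is a^2/4
    data.frame(x_um = cx, y_um = cy,
               major_axis_um = 4 * sqrt(ev[1]),
               minor_axis_um = 4 * sqrt(ev[2]),
               area_px = length(ii))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Derive per-track response, efficiency and LET from a pit table
#'
#' Applies the full pit-to-track chain: axis-order enforcement, the
#' over-etched-pit policy, response \code{S} from the aperture geometry,
#' critical angle, detection efficiency, LET from the calibration curve and
#' the per-track fluence weight \code{1/eta}. Pits whose response falls
#' below the calibration threshold (LET < lower validity bound) are
#' undetectable by the physics and are excluded; nothing is dropped
#' silently -- exclusion counts are attached as attributes.
#'
#' @param pits data.frame with columns \code{x_um}, \code{y_um},
#'   \code{major_axis_um}, \code{minor_axis_um}.
#' @param etch an \code{\link{etchConfig}}.
#' @param curve a \code{\link{defaultCalibration}} or user-loaded curve.
#' @param degenerate policy for over-etched pits (minor axis >= 2B):
#'   \code{"exclude"} (default) drops them, \code{"clamp"} clamps the minor
#'   axis just under 2B (their LET then saturates at the calibration
#'   ceiling).
#' @return data.frame with the input columns plus \code{response_S},
#'   \code{theta_c_rad}, \code{eta}, \code{let_keV_um}, \code{weight};
#'   attributes \code{nDegenerate}, \code{nBelowRange}, \code{nClippedHigh}
#'   count exclusions/clips.
#' @export
deriveTracks <- function(pits, etch = etchConfig(),
                         curve = defaultCalibration(),
                         degenerate = c("exclude", "clamp")) {
  degenerate <- match.arg(degenerate)
  req <- c("x_um", "y_um", "major_axis_um", "minor_axis_um")
  if (!all(req %in% names(pits)))
    stop("pit table must have columns ", paste(req, collapse = ", "))
  B <- etch@removalBUm
  maj <- pits$major_axis_um
  mnr <- pits$minor_axis_um
  swap <- which(mnr > maj)
  if (length(swap)) {
    warning(length(swap), " pit(s) had minor > major axis; axes swapped")
    tmp <- maj[swap]; maj[swap] <- mnr[swap]; mnr[swap] <- tmp
  }
  bad <- which(!(maj > 0 & mnr > 0 & is.finite(maj) & is.finite(mnr)))
  if (length(bad)) stop("non-positive or non-finite pit axes at rows ",
                        paste(utils::head(bad), collapse = ", "))
  degen <- which(mnr >= 2 * B)
  nDegen <- length(degen)
  if (nDegen) {
    if (degenerate == "exclude") {
      keep <- setdiff(seq_along(maj), degen)
      pits <- pits[keep, , drop = FALSE]
      maj <- maj[keep]; mnr <- mnr[keep]
      message(nDegen, " over-etched pit(s) (minor >= 2B) excluded")
    } else {
      mnr[degen] <- 2 * B * (1 - 1e-9)
      maj[degen] <- pmax(maj[degen], mnr[degen])
      message(nDegen, " over-etched pit(s) clamped to minor = 2B")
    }
  }
  out <- pits
  out$major_axis_um <- maj
  out$minor_axis_um <- mnr
  if (nrow(out) == 0L) {
    out$response_S <- out$theta_c_rad <- out$eta <- numeric(0)
    out$let_keV_um <- out$weight <- numeric(0)
  } else {
    S <- detectorResponse(maj, mnr, etch)
    sMin <- min(calibrationKnots(curve)$response_S)
    below <- which(S < sMin)
    if (length(below)) {
      message(length(below),
              " pit(s) below the calibration response threshold excluded")
      out <- out[-below, , drop = FALSE]
      S <- S[-below]
    }
    out$response_S <- S
    out$theta_c_rad <- criticalAngle(S)
    out$eta <- detectionEfficiency(S)
    let <- letFromResponse(S, curve)
    out$let_keV_um <- as.numeric(let)
    out$weight <- 1 / out$eta
    attr(out, "nBelowRange") <- length(below)
    attr(out, "nClippedHigh") <- attr(let, "nClipped") %||% 0L
  }
  attr(out, "nDegenerate") <- nDegen
  if (is.null(attr(out, "nBelowRange"))) attr(out, "nBelowRange") <- 0L
  if (is.null(attr(out, "nClippedHigh"))) attr(out, "nClippedHigh") <- 0L
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a track table
#'
#' Delimited-text (CSV) track tables with at minimum the pit columns
#' \code{x_um, y_um, major_axis_um, minor_axis_um}; derived columns
#' (\code{response_S, eta, theta_c_rad, let_keV_um, weight}) are carried
#' through when present.
#'
#' @param path file path.
#' @return \code{readTrackTable}: a data.frame.
#' @export
readTrackTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  req <- c("x_um", "y_um", "major_axis_um", "minor_axis_um")
  if (!all(req %in% names(df)))
    stop("track table ", path, " lacks required columns ",
         paste(setdiff(req, names(df)), collapse = ", "))
  df
}

#' @param tracks data.frame to write.
#' @rdname readTrackTable
#' @export
writeTrackTable <- function(tracks, path) {
  utils::write.csv(tracks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
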
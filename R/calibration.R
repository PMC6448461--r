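## Response <-> LET calibration. The curve is a monotone knot table,
## log-log linearly interpolated, so forward and inverse lookups are exact
## inverses on and between knots.

#' Construct a calibration curve from a knot table
#'
#' @param knots data.frame with columns \code{let_keV_um}, \code{response_S},
#'   strictly increasing in both.
#' @param validLetRange length-2 LET validity range (keV/um).
#' @param provenance free-text label.
#' @return A \code{\link{CalibrationCurve-class}} object.
#' @export
calibrationCurve <- function(knots, validLetRange = c(3.5, 600),
                             provenance = "user") {
  new("CalibrationCurve", knots = knots, validLetRange = validLetRange,
      provenance = provenance)
}

#' Packaged default calibration curve
#'
#' The default is a synthetic stand-in power law
#' \eqn{S = (L / 100\,\mathrm{keV\,\mu m^{-1}})^{3/2}} tabulated on 41
#' log-spaced knots over 3.5-600 keV/um: monotone, near zero at the
#' 3.5 keV/um detection threshold and of order unity at alpha-particle
#' LETs. It is \emph{not} a measured heavy-ion calibration; replace it with
#' \code{\link{loadCalibration}} for quantitative work with a calibrated
#' detector batch.
#'
#' @return A \code{CalibrationCurve}.
#' @examples
#' responseFromLet(100, defaultCalibration())   # 1
#' @export
defaultCalibration <- function() {
  let <- exp(seq(log(3.5), log(600), length.out = 41))
  knots <- data.frame(let_keV_um = let, response_S = (let / 100)^1.5)
  calibrationCurve(knots, c(3.5, 600),
                   provenance = "synthetic power-law stand-in S=(L/100)^1.5")
}

#' LET from detector response
#'
#' Log-log linear interpolation of the calibration knots. Responses below
#' the curve's threshold response are physically undetectable (LET below
#' the lower validity bound) and raise an error; responses above the top
#' knot are clipped to the upper LET bound, with the number of clipped
#' values returned in the \code{nClipped} attribute.
#'
#' @param responseS detector response, vectorised.
#' @param curve a \code{CalibrationCurve}.
#' @return LET in keV/um with attribute \code{nClipped}.
#' @export
letFromResponse <- function(responseS, curve = defaultCalibration()) {
  k <- calibrationKnots(curve)
  if (any(!is.finite(responseS)))
    stop("responseS must be finite")
  sMin <- min(k$response_S); sMax <- max(k$response_S)
  if (any(responseS < sMin * (1 - 1e-12)))
    stop("response below calibration threshold (LET < ",
         curve@validLetRange[1], " keV/um is undetectable)")
  nClipped <- sum(responseS > sMax * (1 + 1e-12))
  if (nClipped > 0)
    warning(nClipped, " response(s) above calibration ceiling clipped to ",
            curve@validLetRange[2], " keV/um")
  s <- pmin(pmax(responseS, sMin), sMax)
  let <- exp(stats::approx(log(k$response_S), log(k$let_keV_um),
                           xout = log(s), rule = 2)$y)
  let <- pmin(pmax(let, curve@validLetRange[1]), curve@validLetRange[2])
  attr(let, "nClipped") <- nClipped
  let
}

#' Detector response from LET
#'
#' Exact inverse of \code{\link{letFromResponse}} on the knot grid (both
#' directions interpolate the same log-log polyline). Needed by the
#' forward simulator.
#'
#' @param letKeVUm LET in keV/um, within the curve's validity range.
#' @param curve a \code{CalibrationCurve}.
#' @return detector response S.
#' @export
responseFromLet <- function(letKeVUm, curve = defaultCalibration()) {
  k <- calibrationKnots(curve)
  r <- curve@validLetRange
  if (any(!is.finite(letKeVUm)))
    stop("letKeVUm must be finite")
  if (any(letKeVUm < r[1] * (1 - 1e-12)) || any(letKeVUm > r[2] * (1 + 1e-12)))
    stop("LET outside calibration validity range [", r[1], ", ", r[2],
         "] keV/um")
  l <- pmin(pmax(letKeVUm, min(k$let_keV_um)), max(k$let_keV_um))
  exp(stats::approx(log(k$let_keV_um), log(k$response_S),
                    xout = log(l), rule = 2)$y)
}

#' Load / save a calibration curve
#'
#' Two-column delimited text (header \code{let_keV_um, response_S}).
#' Save-then-load round trips are lossless to printed precision (15
#' significant digits).
#'
#' @param path file path.
#' @param validLetRange LET validity range assigned on load; defaults to
#'   the knot span.
#' @param provenance label assigned on load (default: the file path).
#' @return \code{loadCalibration}: a \code{CalibrationCurve}.
#' @export
loadCalibration <- function(path, validLetRange = NULL, provenance = path) {
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) stop("cannot read calibration file ",
                                          path, ": ", conditionMessage(e)))
  if (nrow(df) == 0L) stop("calibration file ", path, " is empty")
  if (!all(c("let_keV_um", "response_S") %in% names(df)))
    stop("calibration file must have columns let_keV_um, response_S")
  if (is.null(validLetRange))
    validLetRange <- range(df$let_keV_um)
  calibrationCurve(df[c("let_keV_um", "response_S")], validLetRange,
                   provenance = provenance)
}

#' @param curve a \code{CalibrationCurve} to save.
#' @rdname loadCalibration
#' @export
saveCalibration <- function(curve, path) {
  k <- calibrationKnots(curve)
  k$let_keV_um <- formatC(k$let_keV_um, digits = 15, format = "g")
  k$response_S <- formatC(k$response_S, digits = 15, format = "g")
  utils::write.csv(k, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
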
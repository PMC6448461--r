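## Efficiency-corrected LET spectra, absorbed dose, cell-scale dose maps,
## track-density maps, and the decay-window correction.

#' Default LET bin edges
#'
#' Bins of width 10 keV/um spanning the detectable range 3.5-600 keV/um,
#' phased so that bin midpoints fall on multiples of 10 keV/um (edges at
#' 3.5, 5, 15, ..., 595, 600). Centering bins on round LET values keeps a
#' spectral peak at a round value (e.g. the ~130 keV/um alpha peak) at a
#' bin center rather than on an edge, where the modal bin would be
#' ill-defined for a symmetric peak.
#'
#' @return numeric vector of ascending bin edges (keV/um).
#' @export
defaultLetBins <- function() {
  c(3.5, seq(5, 595, by = 10), 600)
}

#' Build an efficiency-corrected LET spectrum
#'
#' Each registered track contributes its fluence weight \eqn{1/\eta} to the
#' bin containing its LET; dividing by the scored area gives the incident
#' fluence per bin, \eqn{\phi_i = \sum_{\mathrm{bin}\ i} (1/\eta) / A}.
#' Bins are half-open \code{[low, high)}, last bin closed. The spectrum is
#' additive under track-list concatenation.
#'
#' @param tracks data.frame with columns \code{let_keV_um} and \code{eta}
#'   (or \code{weight}); typically from \code{\link{deriveTracks}}.
#' @param areaCm2 scored detector area (cm^2).
#' @param binEdges ascending LET bin edges (default
#'   \code{\link{defaultLetBins}}).
#' @return A \code{\link{LETSpectrum-class}} object.
#' @export
buildLetSpectrum <- function(tracks, areaCm2, binEdges = defaultLetBins()) {
  stopifnot(areaCm2 > 0)
  nb <- length(binEdges) - 1L
  if (nrow(tracks) == 0L)
    return(new("LETSpectrum", binEdges = binEdges,
               fluence = numeric(nb), counts = integer(nb),
               areaCm2 = areaCm2))
  if (!"let_keV_um" %in% names(tracks))
    stop("tracks need a let_keV_um column")
  w <- if ("eta" %in% names(tracks)) {
    if (any(tracks$eta <= 0))
      stop("track with eta <= 0 reached spectrum building; ",
           "exclude undetectable tracks upstream")
    1 / tracks$eta
  } else if ("weight" %in% names(tracks)) {
    if (any(tracks$weight < 1)) stop("weights must be >= 1")
    tracks$weight
  } else stop("tracks need an eta or weight column")
  let <- tracks$let_keV_um
  bin <- findInterval(let, binEdges, rightmost.closed = TRUE)
  inb <- bin >= 1L & bin <= nb
  if (!all(inb))
    warning(sum(!inb), " track(s) outside the LET bin range dropped")
  fl <- numeric(nb); ct <- integer(nb)
  tb <- tapply(w[inb], factor(bin[inb], levels = seq_len(nb)), sum)
  fl[] <- ifelse(is.na(tb), 0, tb) / areaCm2
  cb <- table(factor(bin[inb], levels = seq_len(nb)))
  ct[] <- as.integer(cb)
  new("LETSpectrum", binEdges = binEdges, fluence = fl, counts = ct,
      areaCm2 = areaCm2)
}

#' Bin midpoints of a spectrum
#' @param spectrum a \code{LETSpectrum} (or numeric edges).
#' @return numeric vector of arithmetic bin midpoints.
#' @export
letBinMids <- function(spectrum) {
  e <- if (is(spectrum, "LETSpectrum")) letBinEdges(spectrum) else spectrum
  (e[-1] + e[-length(e)]) / 2
}

#' Mode of an LET spectrum
#'
#' Midpoint of the bin with the largest efficiency-corrected fluence (ties
#' broken toward lower LET).
#'
#' @param spectrum a \code{LETSpectrum}.
#' @return LET (keV/um) at the modal bin midpoint.
#' @export
spectrumMode <- function(spectrum) {
  letBinMids(spectrum)[which.max(fluencePerBin(spectrum))]
}

#' Absorbed dose from an LET spectrum
#'
#' \deqn{D\,(\mathrm{Gy}) = \frac{1.6\times 10^{-9}}{\rho}
#'   \sum_i \phi_i L_i,}
#' with fluence \eqn{\phi_i} in cm^-2, the bin-representative LET
#' \eqn{L_i} taken as the arithmetic bin midpoint (keV/um) and specific
#' gravity \eqn{\rho} in g/cm^3. The prefactor converts keV/um per cm^2
#' and gram to gray.
#'
#' @param spectrum a \code{LETSpectrum}.
#' @param config a \code{\link{dosimetryConfig}}.
#' @return absorbed dose in Gy.
#' @examples
#' # phi = 1e9 cm^-2 at L = 1 keV/um in water -> 1.6 Gy
#' @export
absorbedDose <- function(spectrum, config = dosimetryConfig()) {
  mids <- letBinMids(spectrum)
  1.6e-9 / config@rhoGCm3 * sum(fluencePerBin(spectrum) * mids)
}

## shared cell-index helper: half-open [low, high) cells, tracks on an
## upper edge belong to the next cell
.gridIndex <- function(coordUm, originUm, cellUm, n) {
  i <- floor((coordUm - originUm) / cellUm) + 1
  ifelse(i >= 1 & i <= n, i, NA_real_)
}

#' Cell-scale absorbed-dose map
#'
#' Bins registered tracks into square cells (default 10 um, a typical cell
#' diameter) and computes per-cell dose from the per-track LET and fluence
#' weight:
#' \deqn{D_{cell} = \frac{1.6\times10^{-9}}{\rho}
#'   \frac{\sum_{cell} L \cdot w}{A_{cell}},}
#' with \eqn{A_{cell}} in cm^2. Tracks outside the grid are excluded and
#' counted in the \code{nOutside} attribute (never silently dropped).
#'
#' @param tracks data.frame with \code{x_um}, \code{y_um},
#'   \code{let_keV_um} and \code{weight} (weight defaults to 1 if absent).
#' @param originUm grid origin (x, y) in um, the lower corner of the
#'   registered tissue bounding box.
#' @param extentUm grid extent (width, height) in um from the origin.
#' @param cellSizeUm square cell size (default 10).
#' @param config a \code{\link{dosimetryConfig}}.
#' @return A \code{\link{DoseMap-class}} with attribute \code{nOutside}.
#' @export
localDoseMap <- function(tracks, originUm, extentUm, cellSizeUm = 10,
                         config = dosimetryConfig()) {
  stopifnot(length(originUm) == 2L, length(extentUm) == 2L,
            all(extentUm > 0), cellSizeUm > 0)
  nx <- as.integer(ceiling(extentUm[1] / cellSizeUm))
  ny <- as.integer(ceiling(extentUm[2] / cellSizeUm))
  dose <- matrix(0, ny, nx)
  cnts <- matrix(0L, ny, nx)
  w <- if ("weight" %in% names(tracks)) tracks$weight else
    rep(1, nrow(tracks))
  nOutside <- 0L
  if (nrow(tracks) > 0L) {
    ix <- .gridIndex(tracks$x_um, originUm[1], cellSizeUm, nx)
    iy <- .gridIndex(tracks$y_um, originUm[2], cellSizeUm, ny)
    ok <- !is.na(ix) & !is.na(iy)
    nOutside <- sum(!ok)
    if (nOutside > 0L)
      message(nOutside, " track(s) outside the dose-map grid excluded")
    if (any(ok)) {
      cellId <- (ix[ok] - 1) * ny + iy[ok]
      lw <- tracks$let_keV_um[ok] * w[ok]
      sums <- tapply(lw, cellId, sum)
      ids <- as.integer(names(sums))
      aCellCm2 <- (cellSizeUm * 1e-4)^2
      dose[ids] <- as.numeric(sums) * 1.6e-9 / config@rhoGCm3 / aCellCm2
      tab <- table(cellId)
      cnts[as.integer(names(tab))] <- as.integer(tab)
    }
  }
  out <- new("DoseMap", originUm = as.numeric(originUm),
             cellSizeUm = cellSizeUm, dose = dose, counts = cnts)
  attr(out, "nOutside") <- nOutside
  out
}

#' Track-density map
#'
#' Integer counts of registered tracks in square bins (default 50 um), the
#' autoradiographic intensity map. Total count equals the number of
#' in-bounds tracks; out-of-grid tracks are counted in \code{nOutside}.
#'
#' @param tracks data.frame with \code{x_um}, \code{y_um}.
#' @param originUm grid origin (x, y) in um.
#' @param extentUm grid extent (width, height) in um.
#' @param binSizeUm square bin size (default 50).
#' @return A \code{\link{DensityMap-class}} with attribute \code{nOutside}.
#' @export
trackDensityMap <- function(tracks, originUm, extentUm, binSizeUm = 50) {
  stopifnot(length(originUm) == 2L, length(extentUm) == 2L,
            all(extentUm > 0), binSizeUm > 0)
  nx <- as.integer(ceiling(extentUm[1] / binSizeUm))
  ny <- as.integer(ceiling(extentUm[2] / binSizeUm))
  cnts <- matrix(0L, ny, nx)
  nOutside <- 0L
  if (nrow(tracks) > 0L) {
    ix <- .gridIndex(tracks$x_um, originUm[1], binSizeUm, nx)
    iy <- .gridIndex(tracks$y_um, originUm[2], binSizeUm, ny)
    ok <- !is.na(ix) & !is.na(iy)
    nOutside <- sum(!ok)
    if (any(ok)) {
      tab <- table((ix[ok] - 1) * ny + iy[ok])
      cnts[as.integer(names(tab))] <- as.integer(tab)
    }
  }
  out <- new("DensityMap", originUm = as.numeric(originUm),
             binSizeUm = binSizeUm, counts = cnts)
  attr(out, "nOutside") <- nOutside
  out
}

#' Decay-window dose correction factor
#'
#' An autoradiograph records only decays between mounting (\code{t1}) and
#' removal (\code{t2}); activity decayed exponentially from injection at
#' \code{t0 = 0}. Since dose scales with the number of decays in each
#' window, the unrecorded initial dose \eqn{D_0} (for \eqn{[t_0, t_1]})
#' relates to the observed dose \eqn{D} (for \eqn{[t_1, t_2]}) by the
#' ratio of decay counts:
#' \deqn{\frac{D_0}{D} =
#'   \frac{1 - e^{-\lambda t_1}}{e^{-\lambda t_1} - e^{-\lambda t_2}}.}
#' Limits: 0 as \eqn{t_1 \to 0} (no pre-window decays); 1 for
#' \eqn{t_1 = T_{1/2}, t_2 \to \infty} (equal decay counts before and
#' after mounting). Defaults give \eqn{D_0/D \approx 2.291}.
#'
#' @param model a \code{\link{decayModel}}.
#' @return the ratio \eqn{D_0/D} (dimensionless).
#' @examples
#' decayCorrectionFactor(decayModel())   # ~2.291
#' @export
decayCorrectionFactor <- function(model = decayModel()) {
  lam <- decayConstant(model)
  t1 <- model@t1H; t2 <- model@t2H
  if (!(t2 > t1)) stop("degenerate decay window: need t1 < t2")
  e1 <- exp(-lam * t1)
  e2 <- if (is.infinite(t2)) 0 else exp(-lam * t2)
  (1 - e1) / (e1 - e2)
}

#' Total (decay-corrected) dose
#'
#' Scales an observed dose (scalar or \code{DoseMap}, recorded over
#' \code{[t1, t2]}) to the total dose over \code{[t0, t2]} by adding the
#' unrecorded initial component:
#' \eqn{D_{tot} = D \cdot (1 + D_0/D)}. Applied cellwise for maps (raw
#' counts are left untouched: they remain observed counts).
#'
#' @param observed numeric dose in Gy or a \code{DoseMap}.
#' @param model a \code{\link{decayModel}}.
#' @return same shape as \code{observed}.
#' @export
setGeneric("totalDose", function(observed, model = decayModel())
  standardGeneric("totalDose"))

#' @rdname totalDose
#' @export
setMethod("totalDose", "numeric", function(observed, model = decayModel()) {
  observed * (1 + decayCorrectionFactor(model))
})

#' @rdname totalDose
#' @export
setMethod("totalDose", "DoseMap", function(observed, model = decayModel()) {
  f <- 1 + decayCorrectionFactor(model)
  new("DoseMap", originUm = observed@originUm,
      cellSizeUm = observed@cellSizeUm,
      dose = observed@dose * f, counts = observed@counts)
})

#' Histogram of nonzero cell doses
#'
#' Tabulates the nonzero cells of a dose map into dose bins, the standard
#' summary of a heterogeneous cell-scale dose distribution. Reports the
#' modal bin and the occupied dose range.
#'
#' @param map a \code{DoseMap}.
#' @param binWidthGy dose bin width in Gy (default 0.5).
#' @return list with \code{breaks}, \code{counts}, \code{mids},
#'   \code{modeGy} (midpoint of the modal bin), \code{rangeGy} and
#'   \code{nNonzero}.
#' @export
doseHistogram <- function(map, binWidthGy = 0.5) {
  v <- doseValues(map)
  v <- v[v > 0]
  if (length(v) == 0L)
    return(list(breaks = numeric(0), counts = integer(0), mids = numeric(0),
                modeGy = NA_real_, rangeGy = c(NA_real_, NA_real_),
                nNonzero = 0L))
  breaks <- seq(0, (floor(max(v) / binWidthGy) + 1) * binWidthGy,
                by = binWidthGy)
  bin <- findInterval(v, breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  list(breaks = breaks, counts = counts, mids = mids,
       modeGy = mids[which.max(counts)], rangeGy = range(v),
       nNonzero = length(v))
}
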
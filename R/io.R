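## Image and grid-map IO. Images are 8-bit PNG or TIFF; grids are
## delimited-text matrices with a JSON sidecar header.

#' Read / write 8-bit images
#'
#' RGB micrographs and grayscale pit images as PNG or TIFF (chosen by file
#' extension). In memory, RGB images are integer arrays
#' \code{[rows, cols, 3]} and grayscale images integer matrices, both with
#' 8-bit values 0-255.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return \code{readImage8}: an integer matrix (grayscale file) or
#'   \code{[rows, cols, 3]} array.
#' @export
readImage8 <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image extension: ", ext))
  if (length(dim(img)) == 3L && dim(img)[3] >= 3L)
    img <- img[, , 1:3, drop = FALSE]   # drop alpha
  out <- round(img * 255)
  storage.mode(out) <- "integer"
  out
}

#' @param image integer matrix or \code{[rows, cols, 3]} array (0-255), or
#'   a logical matrix (written as a black/white mask).
#' @rdname readImage8
#' @export
writeImage8 <- function(image, path) {
  if (is.logical(image)) image <- image * 255L
  ext <- tolower(tools::file_ext(path))
  x <- image / 255
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop("unsupported image extension: ", ext))
  invisible(path)
}

#' Write / read a region mask as 1-bit-style PNG
#'
#' @param mask a \code{\link{RegionMask-class}}.
#' @param path PNG path.
#' @export
writeMask <- function(mask, path) {
  writeImage8(maskValues(mask), path)
}

#' @param pixelSizeUm,label metadata to attach on read.
#' @rdname writeMask
#' @export
readMask <- function(path, pixelSizeUm, label = "region") {
  img <- readImage8(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  regionMask(img > 127, pixelSizeUm, label)
}

#' Write / read a gridded map (dose or density)
#'
#' The grid is written as a headerless delimited-text matrix
#' (\code{<base>.csv}, rows = y) plus a JSON sidecar (\code{<base>.json})
#' recording origin, cell size, units and the map kind; dose maps also
#' write their raw-count grid as \code{<base>_counts.csv}.
#'
#' @param map a \code{DoseMap} or \code{DensityMap}.
#' @param basePath path without extension.
#' @return \code{writeGridMap}: invisibly, the sidecar path.
#' @export
writeGridMap <- function(map, basePath) {
  if (is(map, "DoseMap")) {
    grid <- doseValues(map); cell <- map@cellSizeUm
    kind <- "dose"; units <- "Gy"
    utils::write.table(cellCounts(map), paste0(basePath, "_counts.csv"),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  } else if (is(map, "DensityMap")) {
    grid <- densityCounts(map); cell <- map@binSizeUm
    kind <- "density"; units <- "tracks"
  } else stop("map must be a DoseMap or DensityMap")
  utils::write.table(grid, paste0(basePath, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  side <- list(kind = kind, units = units, origin_um = map@originUm,
               cell_size_um = cell, nrow = nrow(grid), ncol = ncol(grid))
  jsonlite::write_json(side, paste0(basePath, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(basePath, ".json"))
}

#' @rdname writeGridMap
#' @export
readGridMap <- function(basePath) {
  side <- jsonlite::read_json(paste0(basePath, ".json"),
                              simplifyVector = TRUE)
  grid <- as.matrix(utils::read.table(paste0(basePath, ".csv"), sep = ","))
  dimnames(grid) <- NULL
  if (identical(side$kind, "dose")) {
    cnts <- as.matrix(utils::read.table(paste0(basePath, "_counts.csv"),
                                        sep = ","))
    dimnames(cnts) <- NULL
    storage.mode(cnts) <- "integer"
    new("DoseMap", originUm = as.numeric(side$origin_um),
        cellSizeUm = side$cell_size_um, dose = grid, counts = cnts)
  } else {
    storage.mode(grid) <- "integer"
    new("DensityMap", originUm = as.numeric(side$origin_um),
        binSizeUm = side$cell_size_um, counts = grid)
  }
}

#' Write / read an LET spectrum as delimited text
#'
#' Columns: bin low/high edge, midpoint, fluence (cm^-2) and raw counts;
#' the scored area is carried in a comment-free extra column so the file
#' is self-contained.
#'
#' @param spectrum a \code{LETSpectrum}.
#' @param path CSV path.
#' @export
writeSpectrum <- function(spectrum, path) {
  e <- letBinEdges(spectrum)
  df <- data.frame(let_low_keV_um = e[-length(e)], let_high_keV_um = e[-1],
                   let_mid_keV_um = letBinMids(spectrum),
                   fluence_per_cm2 = fluencePerBin(spectrum),
                   counts = rawCounts(spectrum),
                   area_cm2 = spectrum@areaCm2)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSpectrum
#' @export
readSpectrum <- function(path) {
  df <- utils::read.csv(path)
  new("LETSpectrum",
      binEdges = c(df$let_low_keV_um, df$let_high_keV_um[nrow(df)]),
      fluence = df$fluence_per_cm2, counts = as.integer(df$counts),
      areaCm2 = df$area_cm2[1])
}
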
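## Landmark-based affine registration between the pre-etch tissue frame
## and the post-etch detector frame (markers scratched with a diamond pen).

.asXY <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L) stop("points must be n x 2 (x, y)")
  points
}

#' Fit an affine transform to marker pairs
#'
#' Least-squares estimate of the six-parameter affine transform minimizing
#' \eqn{\sum \|T(\mathrm{pre}) - \mathrm{post}\|^2}. With exactly three
#' non-collinear markers the fit interpolates exactly; four or more
#' markers give an overdetermined least-squares solution (and a meaningful
#' \code{\link{rmsResidual}} as registration QC).
#'
#' @param pre n x 2 matrix (or data.frame) of marker positions in the
#'   source (tissue-image) frame, um.
#' @param post n x 2 matrix of the same markers in the target
#'   (detector) frame, um.
#' @return An \code{\link{AffineTransform2D-class}}.
#' @examples
#' pre <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1)) * 1000
#' fitAffine(pre, pre)   # identity
#' @export
fitAffine <- function(pre, post) {
  pre <- .asXY(pre); post <- .asXY(post)
  if (nrow(pre) != nrow(post)) stop("pre and post must pair up row-wise")
  if (nrow(pre) < 3L)
    stop("need at least 3 marker pairs to fit an affine transform")
  if (any(!is.finite(pre)) || any(!is.finite(post)))
    stop("marker coordinates must be finite")
  X <- cbind(pre, 1)
  qrX <- qr(X)
  if (qrX$rank < 3L)
    stop("markers are collinear; affine transform is not identifiable")
  beta <- qr.coef(qrX, post)   # 3 x 2: rows a1., a2., t
  affineTransform(A = t(beta[1:2, , drop = FALSE]), b = beta[3, ])
}

#' Apply an affine transform to points
#'
#' @param points n x 2 matrix or data.frame of (x, y) in um.
#' @param transform an \code{AffineTransform2D}.
#' @return n x 2 matrix of transformed points.
#' @export
applyAffine <- function(points, transform) {
  p <- .asXY(points)
  sweep(p %*% t(transform@A), 2, transform@b, "+")
}

#' Invert an affine transform
#' @param transform an \code{AffineTransform2D}.
#' @return the inverse transform.
#' @export
invertAffine <- function(transform) {
  Ainv <- solve(transform@A)
  affineTransform(A = Ainv, b = as.numeric(-Ainv %*% transform@b))
}

#' Compose two affine transforms
#'
#' \code{composeAffine(t2, t1)} is the transform applying \code{t1} first:
#' \code{apply(t2, apply(t1, p)) == apply(compose(t2, t1), p)}.
#'
#' @param t2,t1 \code{AffineTransform2D} objects.
#' @return the composed transform.
#' @export
composeAffine <- function(t2, t1) {
  affineTransform(A = t2@A %*% t1@A,
                  b = as.numeric(t2@A %*% t1@b) + t2@b)
}

#' RMS registration residual
#'
#' Root-mean-square of \eqn{\|T(\mathrm{pre}) - \mathrm{post}\|} over the
#' marker pairs; zero for an exactly interpolating (3-marker) fit. Used as
#' registration quality control.
#'
#' @param pre,post marker matrices as in \code{\link{fitAffine}}.
#' @param transform the fitted transform.
#' @return RMS residual in um.
#' @export
rmsResidual <- function(pre, post, transform) {
  pre <- .asXY(pre); post <- .asXY(post)
  d <- applyAffine(pre, transform) - post
  sqrt(mean(rowSums(d^2)))
}

#' Read a marker-pair file
#'
#' Delimited text with columns \code{pre_x_um, pre_y_um, post_x_um,
#' post_y_um}, one row per scratched marker.
#'
#' @param path file path.
#' @return list with matrices \code{pre} and \code{post}.
#' @export
readMarkers <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  req <- c("pre_x_um", "pre_y_um", "post_x_um", "post_y_um")
  if (!all(req %in% names(df)))
    stop("marker file must have columns ", paste(req, collapse = ", "))
  list(pre = as.matrix(df[c("pre_x_um", "pre_y_um")]),
       post = as.matrix(df[c("post_x_um", "post_y_um")]))
}

#' @param pre,post marker matrices to write.
#' @rdname readMarkers
#' @export
writeMarkers <- function(pre, post, path) {
  pre <- .asXY(pre); post <- .asXY(post)
  utils::write.csv(data.frame(pre_x_um = pre[, 1], pre_y_um = pre[, 2],
                              post_x_um = post[, 1], post_y_um = post[, 2]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
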
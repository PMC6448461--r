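## Shared fixtures, all built in code.

## Render axis-rotated filled ellipses into an 8-bit grayscale image:
## dark pits (intensity 0) on a bright (255) background. `ellipses` is a
## matrix with columns cx, cy (um), major, minor (full axes, um),
## angle (rad).
renderPitImage <- function(ellipses, nrowPx, ncolPx, pixelSizeUm) {
  img <- matrix(255, nrowPx, ncolPx)
  x <- (seq_len(ncolPx) - 1) * pixelSizeUm
  y <- (seq_len(nrowPx) - 1) * pixelSizeUm
  X <- matrix(x, nrowPx, ncolPx, byrow = TRUE)
  Y <- matrix(y, nrowPx, ncolPx)
  for (i in seq_len(nrow(ellipses))) {
    e <- ellipses[i, ]
    dx <- X - e[1]; dy <- Y - e[2]
    u <- dx * cos(e[5]) + dy * sin(e[5])
    v <- -dx * sin(e[5]) + dy * cos(e[5])
    inside <- (u / (e[3] / 2))^2 + (v / (e[4] / 2))^2 <= 1
    img[inside] <- 0
  }
  img
}

## Small, fast phantom used by most simulator tests: 500 x 500 um field.
smallPhantomConfig <- function(seed = 42L, ...) {
  phantomConfig(imageSizePx = c(250L, 250L), pixelSizeUm = 2,
                seed = seed, ...)
}

## Random valid pit table consistent with the forward model.
randomTrackSet <- function(n, seed = 1L, etch = etchConfig(),
                           curve = defaultCalibration()) {
  set.seed(seed)
  let <- pmin(pmax(rnorm(n, 130, 20), 3.5), 600)
  s <- responseFromLet(let, curve)
  thetac <- criticalAngle(s)
  theta <- asin(sqrt(runif(n, sin(thetac)^2, 1)))  # registered by construction
  ax <- forwardPitModel(let, theta, etch, curve)
  data.frame(x_um = runif(n, 0, 1000), y_um = runif(n, 0, 1000),
             major_axis_um = ax$major_axis_um,
             minor_axis_um = ax$minor_axis_um)
}
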
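test_that("grayscale conversion is the rounded channel mean", {
  px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))
  expect_identical(toGrayscale(px(255, 255, 255))[1, 1], 255)
  expect_identical(toGrayscale(px(0, 0, 0))[1, 1], 0)
  expect_identical(toGrayscale(px(150, 60, 120))[1, 1], 110)
  expect_identical(toGrayscale(px(1, 0, 0))[1, 1], 0)    # 1/3 rounds down
  expect_identical(toGrayscale(px(2, 1, 1))[1, 1], 1)
  expect_error(toGrayscale(matrix(0, 2, 2)), "rows, cols, 3")
  # luminance option differs for colored pixels
  expect_identical(toGrayscale(px(150, 60, 120), "luminance")[1, 1],
                   floor(0.299 * 150 + 0.587 * 60 + 0.114 * 120 + 0.5))
})

test_that("tissue binarization is strict gray < threshold", {
  g <- matrix(c(255, 120, 138, 137), 2, 2)
  m <- binarizeTissue(g, 1)
  expect_identical(maskValues(m), matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2))
  allWhite <- binarizeTissue(matrix(255, 4, 4), 1)
  expect_identical(sum(maskValues(allWhite)), 0L)
})

test_that("the pink band-pass respects bands and the tissue mask", {
  img <- array(0L, c(1, 3, 3))
  img[1, 1, ] <- c(150, 60, 120)   # inside all bands, gray 110 -> pink
  img[1, 2, ] <- c(120, 80, 160)   # R below band -> tissue but not pink
  img[1, 3, ] <- c(255, 255, 255)  # blank
  pink <- bandPassMask(img, 1)
  expect_identical(as.vector(maskValues(pink)), c(TRUE, FALSE, FALSE))
  seg <- segmentTissue(img, 1)
  expect_identical(as.vector(maskValues(seg$tissue)), c(TRUE, TRUE, FALSE))
  expect_identical(as.vector(maskValues(seg$purple)), c(FALSE, TRUE, FALSE))
})

test_that("pink and purple partition the tissue on any image", {
  set.seed(23)
  img <- array(sample(0:255, 60 * 60 * 3, replace = TRUE), c(60, 60, 3))
  seg <- segmentTissue(img, 1)
  expect_false(any(maskValues(seg$pink) & maskValues(seg$purple)))
  expect_identical(maskValues(seg$pink) | maskValues(seg$purple),
                   maskValues(seg$tissue))
})

test_that("track counting uses nearest-pixel lookup with exclusion count", {
  m <- regionMask(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2), 10)
  none <- countTracksInMask(data.frame(x_um = 5, y_um = 5),
                            regionMask(matrix(FALSE, 2, 2), 10))
  expect_identical(as.integer(none), 0L)
  # track at the center of the true pixel (0, 0)
  hit <- countTracksInMask(data.frame(x_um = 0, y_um = 0), m)
  expect_identical(as.integer(hit), 1L)
  # outside the image: excluded and reported
  far <- countTracksInMask(data.frame(x_um = 1e4, y_um = 0), m)
  expect_identical(as.integer(far), 0L)
  expect_identical(attr(far, "nOutside"), 1L)

  # binomial check: uniform tracks over a half-true mask
  half <- regionMask(cbind(matrix(TRUE, 50, 25), matrix(FALSE, 50, 25)), 2)
  set.seed(29)
  n <- 1000
  tr <- data.frame(x_um = runif(n, -1, 99), y_um = runif(n, -1, 99))
  cnt <- as.integer(countTracksInMask(tr, half))
  expect_lt(abs(cnt - n / 2), 3 * sqrt(n * 0.25))
})

test_that("counting respects an affine detector-to-image transform", {
  m <- regionMask(matrix(TRUE, 10, 10), 10)   # image 0..100 um
  shift <- affineTransform(diag(2), c(-1000, -1000))
  tr <- data.frame(x_um = runif(20, 1000, 1090), y_um = runif(20, 1000, 1090))
  expect_identical(as.integer(countTracksInMask(tr, m, shift)), 20L)
  expect_identical(as.integer(countTracksInMask(tr, m)), 0L)
})

test_that("region densities carry Poisson errors", {
  d <- regionDensity(100, 1)
  expect_equal(trackDensity(d), 100)
  expect_equal(densitySigma(d), 10)
  d0 <- regionDensity(0, 2)
  expect_equal(trackDensity(d0), 0)
  expect_equal(densitySigma(d0), 0)
  # density / sigma = sqrt(count)
  d2 <- regionDensity(537, 0.73)
  expect_equal(trackDensity(d2) / densitySigma(d2), sqrt(537))
  expect_error(regionDensity(10, 0), "positive")
})

test_that("concentration efficiency reproduces the printed 6.0 +/- 0.2", {
  # reconstruct integer counts and areas from the printed densities
  # 1060.9 +/- 20.7 and 177.4 +/- 6.1 per mm^2 (sigma = sqrt(N)/A)
  nPink <- round((1060.9 / 20.7)^2)     # 2627
  nPurple <- round((177.4 / 6.1)^2)     # 846
  pink <- regionDensity(nPink, nPink / 1060.9)
  purple <- regionDensity(nPurple, nPurple / 177.4)
  ce <- concentrationEfficiency(pink, purple)
  expect_equal(round(ce$ratio, 1), 6.0)
  expect_equal(round(ce$sigma, 1), 0.2)

  # equal densities -> ratio 1
  eq <- concentrationEfficiency(regionDensity(400, 2), regionDensity(200, 1))
  expect_equal(eq$ratio, 1)
  expect_error(concentrationEfficiency(pink, regionDensity(0, 1)),
               "positive")
})

test_that("the propagated ratio error matches a Monte-Carlo oracle", {
  nP <- 2627L; nN <- 846L; aP <- 2.476; aN <- 4.769
  ce <- concentrationEfficiency(regionDensity(nP, aP),
                                regionDensity(nN, aN))
  set.seed(37)
  draws <- (rpois(1e5, nP) / aP) / (rpois(1e5, nN) / aN)
  expect_lt(abs(sd(draws) - ce$sigma) / ce$sigma, 0.05)
})
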
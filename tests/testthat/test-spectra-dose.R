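test_that("spectrum fluence is the 1/eta-weighted count density", {
  # no tracks -> all-zero spectrum
  s0 <- buildLetSpectrum(data.frame(let_keV_um = numeric(0),
                                    eta = numeric(0)), 1)
  expect_true(all(fluencePerBin(s0) == 0))

  # 10 tracks, eta = 0.5, one bin, 1 cm^2 -> phi = 20 cm^-2
  tr <- data.frame(let_keV_um = rep(132, 10), eta = rep(0.5, 10))
  s <- buildLetSpectrum(tr, 1)
  i <- findInterval(132, letBinEdges(s))
  expect_equal(fluencePerBin(s)[i], 20)
  expect_identical(rawCounts(s)[i], 10L)
  expect_equal(sum(fluencePerBin(s)), 20)

  # eta = 0 tracks must have been excluded upstream
  expect_error(buildLetSpectrum(data.frame(let_keV_um = 100, eta = 0), 1),
               "eta <= 0")
})

test_that("spectra are additive under track-list concatenation", {
  set.seed(21)
  tr <- data.frame(let_keV_um = runif(400, 3.5, 600),
                   eta = runif(400, 0.3, 0.99))
  half <- sample(nrow(tr), 200)
  sAll <- buildLetSpectrum(tr, 2.5)
  s1 <- buildLetSpectrum(tr[half, ], 2.5)
  s2 <- buildLetSpectrum(tr[-half, ], 2.5)
  expect_equal(fluencePerBin(sAll), fluencePerBin(s1) + fluencePerBin(s2),
               tolerance = 1e-12)
  expect_identical(rawCounts(sAll), rawCounts(s1) + rawCounts(s2))
})

test_that("absorbed dose follows the fluence-LET sum", {
  # phi = 1e9 cm^-2 in one bin at L = 1 keV/um, rho = 1 -> 1.6 Gy
  s <- new("LETSpectrum", binEdges = c(0.5, 1.5), fluence = 1e9,
           counts = 0L, areaCm2 = 1)
  expect_equal(absorbedDose(s), 1.6, tolerance = 1e-12)
  # empty spectrum -> 0 Gy
  s0 <- buildLetSpectrum(data.frame(let_keV_um = numeric(0),
                                    eta = numeric(0)), 1)
  expect_equal(absorbedDose(s0), 0)
  # one track of L = 130, eta = 1 on a 10 x 10 um cell -> 0.208 Gy
  tr <- data.frame(let_keV_um = 130, eta = 1)
  s1 <- buildLetSpectrum(tr, (10e-4)^2)
  expect_equal(absorbedDose(s1), 0.208, tolerance = 1e-9)
})

test_that("default LET bins center round values and cover 3.5-600", {
  e <- defaultLetBins()
  expect_equal(min(e), 3.5)
  expect_equal(max(e), 600)
  mids <- letBinMids(e)
  expect_true(130 %in% mids)   # the alpha peak sits at a bin center
  expect_true(all(diff(e) > 0))
})

test_that("dose maps bin correctly and keep the energy bookkeeping", {
  # single track of L = 130, eta = 1 -> its 10-um cell reads 0.208 Gy
  tr <- data.frame(x_um = 23, y_um = 57, let_keV_um = 130, weight = 1)
  m <- localDoseMap(tr, c(0, 0), c(100, 100), 10)
  expect_equal(doseValues(m)[6, 3], 0.208, tolerance = 1e-12)
  expect_equal(sum(doseValues(m) > 0), 1L)
  expect_identical(cellCounts(m)[6, 3], 1L)

  # empty track list -> zero map
  m0 <- localDoseMap(tr[0, ], c(0, 0), c(100, 100), 10)
  expect_true(all(doseValues(m0) == 0))

  # energy bookkeeping: sum(dose * A * rho / 1.6e-9) = sum(L * w)
  set.seed(5)
  n <- 3000
  trk <- data.frame(x_um = runif(n, 0, 500), y_um = runif(n, 0, 500),
                    let_keV_um = runif(n, 3.5, 600),
                    weight = 1 / runif(n, 0.3, 1))
  mm <- localDoseMap(trk, c(0, 0), c(500, 500), 10)
  aCell <- (10e-4)^2
  lhs <- sum(doseValues(mm)) * aCell / 1.6e-9
  expect_equal(lhs, sum(trk$let_keV_um * trk$weight), tolerance = 1e-9)

  # tracks on the upper cell edge go to the next cell; outside is counted
  edge <- data.frame(x_um = c(10, 501), y_um = c(0, 0), let_keV_um = 100,
                     weight = 1)
  me <- suppressMessages(localDoseMap(edge, c(0, 0), c(500, 500), 10))
  expect_identical(cellCounts(me)[1, 2], 1L)
  expect_identical(attr(me, "nOutside"), 1L)
})

test_that("density maps count tracks and shift with the grid", {
  one <- data.frame(x_um = 40, y_um = 90)
  d1 <- trackDensityMap(one, c(0, 0), c(1000, 1000))
  expect_identical(sum(densityCounts(d1)), 1L)

  set.seed(9)
  n <- 10000
  tr <- data.frame(x_um = runif(n, 0, 1000), y_um = runif(n, 0, 1000))
  d <- trackDensityMap(tr, c(0, 0), c(1000, 1000), 50)
  expect_identical(dim(densityCounts(d)), c(20L, 20L))   # 400 bins
  expect_identical(sum(densityCounts(d)), as.integer(n))
  # mean 25 per bin within 3 sigma of the Poisson expectation
  expect_lt(abs(mean(densityCounts(d)) - 25), 3 * sqrt(25 / 400))
  expect_lt(sum(abs(densityCounts(d) - 25) > 3 * sqrt(25)), 5)

  shifted <- tr
  shifted$x_um <- tr$x_um + 50
  ds <- suppressMessages(
    trackDensityMap(shifted, c(0, 0), c(1050, 1000), 50))
  expect_identical(densityCounts(ds)[, 2:21], densityCounts(d))
})

test_that("decay-window correction has the right value and limits", {
  expect_equal(decayCorrectionFactor(decayModel()), 2.290641,
               tolerance = 1e-6)
  # t1 -> 0: no pre-window decays
  expect_lt(decayCorrectionFactor(decayModel(7.2, 1e-9, 43)), 1e-8)
  # t1 = one half-life, t2 -> Inf: equal decays before and after
  expect_equal(decayCorrectionFactor(decayModel(7.2, 7.2, Inf)), 1,
               tolerance = 1e-12)
  expect_error(decayModel(7.2, 12, 12), "t1 < t2")
  # strictly increasing in t1, decreasing in t2
  f <- function(t1, t2) decayCorrectionFactor(decayModel(7.2, t1, t2))
  t1s <- seq(1, 40, by = 1)
  expect_true(all(diff(vapply(t1s, f, numeric(1), t2 = 43)) > 0))
  t2s <- seq(13, 80, by = 1)
  expect_true(all(diff(vapply(t2s, function(t2) f(12, t2), numeric(1))) < 0))
})

test_that("total dose scales observed dose by 1 + D0/D", {
  expect_equal(totalDose(1), 1 + 2.290641, tolerance = 1e-6)
  expect_equal(totalDose(0), 0)
  expect_equal(totalDose(3.5), 3.5 * totalDose(1))   # linearity
  tr <- data.frame(x_um = 5, y_um = 5, let_keV_um = 130, weight = 1)
  m <- localDoseMap(tr, c(0, 0), c(20, 20), 10)
  mt <- totalDose(m)
  expect_equal(doseValues(mt), doseValues(m) * (1 + 2.290641),
               tolerance = 1e-6)
  expect_identical(cellCounts(mt), cellCounts(m))
})

test_that("dose histograms summarize nonzero cells", {
  tr <- data.frame(x_um = 5, y_um = 5, let_keV_um = 130, weight = 1 / 0.1)
  m <- localDoseMap(tr, c(0, 0), c(50, 50), 10)   # single ~2.08 Gy cell
  h <- doseHistogram(m, 0.5)
  expect_identical(sum(h$counts), 1L)
  expect_true(h$breaks[which.max(h$counts)] <= 2.08 &&
              2.08 < h$breaks[which.max(h$counts) + 1])

  # histogram total = number of nonzero cells
  set.seed(31)
  n <- 2000
  trk <- data.frame(x_um = runif(n, 0, 500), y_um = runif(n, 0, 500),
                    let_keV_um = rnorm(n, 130, 20), weight = 1.2)
  mm <- localDoseMap(trk, c(0, 0), c(500, 500), 10)
  hh <- doseHistogram(mm, 0.5)
  expect_identical(sum(hh$counts), hh$nNonzero)
  expect_identical(hh$nNonzero, as.integer(sum(doseValues(mm) > 0)))

  # synthetic map from a known dose distribution: mode within one bin
  set.seed(32)
  grid <- matrix(0, 40, 40)
  grid[sample(1600, 1200)] <- pmax(rnorm(1200, 2, 0.3), 0.01)
  mk <- new("DoseMap", originUm = c(0, 0), cellSizeUm = 10, dose = grid,
            counts = matrix(0L, 40, 40))
  hm <- doseHistogram(mk, 0.25)
  expect_lt(abs(hm$modeGy - 2), 0.25 + 0.125)
})

test_that("grid maps and spectra survive disk round trips", {
  set.seed(41)
  tr <- data.frame(x_um = runif(200, 0, 300), y_um = runif(200, 0, 300),
                   let_keV_um = runif(200, 50, 300),
                   weight = 1 / runif(200, 0.5, 1))
  m <- localDoseMap(tr, c(0, 0), c(300, 300), 10)
  base <- file.path(withr::local_tempdir(), "map")
  writeGridMap(m, base)
  back <- readGridMap(base)
  expect_equal(doseValues(back), doseValues(m), tolerance = 1e-9)
  expect_identical(cellCounts(back), cellCounts(m))

  tr$eta <- 1 / tr$weight
  s <- buildLetSpectrum(tr, 0.5)
  sp <- file.path(withr::local_tempdir(), "spec.csv")
  writeSpectrum(s, sp)
  sb <- readSpectrum(sp)
  expect_equal(fluencePerBin(sb), fluencePerBin(s), tolerance = 1e-9)
  expect_identical(rawCounts(sb), rawCounts(s))
})
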
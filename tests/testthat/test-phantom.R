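test_that("rendered phantoms are recovered pixel-exactly by segmentation", {
  cfg <- smallPhantomConfig()
  ph <- generatePhantom(cfg)
  seg <- segmentTissue(ph$image, cfg@pixelSizeUm)
  for (nm in c("tissue", "pink", "purple"))
    expect_identical(maskValues(seg[[nm]]), maskValues(ph$masks[[nm]]),
                     label = nm)
  # zero-size tumor -> empty pink mask
  cfg0 <- smallPhantomConfig(
    tumorEllipses = matrix(numeric(0), 0, 4))
  ph0 <- generatePhantom(cfg0)
  expect_identical(sum(maskValues(ph0$masks$pink)), 0L)
  # geometry outside the image is rejected
  expect_error(
    phantomConfig(imageSizePx = c(100L, 100L), pixelSizeUm = 1,
                  tumorEllipses = matrix(c(90, 50, 30, 10), 1, 4)),
    "outside")
})

test_that("simulated decay counts and times follow the decay law", {
  cfg <- smallPhantomConfig(seed = 101L)
  ph <- generatePhantom(cfg)
  # zero activity -> no events
  cfg0 <- smallPhantomConfig(activityTumorPerMm2 = 0)
  expect_identical(nrow(simulateDecays(cfg0, generatePhantom(cfg0)$masks)),
                   0L)

  # over [0, Inf): fraction of decays inside [t1, t2] is
  # e^(-lambda t1) - e^(-lambda t2) = 0.299 for the defaults
  ev <- simulateDecays(cfg, ph$masks, windowH = c(0, Inf))
  n <- nrow(ev)
  expect_gt(n, 3000)
  lam <- decayConstant(cfg@decay)
  p <- exp(-lam * 12) - exp(-lam * 43)
  inWin <- mean(ev$decay_time_h >= 12 & ev$decay_time_h <= 43)
  expect_lt(abs(inWin - p), 3 * sqrt(p * (1 - p) / n))

  # positions stay inside their region masks
  pinkEv <- ev[ev$region == "pink", ]
  expect_true(all(tracksInMask(pinkEv, ph$masks$pink)))
})

test_that("angular acceptance reproduces the detection efficiency", {
  # fixed LET = 100 keV/um -> S = 1 -> eta = 0.75
  cfg <- smallPhantomConfig(seed = 7L, letMeanKeVUm = 100,
                            letSdKeVUm = 1e-6)
  ph <- generatePhantom(cfg)
  ev <- simulateDecays(cfg, ph$masks)
  n <- nrow(ev)
  expect_gt(n, 3000)
  expect_lt(abs(mean(ev$registered) - 0.75), 3 * sqrt(0.75 * 0.25 / n))
  # invariant: registered => dip angle above the critical angle
  thc <- criticalAngle(responseFromLet(ev$let_keV_um))
  expect_true(all(ev$dip_angle_rad[ev$registered] > thc[ev$registered]))
  expect_true(all(ev$dip_angle_rad > 0 & ev$dip_angle_rad <= pi / 2))
})

test_that("the forward pit model inverts the response geometry exactly", {
  etch <- etchConfig()
  # normal incidence at S = 2/3: circular pit d = 2B sqrt(S/(S+2)) = B
  L <- as.numeric(letFromResponse(2 / 3))
  ax <- forwardPitModel(L, pi / 2, etch)
  expect_equal(ax$major_axis_um, 3.3, tolerance = 1e-9)
  expect_equal(ax$minor_axis_um, 3.3, tolerance = 1e-9)

  # round trip: response of the modelled pit equals the response of the LET
  set.seed(43)
  L <- runif(100, 3.5, 600)
  S <- responseFromLet(L)
  thc <- criticalAngle(S)
  th <- thc + runif(100) * (pi / 2 - thc)
  axr <- forwardPitModel(L, th, etch)
  expect_equal(detectorResponse(axr$major_axis_um, axr$minor_axis_um, etch),
               S, tolerance = 1e-9)
  expect_true(all(axr$major_axis_um >= axr$minor_axis_um))
  expect_true(all(axr$minor_axis_um < 2 * 3.3))

  # grazing limit: just above the critical angle the minor axis vanishes
  g <- forwardPitModel(130, criticalAngle(responseFromLet(130)) + 1e-7,
                       etch)
  expect_lt(g$minor_axis_um, 0.01)
  expect_error(forwardPitModel(130, 0.1, etch), "critical")
})

test_that("truth bundles are deterministic and internally consistent", {
  cfg <- smallPhantomConfig(seed = 77L)
  d1 <- file.path(withr::local_tempdir(), "b1")
  d2 <- file.path(withr::local_tempdir(), "b2")
  b1 <- writeTruthBundle(cfg, d1)
  b2 <- writeTruthBundle(cfg, d2)
  # same seed -> byte-identical tables
  expect_identical(readLines(file.path(d1, "pits.csv")),
                   readLines(file.path(d2, "pits.csv")))
  expect_identical(readLines(file.path(d1, "events.csv")),
                   readLines(file.path(d2, "events.csv")))

  # recorded pit rows = angularly registered events inside [t1, t2]
  ev <- b1$events
  rec <- ev$registered & ev$decay_time_h >= 12 & ev$decay_time_h <= 43
  pits <- readTrackTable(file.path(d1, "pits.csv"))
  expect_identical(nrow(pits), sum(rec))

  # truth dose map equals an independent per-cell recount of L sums
  truth <- b1$truth
  obs <- truth$doseObserved
  evw <- ev[ev$decay_time_h >= 12 & ev$decay_time_h <= 43, ]
  cell <- cellSize(obs)
  ix <- floor(evw$x_um / cell) + 1
  iy <- floor(evw$y_um / cell) + 1
  keep <- ix >= 1 & ix <= ncol(doseValues(obs)) &
          iy >= 1 & iy <= nrow(doseValues(obs))
  recount <- tapply(evw$let_keV_um[keep],
                    (ix[keep] - 1) * nrow(doseValues(obs)) + iy[keep], sum)
  grid <- doseValues(obs) * (cell * 1e-4)^2 / 1.6e-9
  expect_equal(unname(grid[as.integer(names(recount))]),
               unname(as.numeric(recount)), tolerance = 1e-9)
  expect_identical(sum(cellCounts(obs)), nrow(evw))

  # counts-by-region table matches a direct recount
  expect_identical(truth$countsByRegion["pink", "recording"],
                   sum(evw$region == "pink"))
})

test_that("efficiency weighting recovers the true traversal fluence", {
  cfg <- smallPhantomConfig(seed = 55L)
  ph <- generatePhantom(cfg)
  ev <- simulateDecays(cfg, ph$masks)
  win <- ev[ev$decay_time_h >= 12 & ev$decay_time_h <= 43, ]
  reg <- win[win$registered, ]
  eta <- detectionEfficiency(responseFromLet(reg$let_keV_um))
  edges <- defaultLetBins()
  binAll <- findInterval(win$let_keV_um, edges, rightmost.closed = TRUE)
  binReg <- findInterval(reg$let_keV_um, edges, rightmost.closed = TRUE)
  for (b in unique(binAll)) {
    truthN <- sum(binAll == b)
    if (truthN < 50) next
    sel <- binReg == b
    recon <- sum(1 / eta[sel])
    etaBar <- mean(eta[sel])
    sdRecon <- sqrt(truthN * (1 - etaBar) / etaBar)
    expect_lt(abs(recon - truthN), 3 * sdRecon + 3)
  }
})

test_that("decay correction recovers the pre-mount dose", {
  cfg <- smallPhantomConfig(seed = 91L)
  ph <- generatePhantom(cfg)
  ev <- simulateDecays(cfg, ph$masks)
  pre <- ev$decay_time_h < 12
  rec <- ev$decay_time_h >= 12 & ev$decay_time_h <= 43
  sObs <- sum(ev$let_keV_um[rec])
  sPre <- sum(ev$let_keV_um[pre])
  f <- decayCorrectionFactor(cfg@decay)
  # predicted pre-mount LET sum vs simulated truth, within counting error
  sigma <- mean(ev$let_keV_um) * sqrt(sum(pre) + f^2 * sum(rec))
  expect_lt(abs(sPre - f * sObs), 3 * sigma)
  # map version: totalDose(observed truth map) ~ truth total map in sum
  truth <- phantomGroundTruth(ev, cfg)
  corrected <- totalDose(truth$doseObserved, cfg@decay)
  expect_lt(abs(sum(doseValues(corrected)) - sum(doseValues(truth$doseTotal))) /
            sum(doseValues(truth$doseTotal)), 0.05)
})
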
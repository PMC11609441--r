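test_that("scan durations follow the transient table", {
  expect_equal(scanDuration(60000, 0.250), 0.255)
  expect_equal(scanDuration(7500, 0.010), 0.021)
  expect_equal(scanDuration(120000, 0.050), 0.261)
  # monotone nondecreasing in both arguments
  res <- c(7500, 15000, 30000, 60000, 120000)
  expect_true(all(diff(vapply(res, scanDuration, numeric(1),
                              injectionTime = 0.001)) >= 0))
  expect_true(all(diff(vapply(c(0.01, 0.1, 0.3), function(it)
    scanDuration(60000, it), numeric(1))) >= 0))
  expect_warning(d <- scanDuration(50000, 0.01), "nearest|not in")
  expect_equal(d, scanDuration(60000, 0.01))
})

test_that("fragment matching is greedy-nearest with one use per centroid", {
  expect_equal(matchFragments(numeric(), c(500, 600), 20), 0L)
  mz <- c(400.1, 500.2, 600.3, 700.4, 800.5)
  expect_equal(matchFragments(mz, mz, 20), 5L)
  # off by more than tolerance
  expect_equal(matchFragments(mz * (1 + 50e-6), mz, 20), 0L)
  # one centroid equidistant between two expectations counts once
  exp2 <- c(1000.000, 1000.002)   # 2 ppm apart
  mid <- 1000.001
  expect_equal(matchFragments(mid, exp2, 20), 1L)
  # two centroids near one expectation still count once
  expect_equal(matchFragments(c(500.0000, 500.0001), 500, 20), 1L)
  expect_error(matchFragments(mz, mz, 0), "positive")
})

test_that("the trigger requires the configured number of product ions", {
  panel <- tinyPanel()
  for (k in 1:5) {
    sig <- kIonSignals(panel, k)
    run <- runSureQuant(sig, panel, seed = 1)
    sc <- runScans(run)
    nQuant <- sum(sc$kind == "QUANT_MS2")
    nWatch <- sum(sc$kind == "WATCH_MS2")
    expect_gt(nWatch, 0)
    expect_equal(max(sc$matchedFragments, na.rm = TRUE), k)
    if (k >= 3) expect_gt(nQuant, 0) else expect_equal(nQuant, 0)
  }
})

test_that("a silent heavy peptide is never watched or quantified", {
  panel <- tinyPanel()
  truth <- generateGroundTruth(panel, 2, 1, 5)
  prof <- elutionProfiles(panel, gradient100SPD())
  sig <- renderSignals(truth, panel, prof, 1, noiseCv = 0, floor = 0,
                       background = backgroundModel(0))
  mute <- sig@precursors$peptideId[sig@precursors$isHeavy][1]
  sig@precursors$amplitude[sig@precursors$peptideId == mute] <- 0
  run <- runSureQuant(sig, panel, seed = 1)
  sc <- runScans(run)
  expect_false(any(sc$targetId == mute, na.rm = TRUE))
  expect_false(any(sc$targetId == sub("/heavy$", "/light", mute),
                   na.rm = TRUE))
  # the other peptide is still acquired
  expect_gt(sum(sc$kind == "QUANT_MS2"), 0)
})

test_that("quant scans stay inside the elution support of the peak", {
  panel <- buildPanel(c(TNFA = "VNLLSAIKELTEAGQLFSSDR"),
                      peptidesPerProtein = 1L)
  truth <- generateGroundTruth(panel, 0, 1, 5)
  run <- cleanRun(panel, truth)
  sc <- runScans(run)
  q <- sc[sc$kind == "QUANT_MS2", ]
  apex <- elutionProfiles(panel, gradient100SPD())$apexRt[1]
  expect_gt(nrow(q), 0)
  expect_true(all(abs(q$time - apex) <= 15 + 0.3))
  # offset isolation: light center = heavy - delta/charge
  p <- panelPeptides(panel)
  hv <- p[p$isHeavy, ]
  expect_equal(unique(q$isolationMz),
               hv$precursorMz - hv$labelDelta / hv$charge, tolerance = 1e-9)
})

test_that("every quant scan follows a same-cycle watch scan over threshold", {
  panel <- defaultPanel()
  truth <- generateGroundTruth(panel, 4, 1, 8)
  run <- simulateRun(panel, truth, 1, seed = 8)
  sc <- runScans(run)
  params <- acquisitionParams()
  qs <- which(sc$kind == "QUANT_MS2")
  for (i in qs) {
    hid <- sub("/light$", "/heavy", sc$targetId[i])
    w <- which(sc$kind == "WATCH_MS2" & sc$targetId == hid &
                 sc$time < sc$time[i] &
                 sc$time > sc$time[i] - params@cyclePeriod)
    expect_true(length(w) >= 1)
    expect_true(any(sc$matchedFragments[w] >= params@triggerMinIons))
  }
})

test_that("scan schedule respects time ordering and the cycle budget", {
  panel <- defaultPanel()
  truth <- generateGroundTruth(panel, 4, 1, 8)
  run <- simulateRun(panel, truth, 1, seed = 8)
  sc <- runScans(run)
  expect_true(all(diff(sc$time) > 0))
  ms1 <- sc$time[sc$kind == "MS1"]
  params <- acquisitionParams()
  maxScan <- scanDuration(params@quantResolution, params@quantInjectionTime)
  expect_true(all(diff(ms1) <= params@cyclePeriod + maxScan + 1e-9))
})

test_that("scheduled PRM fires every cycle in-window and defers on contention", {
  panel1 <- buildPanel(c(TNFA = "VNLLSAIKELTEAGQLFSSDR"),
                       peptidesPerProtein = 1L)
  truth1 <- generateGroundTruth(panel1, 0, 1, 5)
  g <- gradient100SPD()
  win <- data.frame(targetId = panelPeptides(panel1)$targetId[1],
                    start = 0, end = activeLength(g))
  run <- cleanRun(panel1, truth1, mode = "prm", rtWindows = win)
  sc <- runScans(run)
  nCycles <- sum(sc$kind == "MS1")
  expect_equal(sum(sc$kind == "QUANT_MS2"), nCycles)
  # 18 fully overlapping windows exceed the budget: per-peptide rate drops
  panel <- defaultPanel()
  truth <- generateGroundTruth(panel, 2, 1, 5)
  prof <- elutionProfiles(panel, g)
  win18 <- data.frame(targetId = prof$targetId,
                      start = 200, end = 400)
  run18 <- cleanRun(panel, truth, mode = "prm", rtWindows = win18)
  sc18 <- runScans(run18)
  q18 <- sc18[sc18$kind == "QUANT_MS2", ]
  perPeptide <- table(q18$targetId)
  cyclesInWindow <- sum(sc18$time[sc18$kind == "MS1"] >= 200 &
                          sc18$time[sc18$kind == "MS1"] <= 400)
  expect_lt(max(perPeptide), cyclesInWindow)
})

test_that("run records round-trip through their CSV tables", {
  panel <- tinyPanel()
  truth <- generateGroundTruth(panel, 2, 1, 5)
  run <- cleanRun(panel, truth)
  prefix <- file.path(tempdir(), "run0")
  writeRunCsv(run, prefix)
  back <- readRunCsv(prefix)
  expect_equal(back@scans$time, run@scans$time)
  expect_equal(back@centroids$intensity, run@centroids$intensity)
  q1 <- quantifyRun(run, panel)
  q2 <- quantifyRun(back, panel)
  expect_equal(q1$totalArea, q2$totalArea)
})

test_that("acquired spectra honour isolation, noise and determinism", {
  panel <- tinyPanel()
  truth <- generateGroundTruth(panel, 2, 1, 5)
  prof <- elutionProfiles(panel, gradient100SPD())
  sig <- renderSignals(truth, panel, prof, 1, noiseCv = 0, floor = 0,
                       background = backgroundModel(0))
  pr <- sig@precursors
  i <- which(!pr$isHeavy)[1]
  t <- pr$apexRt[i]
  sp <- acquireQuantSpectrum(sig, pr$precursorMz[i], t)
  rows <- which(sig@transitions$peptideId == pr$peptideId[i])
  expect_equal(sort(sp$mz), sort(sig@transitions$mz[rows]))
  expect_equal(sp$intensity[order(sp$mz)],
               transitionIntensity(sig, rows, t)[order(sig@transitions$mz[rows])],
               tolerance = 1e-12)
  # heavy partner sits outside the isolation window
  expect_false(any(abs(sp$mz - pr$precursorMz[pr$isHeavy][1]) < 0.5))
  # with noise: same m/z, seed-dependent intensities
  sigN <- renderSignals(truth, panel, prof, 1, noiseCv = 0.05, floor = 0,
                        background = backgroundModel(0))
  a <- acquireQuantSpectrum(sigN, pr$precursorMz[i], t, seed = 1)
  b <- acquireQuantSpectrum(sigN, pr$precursorMz[i], t, seed = 2)
  expect_identical(a$mz, b$mz)
  expect_false(identical(a$intensity, b$intensity))
})
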
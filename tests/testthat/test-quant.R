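test_that("noiseless traces reproduce the rendered signal at scan times", {
  panel <- tinyPanel()
  truth <- generateGroundTruth(panel, 2, 1, 5)
  prof <- elutionProfiles(panel, gradient100SPD())
  sig <- renderSignals(truth, panel, prof, 1, noiseCv = 0, floor = 0,
                       background = backgroundModel(0))
  run <- runSureQuant(sig, panel, seed = 1)
  traces <- extractTraces(run, panel)
  lt <- traces[!traces$isHeavy & traces$targetId == prof$targetId[1], ]
  tr <- sig@transitions
  for (j in seq_len(nrow(lt))) {
    row <- which(tr$peptideId == lt$peptideId[j] &
                   tr$transitionId == lt$transitionId[j])
    expect_equal(lt$intensity[j],
                 transitionIntensity(sig, row, lt$time[j]),
                 tolerance = 1e-9)
  }
})

test_that("trace extraction respects the m/z tolerance", {
  panel <- tinyPanel()
  truth <- generateGroundTruth(panel, 2, 1, 5)
  run <- cleanRun(panel, truth)
  # shift every centroid by 100 ppm: nothing matches at 20 ppm
  shifted <- run
  shifted@centroids$mz <- shifted@centroids$mz * (1 + 100e-6)
  tr <- extractTraces(shifted, panel, tolPpm = 20)
  expect_true(all(tr$intensity == 0))
  # an interferent inside the tolerance is added to the trace
  run2 <- run
  q1 <- run2@scans$scanId[run2@scans$kind == "QUANT_MS2"][1]
  pid <- run2@scans$targetId[run2@scans$scanId == q1]
  tmz <- panelTransitions(panel)
  tmz <- tmz$mz[tmz$peptideId == pid][1]
  run2@centroids <- rbind(run2@centroids,
                          data.frame(scanId = q1, mz = tmz * (1 + 5e-6),
                                     intensity = 1000))
  t1 <- extractTraces(run, panel)
  t2 <- extractTraces(run2, panel)
  expect_equal(sum(t2$intensity) - sum(t1$intensity), 1000)
})

test_that("boundary detection matches the closed-form 5% width", {
  tm <- seq(0, 60, by = 2)
  tr <- data.frame(time = tm, intensity = peakIntensity(30, 3, 100, tm))
  b <- detectBoundaries(tr)
  expect_true(b$detected)
  # the sampled width loses up to one 2 s scan spacing on each side
  wTheory <- 2 * 3 * sqrt(2 * log(20))   # 14.68 s
  expect_lt(abs((b$end - b$start) - wTheory), 4.01)
  expect_true(b$start <= b$apexTime && b$apexTime <= b$end)
  expect_equal(b$apexTime, 30)
})

test_that("boundary detection handles edges, spikes and empty traces", {
  # apex at the run start: clipped, still detected
  tm <- seq(0, 30, by = 2)
  tr <- data.frame(time = tm, intensity = peakIntensity(0, 3, 100, tm))
  b <- detectBoundaries(tr)
  expect_true(b$detected)
  expect_equal(b$start, 0)
  # all-zero trace: not detected
  expect_false(detectBoundaries(
    data.frame(time = tm, intensity = 0))$detected)
  expect_false(detectBoundaries(
    data.frame(time = numeric(), intensity = numeric()))$detected)
  # a lone spike cannot displace a neighbour-supported apex
  tm2 <- seq(0, 60, by = 2)
  y <- peakIntensity(30, 3, 100, tm2)
  y[5] <- 1000   # isolated interferent at t = 8
  b2 <- detectBoundaries(data.frame(time = tm2, intensity = y))
  expect_equal(b2$apexTime, 30)
})

test_that("trapezoidal integration is exact on simple shapes", {
  tm <- seq(10, 20, by = 1)
  expect_equal(integrateTrace(tm, rep(4, 11), 10, 20), 40, tolerance = 1e-9)
  expect_equal(integrateTrace(tm, rep(4, 11), 30, 40), 0)
  expect_equal(integrateTrace(tm[1], 4, 0, 100), 0)   # single point
  expect_equal(integrateTrace(tm, 3 * rep(4, 11), 10, 20),
               3 * integrateTrace(tm, rep(4, 11), 10, 20))
})

test_that("TIC normalization is a median-anchored scale-invariant ratio", {
  expect_equal(ticNormalize(c(10, 20), c(100, 200)), c(15, 15))
  expect_equal(ticNormalize(c(7, 9), c(50, 50)), c(7, 9))
  # scaling one run's every intensity by k (areas and TIC alike) leaves
  # its normalized areas unchanged while the median anchor is untouched
  m <- matrix(c(10, 30, 20, 60, 40, 120), 2)
  n1 <- ticNormalize(m, c(100, 200, 400))
  m2 <- m; m2[, 3] <- m2[, 3] * 5
  n2 <- ticNormalize(m2, c(100, 200, 2000))
  expect_equal(n1, n2, tolerance = 1e-6)
  expect_error(ticNormalize(c(1, 2), c(10, 0)), "run")
})

test_that("protein rollup averages available peptides only", {
  expect_equal(proteinRollup(c(10, 20)), 15)
  expect_equal(proteinRollup(c(NA, 20)), 20)
  expect_true(is.na(proteinRollup(c(NA_real_, NA_real_))))
  v <- c(3, 9, 6)
  expect_true(proteinRollup(v) >= min(v) && proteinRollup(v) <= max(v))
})

test_that("0-100 rescaling is min-max per protein with missing preserved", {
  m <- rbind(A = c(5, 10, 15), B = c(2, NA, 4))
  r <- rescale0to100(m)
  expect_equal(unname(r["A", ]), c(0, 50, 100))
  expect_true(is.na(r["B", 2]))
  expect_equal(unname(r["B", c(1, 3)]), c(0, 100))
  expect_warning(rc <- rescale0to100(rbind(C = c(3, 3, 3))), "constant")
  expect_equal(unname(rc[1, ]), c(0, 0, 0))
  # fewer than 2 values: passthrough missing
  r1 <- rescale0to100(rbind(D = c(7, NA, NA)))
  expect_true(all(is.na(r1)))
})

test_that("integration boundaries are anchored on the internal standard", {
  panel <- tinyPanel()
  truth <- generateGroundTruth(panel, 2, 1, 5)
  run <- cleanRun(panel, truth)
  q1 <- quantifyRun(run, panel)
  # rescale the light amplitudes 100x: boundaries must not move
  truth2 <- truth
  truth2@concentrations$concentration <-
    truth@concentrations$concentration * 100
  run2 <- cleanRun(panel, truth2)
  q2 <- quantifyRun(run2, panel)
  expect_equal(q1$start, q2$start)
  expect_equal(q1$end, q2$end)
  expect_equal(q2$totalArea / q1$totalArea, rep(100, nrow(q1)),
               tolerance = 1e-6)
})

test_that("noiseless end-to-end recovery is rank-perfect within samples", {
  panel <- defaultPanel()
  truth <- generateGroundTruth(panel, 6, 2, 9)
  runs <- lapply(1:2, function(s)
    cleanRun(panel, truth, sample = s, runIndex = s - 1L))
  study <- quantifyStudy(runs, panel)
  for (s in 1:2) {
    tc <- truth@concentrations[truth@concentrations$sample == s, ]
    est <- study$proteinMatrix[tc$proteinId, s]
    expect_equal(cor(tc$concentration, est, method = "spearman"), 1)
  }
  # log2 matrices: no -Inf, correct shape
  cm <- completenessMatrix(study)
  expect_equal(dim(cm$peptideLog2), c(18, 2))
  expect_equal(dim(cm$proteinLog2), c(9, 2))
  expect_false(any(is.infinite(cm$peptideLog2), na.rm = TRUE))
})

test_that("undetected peptides propagate as missing, never zero", {
  panel <- tinyPanel()
  truth <- generateGroundTruth(panel, 2, 1, 5)
  prof <- elutionProfiles(panel, gradient100SPD())
  sig <- renderSignals(truth, panel, prof, 1, noiseCv = 0, floor = 0,
                       background = backgroundModel(0))
  mute <- sig@precursors$peptideId[sig@precursors$isHeavy][1]
  tgt <- sig@precursors$targetId[sig@precursors$peptideId == mute]
  sig@precursors$amplitude[sig@precursors$peptideId == mute] <- 0
  run <- runSureQuant(sig, panel, seed = 1)
  q <- quantifyRun(run, panel)
  expect_false(q$detected[q$targetId == tgt])
  expect_true(is.na(q$totalArea[q$targetId == tgt]))
})
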
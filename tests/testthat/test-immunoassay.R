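test_that("5PL fitting recovers exact synthetic curves", {
  truthFit <- toyCurve()
  conc <- 16 * 500 / 4^(0:6)
  y <- fivePLValue(truthFit, conc)
  fit <- fit5PL(conc, y)
  expect_equal(fit@a, 50, tolerance = 1e-4)
  expect_equal(fit@b, 1.2, tolerance = 1e-4)
  expect_equal(fit@c, 500, tolerance = 1e-4)
  expect_equal(fit@d, 30000, tolerance = 1e-4)
  expect_equal(fit@g, 0.8, tolerance = 1e-4)
})

test_that("5PL handles decreasing orientation and rejects thin designs", {
  dec <- fivePL(a = 30000, b = 1.1, c = 200, d = 40, g = 1.2)
  conc <- 3200 / 4^(0:6)
  fit <- fit5PL(conc, fivePLValue(dec, conc))
  expect_equal(fivePLInverse(fit, fivePLValue(dec, 150)), 150,
               tolerance = 1e-3)
  expect_error(fit5PL(c(1, 10, 100, 1000), c(1, 2, 3, 4)), "at least 5")
  expect_error(fit5PL(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 6)), "decade")
})

test_that("back-calculation inverts the curve and applies dilution", {
  fit <- toyCurve()
  y <- fivePLValue(fit, 432.1)
  bc <- backCalculate(y, fit)
  expect_equal(bc$concentration, 432.1, tolerance = 1e-9)
  expect_equal(bc$censored, "ok")
  bc50 <- backCalculate(y, fit, dilutionFactor = 50)
  expect_equal(bc50$concentration, 50 * 432.1, tolerance = 1e-9)
  hi <- backCalculate(30001, fit)
  expect_true(is.na(hi$concentration))
  expect_equal(hi$censored, "high")
  lo <- backCalculate(49, fit)
  expect_equal(lo$censored, "low")
})

test_that("standard exclusion rules reproduce hand-worked decisions", {
  fit <- toyCurve()
  conc <- 16 * 500 / 4^(0:6)
  st <- data.frame(concentration = conc,
                   netMfi = fivePLValue(fit, conc),
                   cv = rep(2, 7))
  # clean plate: everything survives
  v0 <- validateStandards(st)
  expect_true(v0$valid)
  expect_equal(sum(v0$standards$excluded), 0)
  expect_true(all(abs(v0$recovery - 100) < 1, na.rm = TRUE))
  # top standard within 8% of its neighbour: flattening
  st1 <- st
  st1$netMfi[1] <- st1$netMfi[2] * 1.08
  v1 <- validateStandards(st1)
  expect_true(v1$standards$excluded[1])
  expect_match(v1$standards$reason[1], "flattening")
  # replicate CV 12%: poor replication
  st2 <- st
  st2$cv[4] <- 12
  v2 <- validateStandards(st2)
  expect_true(v2$standards$excluded[4])
  expect_match(v2$standards$reason[4], "replication")
  # a standard reading far off nominal: poor model fit. A denser series
  # is needed for a lone outlier to be identifiable against the flexible
  # five-parameter curve; on the 1:2 series the top standard also
  # flattens by the <10% neighbour rule.
  conc11 <- 16 * 500 / 2^(0:10)
  st3 <- data.frame(concentration = conc11,
                    netMfi = fivePLValue(fit, conc11), cv = 2)
  st3$netMfi[6] <- fivePLValue(fit, 0.6 * conc11[6])
  v3 <- validateStandards(st3)
  expect_true(v3$valid)
  expect_true(v3$standards$excluded[1])
  expect_match(v3$standards$reason[1], "flattening")
  expect_true(v3$standards$excluded[6])
  expect_match(v3$standards$reason[6], "model fit")
  # losing too many standards invalidates the curve
  st4 <- st
  st4$cv[1:3] <- 15
  expect_false(validateStandards(st4)$valid)
})

test_that("sample validation applies the CV and range rules", {
  fit <- toyCurve()
  conc <- 16 * 500 / 4^(0:6)
  curve <- validateStandards(
    data.frame(concentration = conc, netMfi = fivePLValue(fit, conc),
               cv = 2))
  mk <- function(m1, m2) data.frame(sampleId = 1, dilution = 1,
                                    mfi1 = m1, mfi2 = m2)
  keep <- validateSamples(mk(5000, 5050), curve)   # CV ~ 0.7%
  expect_true(keep$kept)
  expect_lt(keep$cv, 1)
  dropCv <- validateSamples(mk(5000, 7000), curve) # CV ~ 23.6%
  expect_false(dropCv$kept)
  expect_match(dropCv$flag, "replication")
  # one replicate outside the standard range: singleton kept with flag
  single <- validateSamples(mk(5000, 31000), curve)
  expect_true(single$kept)
  expect_match(single$flag, "singleton")
  both <- validateSamples(mk(31000, 32000), curve)
  expect_false(both$kept)
})

test_that("plate simulation round-trips concentrations", {
  fit <- toyCurve()
  tc <- list(TNFA = c(143, 800))
  plate0 <- simulatePlate(tc, list(TNFA = fit), noiseCv = 0, background = 0,
                          dilutions = 1, seed = 2)
  y <- plate0$samples$mfi1
  bc <- backCalculate(y, fit)
  expect_equal(bc$concentration, c(143, 800), tolerance = 1e-6)
  # determinism and analyte coverage on the specificity-test fixture
  tcs <- as.list(specificityTestConcentrations())
  curves <- lapply(tcs, function(z) fivePL(a = 50, b = 1.2, c = z / 50,
                                           d = 30000, g = 0.8))
  p1 <- simulatePlate(tcs, curves, seed = 5)
  p2 <- simulatePlate(tcs, curves, seed = 5)
  expect_identical(p1, p2)
  expect_equal(length(unique(p1$standards$analyte)), 8)
  # a curve-less analyte (no reference standard) yields no standards
  curves$TNFA <- NULL
  p3 <- simulatePlate(tcs, curves, seed = 5)
  expect_false("TNFA" %in% p3$standards$analyte)
  expect_true("TNFA" %in% p3$samples$analyte)
})

test_that("round-trip recovery stays within 5% at 2% noise", {
  fit <- toyCurve()
  conc <- 16 * 500 / 4^(0:6)
  # in-range = the standards away from the two asymptote ends, where the
  # curve is responsive and back-calculation is well conditioned
  set.seed(31)
  errs <- replicate(30, {
    noisy <- fivePLValue(fit, conc) *
      rlnorm(7, -0.5 * log(1 + 0.02^2), sqrt(log(1 + 0.02^2)))
    refit <- fit5PL(conc, noisy)
    back <- fivePLInverse(refit, noisy[3:6])
    max(abs(back / conc[3:6] - 1))
  })
  expect_lt(mean(errs), 0.05)
  expect_lt(median(errs), 0.05)
})

test_that("a 42-sample multiplex plate reproduces a 6-order spread", {
  # eight analytes whose median concentrations span six orders; each has
  # its own calibration curve centred so the 1:500 dilution reads
  # mid-curve, as kit assays are designed
  medians <- setNames(10^seq(2, 8, length.out = 8), paste0("A", 1:8))
  set.seed(17)
  trueConc <- lapply(medians, function(m)
    m * rlnorm(42, 0, 0.25))
  curves <- lapply(medians, function(m)
    fivePL(a = 50, b = 1.2, c = m / 500, d = 30000, g = 0.8))
  plate <- simulatePlate(trueConc, curves, noiseCv = 0.02,
                         background = 50, seed = 17)
  recovered <- vapply(names(medians), function(an) {
    st <- plate$standards[plate$standards$analyte == an, ]
    tab <- standardTable(st$concentration,
                         as.matrix(st[c("mfi1", "mfi2", "mfi3")]),
                         plate$background)
    curve <- validateStandards(tab)
    expect_true(curve$valid)
    wells <- plate$samples[plate$samples$analyte == an, ]
    wells$mfi1 <- wells$mfi1 - plate$background
    wells$mfi2 <- wells$mfi2 - plate$background
    res <- validateSamples(wells, curve)
    kept <- res[res$kept & !is.na(res$concentration), ]
    expect_gt(nrow(kept), 0)
    median(kept$concentration)
  }, numeric(1))
  expect_gte(log10(max(recovered) / min(recovered)), 5.9)
})
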
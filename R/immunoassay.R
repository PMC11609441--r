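# Multiplex immunoassay calibration math: five-parameter logistic
# standard curves, the standard/sample exclusion rules, dilution-
# corrected back-calculation, and a plate simulator for testing.

#' FivePL class
#'
#' Five-parameter logistic calibration curve
#' y = d + (a - d) / (1 + (x / c)^b)^g relating analyte concentration x
#' (pg/ml) to net median fluorescence intensity y. `a` is the asymptote
#' at zero concentration, `d` the asymptote at infinity, `c` the
#' inflection concentration, `b` the slope and `g` the asymmetry. For
#' b * g != 0 the curve is strictly monotone.
#'
#' @slot a,b,c,d,g Curve parameters; `c > 0`.
#' @export
setClass("FivePL",
         representation(a = "numeric", b = "numeric", c = "numeric",
                        d = "numeric", g = "numeric"))

setValidity("FivePL", function(object) {
  v <- c(object@a, object@b, object@c, object@d, object@g)
  if (any(!is.finite(v))) return("all parameters must be finite")
  if (object@c <= 0) return("inflection concentration c must be positive")
  if (object@g <= 0) return("asymmetry g must be positive")
  TRUE
})

#' @describeIn FivePL constructor
#' @param a,b,c,d,g Curve parameters.
#' @export
fivePL <- function(a, b, c, d, g)
  new("FivePL", a = a, b = b, c = c, d = d, g = g)

setMethod("show", "FivePL", function(object) {
  cat(sprintf("FivePL: a=%.4g b=%.4g c=%.4g d=%.4g g=%.4g\n",
              object@a, object@b, object@c, object@d, object@g))
})

#' Evaluate a 5PL curve
#'
#' @param fit A [FivePL-class].
#' @param conc Concentrations (pg/ml); vectorised.
#' @return Predicted net MFI.
#' @export
fivePLValue <- function(fit, conc)
  fit@d + (fit@a - fit@d) / (1 + (conc / fit@c)^fit@b)^fit@g

#' Analytic inverse of a 5PL curve
#'
#' @param fit A [FivePL-class].
#' @param y Net MFI values strictly between the asymptotes.
#' @return Concentration (pg/ml); NA outside the asymptote range.
#' @export
fivePLInverse <- function(fit, y) {
  lo <- min(fit@a, fit@d); hi <- max(fit@a, fit@d)
  r <- ((fit@a - fit@d) / (y - fit@d))^(1 / fit@g) - 1
  x <- fit@c * r^(1 / fit@b)
  x[y <= lo | y >= hi] <- NA_real_
  x
}

#' Fit a 5PL standard curve
#'
#' Levenberg-Marquardt least squares of net MFI on concentration, with
#'1/y^2 (relative-error) weighting as is standard for immunoassay
#' calibration, and the inflection fitted on the log-concentration axis
#' for conditioning. The initializer is deterministic: a = response at
#' the lowest concentration, d = response at the highest, c = geometric
#' mid of the concentration range, b = 1 (sign chosen by data
#' orientation), g = 1.
#'
#' @param concentration Standard concentrations (pg/ml), >= 5 points
#'   spanning more than one decade.
#' @param netMfi Net MFI per standard.
#' @return A [FivePL-class].
#' @export
fit5PL <- function(concentration, netMfi) {
  ok <- is.finite(concentration) & is.finite(netMfi) & concentration > 0
  x <- concentration[ok]; y <- netMfi[ok]
  if (length(x) < 5) stop("need at least 5 valid standards, got ", length(x))
  if (max(x) / min(x) <= 10)
    stop("standards must span more than one decade of concentration")
  o <- order(x)
  a0 <- y[o][1]; d0 <- y[o][length(y)]
  b0 <- if (d0 >= a0) 1 else 1   # b and the a/d ordering jointly set orientation
  start <- list(a = a0, d = d0, logc = mean(log(range(x))), b = b0, logg = 0)
  w <- 1 / pmax(abs(y), 1e-6 * max(abs(y)))^2
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ d + (a - d) / (1 + (x / exp(logc))^b)^exp(logg),
      start = start, weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12)),
    error = function(e) stop("5PL fit failed to converge: ",
                             conditionMessage(e), "; residual range of ",
                             "linear start: ",
                             paste(signif(range(y - mean(y)), 3),
                                   collapse = " to ")))
  cf <- coef(fit)
  fivePL(a = unname(cf["a"]), b = unname(cf["b"]), c = exp(unname(cf["logc"])),
         d = unname(cf["d"]), g = exp(unname(cf["logg"])))
}

#' Summarise standard wells into net MFI and replicate CV
#'
#' @param concentration Nominal concentration per standard.
#' @param mfi Matrix of replicate raw MFIs (standards x replicates).
#' @param background Mean background-well MFI to subtract.
#' @return data.frame: `concentration`, `netMfi` (background-subtracted
#'   replicate mean), `cv` (percent CV of the net replicates).
#' @export
standardTable <- function(concentration, mfi, background = 0) {
  net <- mfi - background
  data.frame(concentration = concentration,
             netMfi = rowMeans(net),
             cv = apply(net, 1, function(v) 100 * sd(v) / mean(v)))
}

#' Apply the standard-curve validation rules
#'
#' The three published exclusion rules, applied in the documented order
#' with a refit after any removal:
#' \enumerate{
#'   \item replication: standards with replicate CV > 10 % are removed;
#'   \item flattening: if the highest (lowest) standard's net MFI is
#'     less than 10 % higher (lower) than its nearest neighbour, it is
#'     removed; repeated until both ends are distinct;
#'   \item fit + recovery: a 5PL is fitted to the survivors and any
#'     standard whose back-calculated recovery falls outside 80-120 %
#'     of nominal is removed, refitting until stable.
#' }
#' If fewer than 5 standards survive, the curve is invalid.
#'
#' @param standards data.frame from [standardTable()].
#' @return list: `valid`, `fit` ([FivePL-class] or NULL), `standards`
#'   (input plus `excluded` and `reason` columns), `recovery` (percent,
#'   NA for excluded standards).
#' @export
validateStandards <- function(standards) {
  st <- standards
  st$excluded <- FALSE
  st$reason <- ""
  drop <- function(st, i, why) {
    st$excluded[i] <- TRUE
    st$reason[i] <- why
    st
  }
  # rule 1: replication
  bad <- which(!st$excluded & st$cv > 10)
  for (i in bad) st <- drop(st, i, "poor replication (CV > 10%)")
  # rule 2: flattening at the curve ends
  repeat {
    alive <- which(!st$excluded)
    if (length(alive) < 2) break
    o <- alive[order(st$concentration[alive])]
    top <- o[length(o)]; nxt <- o[length(o) - 1]
    bot <- o[1]; above <- o[2]
    removed <- FALSE
    if (abs(st$netMfi[top] - st$netMfi[nxt]) < 0.10 * abs(st$netMfi[nxt])) {
      st <- drop(st, top, "flattening (top)")
      removed <- TRUE
    }
    alive <- which(!st$excluded)
    if (bot %in% alive && above %in% alive &&
        abs(st$netMfi[bot] - st$netMfi[above]) < 0.10 * abs(st$netMfi[bot])) {
      st <- drop(st, bot, "flattening (bottom)")
      removed <- TRUE
    }
    if (!removed) break
  }
  # rule 3: fit, recovery, refit until stable
  st$recovery <- NA_real_
  fit <- NULL
  repeat {
    alive <- which(!st$excluded)
    if (length(alive) < 5)
      return(list(valid = FALSE, fit = NULL, standards = st,
                  recovery = st$recovery))
    fit <- fit5PL(st$concentration[alive], st$netMfi[alive])
    back <- fivePLInverse(fit, st$netMfi[alive])
    rec <- 100 * back / st$concentration[alive]
    st$recovery[alive] <- rec
    bad <- alive[!is.na(rec) & (rec < 80 | rec > 120)]
    if (!length(bad)) break
    for (i in bad) st <- drop(st, i, "poor model fit (recovery outside 80-120%)")
  }
  list(valid = TRUE, fit = fit, standards = st, recovery = st$recovery)
}

#' Back-calculate a concentration from net MFI
#'
#' Analytic 5PL inverse times the dilution factor. Net MFIs outside the
#' open asymptote range cannot be inverted and are censored with a side
#' indicator.
#'
#' @param netMfi Net MFI values; vectorised.
#' @param fit A [FivePL-class].
#' @param dilutionFactor Dilution factor applied to the well (default 1).
#' @return data.frame: `concentration` (pg/ml, NA when censored),
#'   `censored` ("ok", "low" or "high" relative to the curve).
#' @export
backCalculate <- function(netMfi, fit, dilutionFactor = 1) {
  conc <- fivePLInverse(fit, netMfi) * dilutionFactor
  lowEnd <- fivePLValue(fit, 0)           # response at zero concentration
  side <- rep("ok", length(netMfi))
  lo <- min(fit@a, fit@d); hi <- max(fit@a, fit@d)
  out <- netMfi <= lo | netMfi >= hi
  increasing <- fit@d > fit@a
  side[out] <- ifelse((netMfi[out] <= lo) == increasing, "low", "high")
  conc[out] <- NA_real_
  data.frame(concentration = conc, censored = side)
}

#' Validate and back-calculate sample wells
#'
#' Duplicate sample measurements are removed when their replicate CV
#' exceeds 10 %; wells whose net MFI falls outside the valid standards'
#' net MFI range are censored (range-based reading of the published
#' rule, recorded in the output); a singleton whose partner was
#' censored is kept and flagged.
#'
#' @param wells data.frame: `sampleId`, `dilution`, and replicate net
#'   MFIs `mfi1`, `mfi2`.
#' @param curve Result of [validateStandards()].
#' @return data.frame: `sampleId`, `dilution`, `netMfi`, `cv`, `kept`,
#'   `flag`, `concentration` (dilution-corrected pg/ml, NA when
#'   censored/removed).
#' @export
validateSamples <- function(wells, curve) {
  if (!curve$valid) stop("standard curve is invalid; cannot quantify samples")
  alive <- !curve$standards$excluded
  rng <- range(curve$standards$netMfi[alive])
  out <- wells[c("sampleId", "dilution")]
  reps <- as.matrix(wells[c("mfi1", "mfi2")])
  inRange <- reps > rng[1] & reps < rng[2]
  netMfi <- cv <- numeric(nrow(wells))
  kept <- logical(nrow(wells))
  flag <- character(nrow(wells))
  for (i in seq_len(nrow(wells))) {
    v <- reps[i, inRange[i, ]]
    if (length(v) == 0) {
      kept[i] <- FALSE; flag[i] <- "both replicates outside standard range"
      netMfi[i] <- NA; cv[i] <- NA
    } else if (length(v) == 1) {
      kept[i] <- TRUE; flag[i] <- "singleton (partner censored)"
      netMfi[i] <- v; cv[i] <- NA
    } else {
      cv[i] <- 100 * sd(v) / mean(v)
      netMfi[i] <- mean(v)
      if (cv[i] > 10) {
        kept[i] <- FALSE; flag[i] <- "poor replication (CV > 10%)"
      } else kept[i] <- TRUE
    }
  }
  out$netMfi <- netMfi
  out$cv <- cv
  out$kept <- kept
  out$flag <- flag
  out$concentration <- NA_real_
  if (any(kept)) {
    bc <- backCalculate(netMfi[kept], curve$fit, 1)
    out$concentration[kept] <- bc$concentration * out$dilution[kept]
  }
  out
}

#' Simulate a multiplex immunoassay plate
#'
#' Renders standards (7-point series, triplicate) and samples
#' (duplicate, at the default 1:50 / 1:500 / 1:10000 dilutions) through
#' per-analyte true 5PL curves with multiplicative lognormal noise plus
#' an additive background. An analyte whose entry in `truthCurves` is
#' NULL is rendered without standards, mirroring an analyte shipped
#' without a reference standard.
#'
#' @param trueConc Named list (per analyte) of numeric vectors: true
#'   sample concentrations (pg/ml), one per sample.
#' @param truthCurves Named list (per analyte) of [FivePL-class] (or
#'   NULL for a curve-less analyte).
#' @param standardTop Named numeric: top standard concentration per
#'   analyte (default 4^6 times a bottom of 1 pg/ml scaled per curve
#'   inflection: top = 16 * c).
#' @param noiseCv Multiplicative MFI noise CV (default 0.02).
#' @param background Additive background MFI (default 50).
#' @param dilutions Sample dilution factors.
#' @param seed Integer seed.
#' @return list with `standards` (analyte, concentration, replicate MFI
#'   matrix columns mfi1..mfi3), `samples` (analyte, sampleId, dilution,
#'   mfi1, mfi2), `background`.
#' @export
simulatePlate <- function(trueConc, truthCurves, standardTop = NULL,
                          noiseCv = 0.02, background = 50,
                          dilutions = c(50, 500, 10000), seed = 1L) {
  analytes <- names(trueConc)
  .withSeed(.subSeed(seed, "plate"), {
    stdL <- list(); smpL <- list()
    for (an in analytes) {
      fit <- truthCurves[[an]]
      sdl <- .noiseSdlog(noiseCv)
      noisy <- function(v) v * rlnorm(length(v), -sdl^2 / 2, sdl) + background
      if (!is.null(fit)) {
        top <- if (!is.null(standardTop[[an]])) standardTop[[an]] else
          16 * fit@c
        conc <- top / 4^(0:6)   # 7-point 1:4 series
        y <- fivePLValue(fit, conc)
        stdL[[an]] <- data.frame(analyte = an, concentration = conc,
                                 mfi1 = noisy(y), mfi2 = noisy(y),
                                 mfi3 = noisy(y))
      }
      for (s in seq_along(trueConc[[an]])) {
        diluted <- trueConc[[an]][s] / dilutions
        resp <- if (is.null(fit)) rep(NA_real_, length(diluted)) else
          fivePLValue(fit, diluted)
        smpL[[length(smpL) + 1L]] <- data.frame(
          analyte = an, sampleId = s, dilution = dilutions,
          mfi1 = noisy(resp), mfi2 = noisy(resp))
      }
    }
    list(standards = do.call(rbind, c(stdL, list(make.row.names = FALSE))),
         samples = do.call(rbind, c(smpL, list(make.row.names = FALSE))),
         background = background)
  })
}

#' Published target concentrations for the specificity-test biomarkers
#'
#' The eight recombinant-biomarker target concentrations (pg/ml) used as
#' plate-simulation fixtures: COL1A1 260, FN1 59100, IL1B 316, MMP2
#' 5416, MMP9 2108, S100A8 1205, S100A9 426, TNFA 143. ELNE had no
#' reference standard and is absent.
#'
#' @return Named numeric vector of concentrations (pg/ml).
#' @export
specificityTestConcentrations <- function() {
  c(COL1A1 = 260, FN1 = 59100, IL1B = 316, MMP2 = 5416,
    MMP9 = 2108, S100A8 = 1205, S100A9 = 426, TNFA = 143)
}
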
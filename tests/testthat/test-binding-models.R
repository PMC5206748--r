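test_that("zero enthalpy gives zero heats (plus noise only)", {
  exp0 <- simulateItc(1, 1e7, dH = 0)
  expect_true(all(exp0@heats == 0))
  expN <- simulateItc(1, 1e7, dH = 0, noiseSd = 0.5, seed = 41)
  expect_false(all(expN@heats == 0))
  expect_lt(max(abs(expN@heats)), 5 * 0.5 + 1)
})

test_that("very tight binding yields a step isotherm at the stoichiometry", {
  exp <- simulateItc(1, 1e12, -1e4)
  ratio <- molarRatio(exp)
  perMol <- exp@heats / (exp@syringeConc * exp@injectionVolumes * 1e6)
  # before the equivalence point each injected mole releases ~dH
  expect_equal(stats::median(perMol[ratio < 0.8]), -1e4, tolerance = 0.01)
  # well past it, almost nothing
  expect_lt(max(abs(perMol[ratio > 1.3])), 0.05 * 1e4)
})

test_that("cumulative heat is monotone and saturates at n dH Mt V0", {
  # concentrated syringe keeps the dilution correction negligible, so the
  # saturation limit is clean; c-value = K*Mt = 2e4 >> 1e3
  layout <- itcLayout(syringeConc = 1e-2, nInjections = 25,
                      injectionVolume = 0.2e-6)
  for (dH in c(-1e4, 8e3)) {
    exp <- simulateItc(1.2, 1e9, dH, layout)
    Q <- cumsum(exp@heats)
    # monotone up to the (tiny) displaced-volume bookkeeping term
    expect_true(all(diff(Q) * sign(dH) >= -1e-3))
    totalExpected <- 1.2 * dH * layout$cellConc * layout$cellVolume * 1e6
    expect_equal(Q[length(Q)], totalExpected, tolerance = 0.01)
  }
})

test_that("the fitter recovers noiseless parameters to machine-level accuracy", {
  fit <- fitItc(simulateItc(1.5, 1e8, -1e4))
  expect_equal(fit@n, 1.5, tolerance = 1e-3)
  expect_equal(fit@K, 1e8, tolerance = 1e-3)
  expect_equal(fit@dH, -1e4, tolerance = 1e-3)
  expect_lt(sqrt(mean(fit@residuals^2)), 1e-6)
})

test_that("ITC fit reports standard errors, residuals and a molar-ratio axis", {
  fit <- fitItc(simulateItc(1.0, 1e7, -8e3, noiseSd = 0.2, seed = 42))
  expect_true(all(is.finite(fit@stderr[c("n", "K", "dH")])))
  expect_identical(length(fit@residuals), 24L)   # first injection excluded
  expect_identical(length(fit@molarRatio), 24L)
  expect_true(all(diff(fit@molarRatio) > 0))
  expect_error(fitItc(simulateItc(1, 1e7, -1e4, itcLayout(nInjections = 5))),
               "at least 8")
})

test_that("stoichiometry 0.75 and 1.5 isotherms are cleanly discriminated", {
  nsd <- 0.01 * max(abs(simulateItc(1.5, 1e8, -1e4)@heats))
  nHat075 <- vapply(1:10, function(s)
    fitItc(simulateItc(0.75, 1e8, -1e4, noiseSd = nsd, seed = s))@n,
    numeric(1))
  nHat150 <- vapply(1:10, function(s)
    fitItc(simulateItc(1.5, 1e8, -1e4, noiseSd = nsd, seed = 100 + s))@n,
    numeric(1))
  expect_true(all(nHat075 > 0.65 & nHat075 < 0.85))
  expect_true(all(nHat150 > 1.4 & nHat150 < 1.6))
  expect_gt(min(nHat150) - max(nHat075), 0.5)
})

test_that("zero analyte concentration gives a flat zero sensorgram", {
  exp <- simulateSensorgram(1e6, 1e-3, 100, concentrations = c(0, 1e-9))
  df <- exp@data
  expect_true(all(df$response[df$concentration == 0] == 0))
})

test_that("association plateaus at the Langmuir limit C Rmax / (C + KD)", {
  kon <- 1e6; koff <- 1e-3; Rmax <- 100; KD <- koff / kon
  exp <- simulateSensorgram(kon, koff, Rmax, concentrations = c(KD, 10 * KD),
                            associationTime = 30000, dissociationTime = 10,
                            dt = 100)
  df <- exp@data
  endOf <- function(C) {
    sub <- df[df$concentration == C & df$phase == "association", ]
    sub$response[which.max(sub$time)]
  }
  expect_equal(endOf(KD), Rmax / 2, tolerance = 1e-6)        # half saturation
  expect_equal(endOf(10 * KD), 10 * KD * Rmax / (10 * KD + KD),
               tolerance = 1e-6)
})

test_that("global SPR fit recovers noiseless kinetics to machine-level accuracy", {
  fit <- fitSprGlobal(simulateSensorgram(1e6, 1e-3, 100))
  expect_equal(fit@kon, 1e6, tolerance = 1e-3)
  expect_equal(fit@koff, 1e-3, tolerance = 1e-3)
  expect_equal(fit@KD, 1e-9, tolerance = 1e-3)
  expect_equal(fit@KD, fit@koff / fit@kon, tolerance = 1e-12)
  expect_lt(sqrt(mean(fit@residuals^2)), 1e-6)
})

test_that("fitted KD is invariant to doubling Rmax with rescaled data", {
  f1 <- fitSprGlobal(simulateSensorgram(1e6, 1e-3, 100, noiseSd = 0.5,
                                        seed = 43))
  e2 <- simulateSensorgram(1e6, 1e-3, 200, noiseSd = 0.5, seed = 43)
  f2 <- fitSprGlobal(e2)
  expect_lt(abs(f2@KD - f1@KD) / f1@KD, 0.01)
  expect_equal(f2@Rmax / f1@Rmax, 2, tolerance = 0.02)
})

test_that("a single-concentration series refuses a global fit", {
  exp <- simulateSensorgram(1e6, 1e-3, 100, concentrations = 5e-9)
  expect_error(fitSprGlobal(exp), "at least 2")
})

test_that("ITC and SPR file round trips preserve the experiments", {
  dir <- file.path(withr::local_tempdir(), "itc")
  itc <- makeItcFixture(dir, n = 1.2, K = 5e7, dH = -9e3, noiseSd = 0.1,
                        seed = 44)
  back <- readItcExperiment(itc$paths["heats"], itc$paths["header"])
  expect_equal(back@heats, itc$experiment@heats, tolerance = 1e-9)
  expect_equal(back@cellConc, itc$experiment@cellConc)
  spr <- makeSprFixture(file.path(dirname(dir), "spr"), noiseSd = 0.2,
                        seed = 45)
  back2 <- readSprCsv(spr$paths["sensorgrams"])
  expect_equal(back2@data$response, spr$experiment@data$response,
               tolerance = 1e-9)
  expect_equal(back2@associationTime, 120)
  gt <- readGroundTruth(itc$paths["groundTruth"])
  expect_equal(gt$n, 1.2)
})
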
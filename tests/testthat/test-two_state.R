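test_that("baselines of an ideal sigmoid are the exact plateau levels", {
  cv <- idealCurve(fLow = 100, fHigh = 1100)
  b <- estimateBaselines(cv)
  expect_identical(fitFlag(b), "ok")
  expect_equal(b@fMin, 100, tolerance = 1e-6)
  expect_equal(b@fMax, 1100, tolerance = 1e-6)
})

test_that("baselines on noisy generator curves recover the plateaus", {
  # 1% amplitude noise; plateau medians should land within a few a.u.
  spec <- alphaOnlySpec(seed = 8L)
  for (r in 1:4) {
    cv <- simulateCurve(spec, "WT:alpha-T", 0, r)
    b <- estimateBaselines(cv)
    expect_identical(fitFlag(b), "ok")
    # true folded baseline drifts 100 -> ~115 over the folded region;
    # unfolded top plateau sits near 1100 + slope drift
    expect_lt(abs(b@fMin - 108), 12)
    expect_lt(abs(b@fMax - 1112), 12)
  }
})

test_that("flat and noise-only curves are flagged as no transition", {
  tt <- seq(293.15, 372.15, by = 1)
  flat <- methods::new("MeltingCurve", wellId = "A1", temperature = tt,
                       fluorescence = rep(500, length(tt)), protein = "P",
                       ligand = "L", urea = 0, replicate = 1L)
  expect_identical(fitFlag(estimateBaselines(flat)), "no_transition")
  noisy <- methods::new("MeltingCurve", wellId = "A1", temperature = tt,
                        fluorescence = withr::with_seed(1, rnorm(length(tt), 500, 5)),
                        protein = "P", ligand = "L", urea = 0, replicate = 1L)
  expect_identical(fitFlag(estimateBaselines(noisy)), "no_transition")
  f <- vantHoffFit(flat, estimateBaselines(flat))
  expect_identical(fitFlag(f), "no_transition")
  expect_true(isFlagged(f))
})

test_that("fraction unfolded normalises, clamps, and is affine-invariant", {
  b <- methods::new("BaselineEstimate", fMin = 100, fMax = 1100, flag = "ok")
  expect_equal(fractionUnfolded(100, b), 1e-6)
  expect_equal(fractionUnfolded(600, b), 0.5)
  expect_equal(fractionUnfolded(1100, b), 1 - 1e-6)
  expect_equal(fractionUnfolded(-1e5, b), 1e-6)   # clamped, no error

  # affine transform of trace and baselines leaves f_u unchanged
  F <- seq(100, 1100, length.out = 21)
  for (scale in c(0.25, 3)) for (shift in c(-200, 500)) {
    b2 <- methods::new("BaselineEstimate", fMin = 100 * scale + shift,
                       fMax = 1100 * scale + shift, flag = "ok")
    expect_equal(fractionUnfolded(F * scale + shift, b2),
                 fractionUnfolded(F, b), tolerance = 1e-12)
  }
})

test_that("equilibrium constant is f_u/(1-f_u) and monotone", {
  expect_equal(equilibriumConstant(0.5), 1)
  expect_equal(equilibriumConstant(0.8), 4)
  grid <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(equilibriumConstant(grid)) > 0))
  expect_error(equilibriumConstant(1), "0, 1")
})

test_that("midpoint detection hits the true melting point of clean curves", {
  # local two-state model: K = 1 exactly at tmTrue
  cv <- idealCurve(tmTrue = 336.73, dH = 159.15)
  b <- estimateBaselines(cv)
  expect_equal(detectTm(cv, b), 336.73, tolerance = 0.05)

  # invariance under a constant fluorescence offset
  cvShift <- methods::new("MeltingCurve", wellId = "A1",
                          temperature = temperatures(cv),
                          fluorescence = fluorescence(cv) + 500,
                          protein = "P", ligand = "L", urea = 0,
                          replicate = 1L)
  bShift <- estimateBaselines(cvShift)
  expect_equal(detectTm(cvShift, bShift), detectTm(cv, b), tolerance = 1e-6)

  # derivative-based estimate agrees within one temperature step
  expect_lt(abs(detectTm(cv, b, method = "derivative") - 336.73), 1)

  # curve that never crosses the midpoint: flagged (NA)
  half <- idealCurve(tmTrue = 380, dH = 159.15)
  bHalf <- methods::new("BaselineEstimate", fMin = 100, fMax = 1100,
                        flag = "ok")
  expect_true(is.na(detectTm(half, bHalf)))
})

test_that("van't Hoff fit recovers exact linear data to machine precision", {
  # fluorescence built so that ln K is exactly linear in 1/T
  dH <- 120
  tmTrue <- 335
  cv <- idealCurve(tmTrue = tmTrue, dH = dH)
  b <- methods::new("BaselineEstimate", fMin = 100, fMax = 1100, flag = "ok")
  fit <- vantHoffFit(cv, b)
  expect_identical(fitFlag(fit), "ok")
  expect_equal(fit@dHvH, dH, tolerance = 1e-6)
  expect_equal(fit@tm, tmTrue, tolerance = 1e-3)
  expect_gte(fit@nPoints, 5L)
  expect_gt(fit@rSquared, 1 - 1e-10)
  expect_true(fit@window[1] < fit@tm && fit@tm < fit@window[2])
})

test_that("van't Hoff slope equals brute-force normal equations", {
  # independent oracle: solve X'X beta = X'y directly on the window points
  cv <- idealCurve(tmTrue = 331.4, dH = 95)
  b <- methods::new("BaselineEstimate", fMin = 100, fMax = 1100, flag = "ok")
  fit <- vantHoffFit(cv, b)
  tt <- temperatures(cv)
  sel <- tt >= fit@window[1] & tt <= fit@window[2]
  fu <- fractionUnfolded(fluorescence(cv)[sel], b)
  y <- log(fu / (1 - fu))
  x <- 1 / tt[sel]
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit@dHvH, -beta[2] * RGAS, tolerance = 1e-9)
})

test_that("van't Hoff enthalpy on generator ground truth curves is accurate", {
  spec <- alphaOnlySpec(noiseSigma = 0)
  cv <- simulateCurve(spec, "WT:alpha-T", 0, 1)
  fit <- vantHoffFit(cv, estimateBaselines(cv))
  expect_equal(fit@dHvH, 159.15, tolerance = 0.5 / 159.15)
  expect_equal(fit@tm, 336.73, tolerance = 0.05 / 336.73)
})

test_that("doubling the noise roughly doubles the slope standard error", {
  ses <- sapply(c(5, 10), function(sigma) {
    mean(sapply(1:40, function(s) {
      cv <- idealCurve(tmTrue = 335, dH = 140, noise = sigma, seed = s)
      b <- methods::new("BaselineEstimate", fMin = 100, fMax = 1100,
                        flag = "ok")
      vantHoffFit(cv, b)@slopeStderr
    }))
  })
  ratio <- ses[2] / ses[1]
  expect_gt(ratio, 2 / 1.5)
  expect_lt(ratio, 2 * 1.5)
})

test_that("Kirchhoff fit returns the exact slope on collinear data", {
  tmv <- seq(329, 336.73, length.out = 8)
  dh <- 159.15 + 7.12 * (tmv - 336.73)
  kh <- kirchhoffFit(tmv, dh)
  expect_equal(kh$dCp, 7.12, tolerance = 1e-10)
  expect_equal(kh$stderr, 0, tolerance = 1e-8)
  # weights leave an exact line unchanged
  khW <- kirchhoffFit(tmv, dh, rep(2, 8))
  expect_equal(khW$dCp, 7.12, tolerance = 1e-10)
})

test_that("Kirchhoff fit rejects underdetermined or singular designs", {
  expect_error(kirchhoffFit(c(330, 335), c(100, 140)), "3 points")
  expect_error(kirchhoffFit(rep(333, 4), c(1, 2, 3, 4)), "singular")
})

test_that("Gibbs-Helmholtz identities hold", {
  p <- table1Params()
  # dG(Tm) = 0 to machine precision for arbitrary parameter sets
  for (par in p) expect_equal(gibbsHelmholtz(par, par@tm), 0, tolerance = 1e-12)
  withr::with_seed(7, {
    for (i in 1:20) {
      tmv <- runif(1, 300, 360); dh <- runif(1, 50, 250); dcp <- runif(1, 0, 15)
      expect_equal(gibbsHelmholtz(tmv, tmv, dHm = dh, dCp = dcp), 0,
                   tolerance = 1e-12)
      # dCp = 0 reduces to the linear van't Hoff form
      T <- runif(1, 280, 350)
      expect_equal(gibbsHelmholtz(tmv, T, dHm = dh, dCp = 0),
                   dh * (1 - T / tmv), tolerance = 1e-12)
    }
  })
  # frozen high-precision evaluation at 300 K for the WT alpha complex
  expect_equal(gibbsHelmholtz(p$wtAlpha, 300), 2.54799385222833,
               tolerance = 1e-10)
})

test_that("full-trace model fit is exact on noiseless curves", {
  spec <- syntheticSpec(noiseSigma = 0)
  for (cpx in c("WT:alpha-T", "WT:gamma-T")) {
    cv <- simulateCurve(spec, cpx, 1.5, 1)
    b <- estimateBaselines(cv)
    f <- vantHoffFit(cv, b)
    r <- fitCurveTwoState(cv, b, f)
    expect_true(r$converged)
    expect_equal(r$tm, trueTm(spec, cpx, 1.5), tolerance = 1e-6)
    expect_equal(r$dH, trueDH(spec, cpx, 1.5), tolerance = 1e-4)
    i <- match(cpx, paste(spec@complexes$protein, spec@complexes$ligand,
                          sep = ":"))
    expect_equal(r$dCp, spec@complexes$dCp[i], tolerance = 1e-3)
  }
})
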
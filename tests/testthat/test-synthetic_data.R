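test_that("ground-truth stability surface behaves as specified", {
  spec <- syntheticSpec()
  # dG(Tm0, 0 M) = 0 for every complex
  for (i in seq_len(nrow(spec@complexes))) {
    cpx <- paste(spec@complexes$protein[i], spec@complexes$ligand[i], sep = ":")
    expect_equal(trueStability(spec, cpx, spec@complexes$tm0[i], 0), 0,
                 tolerance = 1e-12)
  }
  # m = 0 makes dG independent of denaturant
  spec0 <- syntheticSpec(complexes = data.frame(
    protein = "P", ligand = "L", tm0 = 335, dHm0 = 150, dCp = 7, mUrea = 0))
  for (T in c(300, 320, 340)) {
    expect_equal(trueStability(spec0, "P:L", T, 0),
                 trueStability(spec0, "P:L", T, 3), tolerance = 1e-12)
  }
  # Tm(c) strictly decreasing in c when m > 0 (root-bracketing oracle)
  tms <- sapply(seq(0, 3, by = 0.5), function(u) trueTm(spec, "WT:alpha-T", u))
  expect_true(all(diff(tms) < 0))
  # and each root actually solves dG = 0
  for (j in seq_along(tms)) {
    expect_equal(trueStability(spec, "WT:alpha-T", tms[j], seq(0, 3, by = 0.5)[j]),
                 0, tolerance = 1e-6)
  }
})

test_that("simulated wells are reproducible and stream-independent", {
  spec <- alphaOnlySpec(seed = 21L)
  c1 <- simulateCurve(spec, "WT:alpha-T", 0, 1)
  c2 <- simulateCurve(spec, "WT:alpha-T", 0, 1)
  expect_identical(fluorescence(c1), fluorescence(c2))
  # different replicate -> different noise
  c3 <- simulateCurve(spec, "WT:alpha-T", 0, 2)
  expect_false(identical(fluorescence(c1), fluorescence(c3)))
  # simulation does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(simulateCurve(spec, "WT:alpha-T", 0, 1))
  after <- rnorm(3)
  expect_identical(before, after)
})

test_that("noiseless curve midpoint equals the root of the stability surface", {
  spec <- syntheticSpec(noiseSigma = 0)
  for (cpx in c("WT:alpha-T", "WT:gamma-T")) for (u in c(0, 1, 3)) {
    cv <- simulateCurve(spec, cpx, u, 1)
    b <- estimateBaselines(cv)
    expect_lt(abs(detectTm(cv, b) - trueTm(spec, cpx, u)), spec@tStep)
  }
})

test_that("plate generation has the right design and oracle table", {
  gen <- generatePlate(syntheticSpec(seed = 2L))
  expect_equal(ncol(gen$plate), 64L)     # 2 complexes x 8 urea x 4 reps
  expect_equal(nrow(gen$truth), 16L)     # one row per condition
  lay <- plateLayout(gen$plate)
  expect_equal(sort(unique(lay$urea)), c(0, 0.25, 0.5, 1, 1.5, 2, 2.5, 3))
  expect_equal(max(lay$replicate), 4L)
  expect_false(anyDuplicated(lay$well) > 0)

  tiny <- generatePlate(syntheticSpec(
    complexes = data.frame(protein = "P", ligand = "L", tm0 = 335,
                           dHm0 = 150, dCp = 7, mUrea = 1),
    ureaLevels = 0, replicates = 1L, seed = 1L))
  expect_equal(ncol(tiny$plate), 1L)

  expect_error(generatePlate(syntheticSpec(replicates = 7L)), "96")
})

test_that("truth table matches per-curve noiseless midpoints within one step", {
  spec <- syntheticSpec(noiseSigma = 0, replicates = 1L)
  gen <- generatePlate(spec)
  for (i in seq_len(nrow(gen$truth))) {
    tr <- gen$truth[i, ]
    cv <- meltingCurve(gen$plate,
                       plateLayout(gen$plate)$well[
                         plateLayout(gen$plate)$ligand == tr$ligand &
                         plateLayout(gen$plate)$urea == tr$urea][1])
    b <- estimateBaselines(cv)
    expect_lt(abs(detectTm(cv, b) - tr$tmTrue), spec@tStep)
  }
})

test_that("van't Hoff enthalpy is Kirchhoff-consistent across the urea series", {
  # dH(Tm(c)) = dHm0 + dCp (Tm(c) - Tm0) on noiseless curves: the plateau
  # path achieves 1% where a genuine folded plateau exists (low urea); the
  # full-trace fit achieves it at every urea level, including the
  # cold-denaturing high-urea conditions where plateau baselines degrade
  spec <- alphaOnlySpec(noiseSigma = 0,
                        ureaLevels = c(0, 0.25, 0.5, 1, 1.5, 2, 2.5, 3),
                        replicates = 1L)
  for (u in spec@ureaLevels) {
    cv <- simulateCurve(spec, "WT:alpha-T", u, 1)
    b <- estimateBaselines(cv)
    fit <- vantHoffFit(cv, b)
    dhExpected <- 159.15 + 7.12 * (trueTm(spec, "WT:alpha-T", u) - 336.73)
    expect_equal(trueDH(spec, "WT:alpha-T", u), dhExpected, tolerance = 1e-9)
    # window-curvature bias limits the ln K path to the few-percent class
    expect_lt(abs(fit@dHvH - dhExpected) / dhExpected, 0.05)
    refined <- fitCurveTwoState(cv, b, fit)
    expect_lt(abs(refined$dH - dhExpected) / dhExpected, 0.01)
  }
})

test_that("Kirchhoff slope is recovered across the urea series", {
  # noiseless: within 5% (full-trace per-curve estimates, the estimator
  # fitPlate aggregates with)
  spec0 <- alphaOnlySpec(noiseSigma = 0,
                         ureaLevels = c(0, 0.25, 0.5, 1, 1.5, 2, 2.5, 3),
                         replicates = 1L)
  fits <- lapply(spec0@ureaLevels, function(u) {
    cv <- simulateCurve(spec0, "WT:alpha-T", u, 1)
    b <- estimateBaselines(cv)
    fitCurveTwoState(cv, b, vantHoffFit(cv, b))
  })
  kh0 <- kirchhoffFit(vapply(fits, function(f) f$tm, numeric(1)),
                      vapply(fits, function(f) f$dH, numeric(1)))
  expect_lt(abs(kh0$dCp - 7.12) / 7.12, 0.05)

  # 1% amplitude noise, replicate-averaged conditions: within 15%
  spec1 <- alphaOnlySpec(seed = 31L,
                         ureaLevels = c(0, 0.25, 0.5, 1, 1.5, 2, 2.5, 3))
  condTm <- condDH <- c()
  for (u in spec1@ureaLevels) {
    fs <- lapply(1:4, function(r) {
      cv <- simulateCurve(spec1, "WT:alpha-T", u, r)
      vantHoffFit(cv, estimateBaselines(cv))
    })
    condTm <- c(condTm, mean(vapply(fs, tm, numeric(1))))
    condDH <- c(condDH, mean(vapply(fs, function(f) f@dHvH, numeric(1))))
  }
  kh1 <- kirchhoffFit(condTm, condDH)
  expect_lt(abs(kh1$dCp - 7.12) / 7.12, 0.15)
})

test_that("midpoint detection recovers the published Tm from 4 replicates", {
  spec <- alphaOnlySpec(seed = 13L)
  tms <- sapply(1:4, function(r) {
    cv <- simulateCurve(spec, "WT:alpha-T", 0, r)
    detectTm(cv, estimateBaselines(cv))
  })
  expect_lt(abs(mean(tms) - 336.73), 0.3)
})

test_that("optional post-transition dye decay bends the top plateau down", {
  specD <- alphaOnlySpec(noiseSigma = 0)
  specD@decayRate <- 0.02
  specD@decayOnset <- 350
  cv <- simulateCurve(specD, "WT:alpha-T", 0, 1)
  f <- fluorescence(cv)
  tt <- temperatures(cv)
  expect_lt(f[length(f)], max(f))          # signal decays after the peak
  expect_gt(tt[which.max(f)], 336.73)      # peak sits past the transition
  # decay leaves the midpoint essentially unchanged
  b <- estimateBaselines(cv)
  expect_lt(abs(detectTm(cv, b) - 336.73), 0.3)
})
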
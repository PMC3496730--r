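# RT = 1 unit system for closed-form comparisons
rt1 <- 1 / RGAS

test_that("coupling Hamiltonian endpoint and mixing identities are exact", {
  sys <- toySystem(function(x) 2, function(x) 4, temperature = rt1)
  expect_equal(coupledEnergy(sys, 0, 0), 2)
  expect_equal(coupledEnergy(sys, 0, 1), 4)
  expect_equal(coupledEnergy(sys, 0, 0.5), 3)
  expect_error(coupledEnergy(sys, 0, 1.2), "lambda")
  expect_error(coupledEnergy(sys, 0, -0.1), "lambda")

  # arbitrary toy systems: endpoints hold for random configurations
  harm <- harmonicSystem(1.3, 3.7, temperature = rt1)
  withr::with_seed(5, {
    for (i in 1:10) {
      x <- rnorm(1)
      expect_equal(coupledEnergy(harm, x, 0), 0.5 * 1.3 * x^2)
      expect_equal(coupledEnergy(harm, x, 1), 0.5 * 3.7 * x^2)
    }
  })
})

test_that("dH/dlambda is the end-state energy gap, matching finite differences", {
  sys <- toySystem(function(x) 2, function(x) 4, temperature = rt1)
  expect_equal(dhdl(sys, 0, 0.3), 2)
  same <- toySystem(function(x) sum(x^2), function(x) sum(x^2),
                    temperature = rt1)
  expect_equal(dhdl(same, 1.7, 0.5), 0)

  harm <- harmonicSystem(1, 4, temperature = rt1)
  h <- 1e-6
  withr::with_seed(6, {
    for (i in 1:10) {
      x <- rnorm(1); lam <- runif(1, 0.1, 0.9)
      fd <- (coupledEnergy(harm, x, lam + h) -
             coupledEnergy(harm, x, lam - h)) / (2 * h)
      expect_equal(dhdl(harm, x, lam), fd, tolerance = 1e-8)
    }
  })
})

test_that("Metropolis sampling matches the harmonic closed form", {
  # <dH/dl> at lambda: (k1-k0)/2 * <x^2> with <x^2> = RT/((1-l)k0 + l k1)
  harm <- harmonicSystem(1, 4, temperature = rt1)
  for (lam in c(0, 0.5, 1)) {
    m <- mcSampleDhdl(harm, lam, nSteps = 20000, burnIn = 4000,
                      seed = 100 + round(10 * lam))
    expect_identical(m$flag, "ok")
    exact <- 1.5 / (1 + 3 * lam)
    expect_lt(abs(m$mean - exact), 3 * m$stderr + 1e-12)
    expect_gt(m$acceptance, 0.2)
    expect_lt(m$acceptance, 0.65)
  }
  # identical end states: the estimate is exactly zero whatever the seed
  same <- toySystem(function(x) 0.5 * x^2, function(x) 0.5 * x^2,
                    temperature = rt1)
  for (s in c(1, 2)) {
    expect_identical(mcSampleDhdl(same, 0.5, nSteps = 2000, burnIn = 200,
                                  seed = s)$mean, 0)
  }
})

test_that("standard error shrinks like one over root sample size", {
  harm <- harmonicSystem(1, 4, temperature = rt1)
  ses <- sapply(c(4000, 16000), function(n) {
    mean(sapply(1:12, function(s) {
      mcSampleDhdl(harm, 0.5, nSteps = n, burnIn = 1000, seed = s)$stderr
    }))
  })
  ratio <- ses[1] / ses[2]   # expect ~2 for a 4x sample increase
  expect_gt(ratio, 2 / 1.3)
  expect_lt(ratio, 2 * 1.3)
})

test_that("trapezoidal integration handles schedules and degenerate input", {
  lam <- lambdaSchedule(7)
  expect_equal(lam[1], 0)
  expect_equal(lam[7], 1)
  expect_true(all(diff(lam) > 0))
  expect_error(lambdaSchedule(1), "at least 2")

  expect_equal(tiIntegrate(lam, rep(3.7, 7)), 3.7, tolerance = 1e-12)
  expect_equal(tiIntegrate(lam, rep(0, 7)), 0)
  expect_error(tiIntegrate(lam, rep(1, 6)), "one mean per lambda")
  expect_error(tiIntegrate(c(0, 0.5, 0.9), c(1, 1, 1)), "schedule")

  # 7-point trapezoid on the exact harmonic integrand is within its
  # quadrature error bound of the closed form (RT/2) ln(k1/k0)
  exact <- 0.5 * log(4)
  means <- 1.5 / (1 + 3 * lam)
  quadErr <- (1 / 6)^2 / 12 * abs(-4.5 / 16 + 4.5)  # h^2/12 |f'(1)-f'(0)|
  expect_lt(abs(tiIntegrate(lam, means) - exact), quadErr * 1.05)
})

test_that("forward/backward transformation brackets the combined estimate", {
  harm <- harmonicSystem(1, 4, temperature = rt1)
  res <- runTransformation(harm, lambdaSchedule(7), nSteps = 6000, seed = 3)
  exact <- 0.5 * log(4)
  expect_lt(abs(res@dGCombined - exact), 3 * res@dGStderr + 0.011)
  expect_gte(res@hysteresis, 0)
  lo <- min(res@dGForward, -res@dGBackward)
  hi <- max(res@dGForward, -res@dGBackward)
  expect_gte(res@dGCombined, lo - 1e-12)
  expect_lte(res@dGCombined, hi + 1e-12)

  # identical end states: both legs vanish identically
  same <- harmonicSystem(2, 2, temperature = rt1)
  res0 <- runTransformation(same, lambdaSchedule(5), nSteps = 2000, seed = 1)
  expect_identical(res0@dGForward, 0)
  expect_identical(res0@dGBackward, 0)
  expect_identical(res0@hysteresis, 0)
})

test_that("free energy is a state function on toy systems", {
  # dG(1->2) + dG(2->4) = dG(1->4) within combined Monte-Carlo error
  lam <- lambdaSchedule(7)
  ab <- runTransformation(harmonicSystem(1, 2, temperature = rt1), lam,
                          nSteps = 5000, seed = 11)
  bc <- runTransformation(harmonicSystem(2, 4, temperature = rt1), lam,
                          nSteps = 5000, seed = 12)
  ac <- runTransformation(harmonicSystem(1, 4, temperature = rt1), lam,
                          nSteps = 5000, seed = 13)
  gap <- (ab@dGCombined + bc@dGCombined) - ac@dGCombined
  se <- sqrt(ab@dGStderr^2 + bc@dGStderr^2 + ac@dGStderr^2)
  expect_lt(abs(gap), 3 * se + 0.011)  # sampling error plus quadrature bias
})

test_that("hysteresis decreases with sampling effort", {
  harm <- harmonicSystem(1, 4, temperature = rt1)
  hyst <- function(n) {
    median(sapply(1:8, function(s) {
      runTransformation(harm, lambdaSchedule(5), nSteps = n,
                        seed = 40 + s)@hysteresis
    }))
  }
  expect_lt(hyst(8000), hyst(500))
})

test_that("the thermodynamic cycle closes and is antisymmetric", {
  expect_equal(cycleDdg(5, 3), 2)
  expect_equal(cycleDdg(4.2, 4.2), 0)
  withr::with_seed(8, {
    for (i in 1:10) {
      gp <- rnorm(1); gw <- rnorm(1)
      expect_equal(cycleDdg(-gp, -gw), -cycleDdg(gp, gw), tolerance = 1e-12)
    }
  })
})
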
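## Desk-scale alchemical free energies on toy systems.
##
## Linear coupling H(lambda) = (1 - lambda) H_A + lambda H_B, equilibrium
## averages of dH/dlambda = H_B - H_A by Metropolis sampling, thermodynamic
## integration by trapezoidal quadrature over the lambda schedule, and
## hysteresis balancing by averaging forward and backward transformations.

#' Uniform lambda schedule
#'
#' @param n number of lambda points (>= 2); 7 is the conventional default
#'   for a single transformation leg
#' @return increasing values in [0, 1] with both endpoints included
#' @export
lambdaSchedule <- function(n = 7L) {
  n <- as.integer(n)
  if (n < 2L) usageError("a lambda schedule needs at least 2 points")
  seq(0, 1, length.out = n)
}

checkSchedule <- function(lambda) {
  if (length(lambda) < 2L || lambda[1] != 0 || lambda[length(lambda)] != 1 ||
      any(diff(lambda) <= 0)) {
    usageError("lambda schedule must increase strictly from 0 to 1")
  }
  lambda
}

#' Coupled Hamiltonian
#'
#' H(lambda, x) = (1 - lambda) H_A(x) + lambda H_B(x).
#'
#' @param sys a \linkS4class{ToyAlchemicalSystem}
#' @param x configuration vector
#' @param lambda coupling parameter in [0, 1]
#' @return energy, kcal/mol
#' @export
coupledEnergy <- function(sys, x, lambda) {
  stopifnot(methods::is(sys, "ToyAlchemicalSystem"))
  if (lambda < 0 || lambda > 1) usageError("lambda must lie in [0, 1]")
  (1 - lambda) * sys@hA(x) + lambda * sys@hB(x)
}

#' Derivative of the coupled Hamiltonian with respect to lambda
#'
#' For linear coupling this is H_B(x) - H_A(x), independent of lambda.
#'
#' @inheritParams coupledEnergy
#' @return dH/dlambda, kcal/mol
#' @export
dhdl <- function(sys, x, lambda = 0) {
  stopifnot(methods::is(sys, "ToyAlchemicalSystem"))
  sys@hB(x) - sys@hA(x)
}

#' Metropolis estimate of the equilibrium mean of dH/dlambda at fixed lambda
#'
#' A single Metropolis chain targets exp(-H(lambda, x)/RT) with isotropic
#' Gaussian proposals. The step size is auto-tuned during burn-in towards
#' 30-50\% acceptance, then frozen. The standard error of the post-burn-in
#' mean is computed by batch means (about 30 batches), which inflates the
#' naive error for autocorrelation. Deterministic given \code{seed}.
#'
#' @param sys a \linkS4class{ToyAlchemicalSystem}
#' @param lambda coupling parameter in [0, 1]
#' @param nSteps total chain length (> burnIn)
#' @param burnIn steps discarded (and used for step-size tuning)
#' @param seed integer seed for this chain
#' @param x0 starting configuration (default origin)
#' @return list with \code{mean}, \code{stderr}, \code{acceptance},
#'   \code{stepSize}, \code{flag} ("ok" or "zero_acceptance")
#' @export
mcSampleDhdl <- function(sys, lambda, nSteps = 10000L, burnIn = 1000L,
                         seed = 1L, x0 = NULL) {
  stopifnot(methods::is(sys, "ToyAlchemicalSystem"))
  if (lambda < 0 || lambda > 1) usageError("lambda must lie in [0, 1]")
  nSteps <- as.integer(nSteps); burnIn <- as.integer(burnIn)
  if (nSteps <= burnIn || burnIn < 0L) usageError("need nSteps > burnIn >= 0")
  d <- sys@dimension
  rt <- RGAS * sys@temperature
  hA <- sys@hA; hB <- sys@hB
  hL <- function(x) (1 - lambda) * hA(x) + lambda * hB(x)
  x <- x0 %||% rep(0, d)
  withSeed(seed, {
    eCur <- hL(x)
    step <- 1
    nAccTune <- 0L
    ## burn-in with step-size adaptation every 100 steps
    if (burnIn > 0L) {
      zs <- matrix(rnorm(burnIn * d), ncol = d)
      us <- runif(burnIn)
      for (i in seq_len(burnIn)) {
        xp <- x + step * zs[i, ]
        ep <- hL(xp)
        if (log(us[i]) < (eCur - ep) / rt) {
          x <- xp; eCur <- ep; nAccTune <- nAccTune + 1L
        }
        if (i %% 100L == 0L) {
          acc <- nAccTune / 100
          if (acc < 0.3) step <- step * 0.8
          else if (acc > 0.5) step <- step * 1.25
          nAccTune <- 0L
        }
      }
    }
    nProd <- nSteps - burnIn
    zs <- matrix(rnorm(nProd * d), ncol = d)
    us <- runif(nProd)
    vals <- numeric(nProd)
    nAcc <- 0L
    for (i in seq_len(nProd)) {
      xp <- x + step * zs[i, ]
      ep <- hL(xp)
      if (log(us[i]) < (eCur - ep) / rt) {
        x <- xp; eCur <- ep; nAcc <- nAcc + 1L
      }
      vals[i] <- hB(x) - hA(x)
    }
    flag <- if (nAcc == 0L) "zero_acceptance" else "ok"
    ## batch-means standard error (autocorrelation-robust)
    nb <- max(2L, min(30L, nProd %/% 10L))
    bsize <- nProd %/% nb
    bm <- vapply(seq_len(nb), function(b) {
      mean(vals[((b - 1L) * bsize + 1L):(b * bsize)])
    }, numeric(1))
    list(mean = mean(vals), stderr = sd(bm) / sqrt(nb),
         acceptance = nAcc / nProd, stepSize = step, flag = flag)
  })
}

#' Thermodynamic integration over a lambda schedule
#'
#' Trapezoidal quadrature of the per-lambda means of dH/dlambda.
#'
#' @param lambda increasing schedule from 0 to 1
#' @param means per-lambda mean dH/dlambda, kcal/mol
#' @return integrated free-energy difference, kcal/mol
#' @export
tiIntegrate <- function(lambda, means) {
  checkSchedule(lambda)
  if (length(means) != length(lambda)) {
    usageError("one mean per lambda point is required")
  }
  sum(diff(lambda) * (means[-length(means)] + means[-1]) / 2)
}

## trapezoid weights, for error propagation of independent per-lambda means
trapezoidWeights <- function(lambda) {
  n <- length(lambda)
  w <- numeric(n)
  dl <- diff(lambda)
  w[1] <- dl[1] / 2
  w[n] <- dl[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dl[-(n - 1)] + dl[-1]) / 2
  w
}

#' Run a full forward/backward alchemical transformation
#'
#' The forward leg integrates A to B over the schedule; the backward leg
#' swaps the end states (relabelling lambda) and integrates B to A. The two
#' are combined as (dG_forward - dG_backward)/2 to balance hysteresis bias;
#' the hysteresis |dG_forward + dG_backward| is reported as a convergence
#' diagnostic. Each (direction, lambda) chain gets its own seed derived from
#' \code{seed}.
#'
#' @param sys a \linkS4class{ToyAlchemicalSystem}
#' @param lambda schedule from [lambdaSchedule()]
#' @param nSteps Metropolis steps per lambda point
#' @param burnIn discarded steps per chain (default \code{nSteps \%/\% 5})
#' @param seed master seed
#' @return a \linkS4class{TIResult}
#' @examples
#' res <- runTransformation(harmonicSystem(1, 4), lambdaSchedule(7),
#'                          nSteps = 2000, seed = 1)
#' @export
runTransformation <- function(sys, lambda = lambdaSchedule(7L),
                              nSteps = 10000L, burnIn = nSteps %/% 5L,
                              seed = 1L) {
  checkSchedule(lambda)
  back <- toySystem(sys@hB, sys@hA, dimension = sys@dimension,
                    temperature = sys@temperature)
  leg <- function(s, tag) {
    res <- lapply(seq_along(lambda), function(i) {
      mcSampleDhdl(s, lambda[i], nSteps = nSteps, burnIn = burnIn,
                   seed = deriveSeed(seed, sprintf("%s|%d", tag, i)))
    })
    flags <- vapply(res, function(r) r$flag, character(1))
    if (any(flags != "ok")) {
      dataError(sprintf("Metropolis chain with zero acceptance (%s leg)", tag))
    }
    list(mean = vapply(res, function(r) r$mean, numeric(1)),
         se = vapply(res, function(r) r$stderr, numeric(1)))
  }
  fw <- leg(sys, "forward")
  bw <- leg(back, "backward")
  w <- trapezoidWeights(lambda)
  dgF <- tiIntegrate(lambda, fw$mean)
  dgB <- tiIntegrate(lambda, bw$mean)
  seF2 <- sum((w * fw$se)^2)
  seB2 <- sum((w * bw$se)^2)
  methods::new("TIResult", lambda = lambda,
               dhdlForward = fw$mean, dhdlForwardSe = fw$se,
               dhdlBackward = bw$mean, dhdlBackwardSe = bw$se,
               dGForward = dgF, dGBackward = dgB,
               dGCombined = (dgF - dgB) / 2,
               hysteresis = abs(dgF + dgB),
               dGStderr = sqrt(seF2 + seB2) / 2,
               temperature = sys@temperature)
}

#' Relative binding free energy from a thermodynamic cycle
#'
#' The alchemical transformation of ligand A into ligand B is carried out
#' once in the bound (protein) environment and once free in solution; the
#' difference closes the cycle and equals the relative binding free energy:
#' ddG_bind = dG_protein - dG_water.
#'
#' @param dGProtein alchemical dG in the protein leg, kcal/mol
#' @param dGWater alchemical dG in the solvent leg, kcal/mol
#' @return ddG of binding, kcal/mol
#' @export
cycleDdg <- function(dGProtein, dGWater) {
  stopifnotScalarNum(dGProtein, "dGProtein")
  stopifnotScalarNum(dGWater, "dGWater")
  dGProtein - dGWater
}
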
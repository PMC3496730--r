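## Two-state unfolding thermodynamics.
##
## The analysis chain per curve: plateau baselines -> fraction unfolded
## f_u = (F - F_min)/(F_max - F_min) -> equilibrium constant K = f_u/(1-f_u)
## -> melting midpoint (K = 1 crossing) -> van't Hoff fit of ln K vs 1/T
## (dH = -slope * R). Across a denaturant series, dH vs Tm gives the
## heat-capacity change (Kirchhoff slope); the Gibbs-Helmholtz relation then
## extrapolates dG away from Tm.

#' Default analysis configuration
#'
#' @param plateauFraction fraction of points/range defining the plateau
#'   regions for baseline estimation (in (0, 0.5))
#' @param fuWindow fraction-unfolded window for the van't Hoff fit
#' @param r2Floor r-squared below which a fit is flagged \code{"low_r2"}
#' @param epsilonClamp clamp for fraction unfolded, keeps ln K finite
#' @param minPoints minimum points in the van't Hoff window; when fewer raw
#'   points fall inside \code{fuWindow} the window is expanded to the
#'   \code{minPoints} samples nearest the midpoint
#' @param ampRatioFloor conditions whose fitted amplitude falls below this
#'   fraction of the complex's 0 M-urea median amplitude are excluded from
#'   aggregation (guards against transitions truncated by denaturant)
#' @param refine logical; refine per-curve parameters for aggregation with
#'   the full-trace model fit of [fitCurveTwoState()] (recommended for
#'   marginally stable complexes whose folded plateau never reaches the
#'   folded baseline)
#' @param referenceTemperature evaluation temperature for ddG, K
#' @return a named list of settings
#' @export
analysisConfig <- function(plateauFraction = 0.2,
                           fuWindow = c(0.2, 0.8),
                           r2Floor = 0.95,
                           epsilonClamp = 1e-6,
                           minPoints = 5L,
                           ampRatioFloor = 0.8,
                           refine = TRUE,
                           referenceTemperature = 300) {
  if (plateauFraction <= 0 || plateauFraction >= 0.5) {
    usageError("plateauFraction must lie in (0, 0.5)")
  }
  if (length(fuWindow) != 2L || fuWindow[1] <= 0 || fuWindow[2] >= 1 ||
      fuWindow[1] >= fuWindow[2]) {
    usageError("fuWindow must be an increasing pair inside (0, 1)")
  }
  list(plateauFraction = plateauFraction, fuWindow = fuWindow,
       r2Floor = r2Floor, epsilonClamp = epsilonClamp,
       minPoints = as.integer(minPoints), ampRatioFloor = ampRatioFloor,
       refine = isTRUE(refine), referenceTemperature = referenceTemperature)
}

## index of the folded-plateau centre: minimum of the median-smoothed trace.
## Thiol-dye traces can start high (cold-denatured tail) before the folded
## plateau, so the plateau is located by signal level, not by position.
foldedPlateauIndex <- function(f) {
  sm <- runmed(f, k = min(7L, 2L * (length(f) %/% 2L) - 1L))
  which.min(sm)
}

#' Estimate folded/unfolded baseline fluorescence levels
#'
#' F_min is a robust (median) level over a window of points centred on the
#' minimum of the median-smoothed trace — the folded plateau, wherever it
#' sits in the scan. F_max is the median of the points whose fluorescence
#' lies in the top \code{plateauFraction} of the observed range (the
#' post-transition plateau, before any high-temperature signal decay). A
#' curve whose amplitude is indistinguishable from its point-to-point noise
#' is flagged \code{"no_transition"}.
#'
#' @param curve a \linkS4class{MeltingCurve}
#' @param plateauFraction plateau width as a fraction of points/range
#' @return a \linkS4class{BaselineEstimate}
#' @export
estimateBaselines <- function(curve, plateauFraction = 0.2) {
  stopifnot(methods::is(curve, "MeltingCurve"))
  if (plateauFraction <= 0 || plateauFraction >= 0.5) {
    usageError("plateauFraction must lie in (0, 0.5)")
  }
  f <- fluorescence(curve)
  n <- length(f)
  iMin <- foldedPlateauIndex(f)
  half <- max(1L, floor(plateauFraction * n / 2))
  lo <- max(1L, iMin - half)
  hi <- min(n, iMin + half)
  fMin <- median(f[lo:hi])
  rng <- range(f)
  topSel <- which(f >= rng[2] - plateauFraction * diff(rng) & seq_len(n) > iMin)
  if (!length(topSel)) topSel <- which.max(f)
  fMax <- median(f[topSel])
  ## noise floor: robust sd of first differences (signal is smooth on the
  ## ramp scale, so differences are noise-dominated)
  noise <- mad(diff(f)) / sqrt(2)
  if (!is.finite(fMax - fMin) || (fMax - fMin) <= max(6 * noise, .Machine$double.eps * max(abs(rng)))) {
    return(methods::new("BaselineEstimate", fMin = fMin, fMax = fMin + 1,
                        flag = "no_transition"))
  }
  methods::new("BaselineEstimate", fMin = fMin, fMax = fMax, flag = "ok")
}

#' Fraction of unfolded protein from fluorescence
#'
#' f_u = (F - F_min)/(F_max - F_min), clamped to \code{[eps, 1 - eps]} so
#' that downstream logarithms stay finite.
#'
#' @param F fluorescence value(s), a.u.
#' @param b a valid \linkS4class{BaselineEstimate}
#' @param eps clamp width (default 1e-6)
#' @return fraction(s) unfolded in \code{[eps, 1 - eps]}
#' @export
fractionUnfolded <- function(F, b, eps = 1e-6) {
  stopifnot(methods::is(b, "BaselineEstimate"))
  if (isFlagged(b)) usageError("cannot normalise against a flagged baseline estimate")
  fu <- (F - b@fMin) / (b@fMax - b@fMin)
  pmin(pmax(fu, eps), 1 - eps)
}

#' Two-state unfolding equilibrium constant
#'
#' K = f_u / (1 - f_u) (unfolded over folded); strictly increasing in f_u.
#'
#' @param fu fraction unfolded in (0, 1)
#' @return equilibrium constant(s)
#' @export
equilibriumConstant <- function(fu) {
  if (any(fu <= 0 | fu >= 1)) usageError("fraction unfolded must lie in (0, 1)")
  fu / (1 - fu)
}

#' Detect the melting midpoint of a curve
#'
#' The thermodynamic midpoint is where the fraction unfolded crosses 0.5
#' (K = 1), located by linear interpolation between the bracketing samples.
#' The \emph{last} upward crossing is taken so that the heat transition is
#' reported even when a trace starts partially unfolded (cold-denatured
#' tail). \code{method = "derivative"} instead returns the temperature of
#' the maximum slope of the smoothed trace — the instrument-style estimate,
#' provided as a cross-check; for symmetric transitions the two agree within
#' one temperature step.
#'
#' @param curve a \linkS4class{MeltingCurve}
#' @param b a valid \linkS4class{BaselineEstimate}
#' @param method \code{"midpoint"} (default) or \code{"derivative"}
#' @param eps clamp passed to [fractionUnfolded()]
#' @return Tm in K, or \code{NA_real_} (flagged failure) when f_u never
#'   crosses 0.5 upward
#' @export
detectTm <- function(curve, b, method = c("midpoint", "derivative"),
                     eps = 1e-6) {
  method <- match.arg(method)
  tt <- temperatures(curve)
  if (method == "derivative") {
    f <- runmed(fluorescence(curve), k = min(5L, 2L * (length(tt) %/% 2L) - 1L))
    i <- foldedPlateauIndex(fluorescence(curve))
    d <- diff(f) / diff(tt)
    d[seq_len(max(i - 1L, 0L))] <- -Inf  # only the heat transition
    j <- which.max(d)
    return((tt[j] + tt[j + 1]) / 2)
  }
  fu <- fractionUnfolded(fluorescence(curve), b, eps = eps)
  up <- which(fu[-length(fu)] < 0.5 & fu[-1] >= 0.5)
  if (!length(up)) return(NA_real_)
  i <- up[length(up)]
  tt[i] + (0.5 - fu[i]) / (fu[i + 1] - fu[i]) * (tt[i + 1] - tt[i])
}

#' Van't Hoff fit of one melting curve
#'
#' Ordinary least squares of ln K against 1/T over the transition window:
#' the contiguous run of samples around the detected midpoint whose fraction
#' unfolded lies inside \code{fuWindow} (default [0.2, 0.8], where the
#' two-state, locally constant-enthalpy approximation holds). When the
#' sampling is too coarse for \code{minPoints} samples to fall inside the
#' window, the window is expanded symmetrically to the \code{minPoints}
#' samples nearest the midpoint. The unfolding enthalpy is minus the fitted
#' slope times the gas constant.
#'
#' @param curve a \linkS4class{MeltingCurve}
#' @param b a \linkS4class{BaselineEstimate} (from [estimateBaselines()])
#' @param config list from [analysisConfig()]
#' @return a \linkS4class{VantHoffFit}; failures are flagged, not raised
#' @export
vantHoffFit <- function(curve, b, config = analysisConfig()) {
  stopifnot(methods::is(curve, "MeltingCurve"))
  flaggedFit <- function(flag) {
    methods::new("VantHoffFit", wellId = curve@wellId, protein = curve@protein,
                 ligand = curve@ligand, urea = curve@urea,
                 replicate = curve@replicate, tm = NA_real_, dHvH = NA_real_,
                 dHvHStderr = NA_real_, slopeStderr = NA_real_,
                 nPoints = 0L, rSquared = NA_real_,
                 window = c(NA_real_, NA_real_), flag = flag)
  }
  if (isFlagged(b)) return(flaggedFit("no_transition"))
  tt <- temperatures(curve)
  fu <- fractionUnfolded(fluorescence(curve), b, eps = config$epsilonClamp)
  tmEst <- detectTm(curve, b, eps = config$epsilonClamp)
  if (is.na(tmEst)) return(flaggedFit("no_tm"))

  ## contiguous in-window run around the midpoint (avoids picking up a
  ## cold-denaturation branch at the start of the scan)
  iRight <- findInterval(tmEst, tt)  # tt[iRight] <= tmEst < tt[iRight+1]
  inWin <- fu >= config$fuWindow[1] & fu <= config$fuWindow[2]
  lo <- iRight
  while (lo >= 1L && inWin[lo]) lo <- lo - 1L
  hi <- iRight + 1L
  while (hi <= length(tt) && inWin[hi]) hi <- hi + 1L
  sel <- seq.int(lo + 1L, hi - 1L)
  sel <- sel[sel >= 1L & sel <= length(tt)]
  if (length(sel) < config$minPoints) {
    ## coarse sampling: take the minPoints samples nearest the midpoint
    sel <- order(abs(tt - tmEst))[seq_len(min(config$minPoints, length(tt)))]
    sel <- sort(sel)
  }
  if (length(sel) < config$minPoints) return(flaggedFit("too_few_points"))

  lnK <- log(equilibriumConstant(fu[sel]))
  invT <- 1 / tt[sel]
  fit <- lm(lnK ~ invT)
  sm <- summary(fit)
  slope <- coef(fit)[["invT"]]
  slopeSe <- sm$coefficients["invT", "Std. Error"]
  dH <- -slope * RGAS
  flag <- "ok"
  if (dH <= 0) flag <- "noncooperative"
  else if (is.finite(sm$r.squared) && sm$r.squared < config$r2Floor) flag <- "low_r2"
  methods::new("VantHoffFit", wellId = curve@wellId, protein = curve@protein,
               ligand = curve@ligand, urea = curve@urea,
               replicate = curve@replicate, tm = tmEst, dHvH = dH,
               dHvHStderr = slopeSe * RGAS, slopeStderr = slopeSe,
               nPoints = length(sel), rSquared = sm$r.squared,
               window = range(tt[sel]), flag = flag)
}

#' Full-trace two-state model fit of one melting curve
#'
#' Nonlinear least squares of the entire trace against a two-state model
#' with linear folded/unfolded baselines and Gibbs-Helmholtz occupancy:
#' \deqn{F(T) = (a_f + b_f (T - T_1))(1 - f_u) + (a_u + b_u (T - T_1)) f_u}
#' with \eqn{f_u = 1/(1 + e^{\Delta G(T)/RT})} and \eqn{\Delta G(T)} the
#' Gibbs-Helmholtz expression in (Tm, dH, dCp). Because the baselines are
#' fitted jointly with the occupancy, the estimates stay unbiased for
#' marginally stable complexes whose folded "plateau" retains a few percent
#' residual unfolding (including in-range cold denaturation) — the regime
#' where plateau-level baselines distort the van't Hoff fit. Starting values
#' come from the plateau-path estimates ([estimateBaselines()],
#' [detectTm()], [vantHoffFit()]).
#'
#' @param curve a \linkS4class{MeltingCurve}
#' @param b a \linkS4class{BaselineEstimate} for starting values
#' @param fit a \linkS4class{VantHoffFit} for starting values
#' @param dCpStarts starting heat-capacity values tried in turn (the
#'   per-curve dCp likelihood can be multimodal for strongly cold-denaturing
#'   traces); the lowest-residual solution is kept
#' @return list with \code{tm}, \code{dH}, \code{dCp}, baseline
#'   coefficients, \code{rss}, \code{converged}; \code{converged = FALSE}
#'   (with the starting values passed through) when the optimiser fails
#' @export
fitCurveTwoState <- function(curve, b, fit, dCpStarts = c(2, 8, 16)) {
  stopifnot(methods::is(curve, "MeltingCurve"))
  fallback <- list(tm = fit@tm, dH = fit@dHvH, dCp = NA_real_,
                   aF = b@fMin, bF = 0, aU = b@fMax, bU = 0,
                   rss = NA_real_, converged = FALSE)
  if (isFlagged(b) || isFlagged(fit)) return(fallback)
  tt <- temperatures(curve)
  fl <- fluorescence(curve)
  t1 <- tt[1]
  model <- function(aF, bF, aU, bU, tmv, dH, dcp) {
    dg <- dH * (1 - tt / tmv) - dcp * ((tmv - tt) + tt * log(tt / tmv))
    fu <- 1 / (1 + exp(pmin(700, dg / (RGAS * tt))))
    (aF + bF * (tt - t1)) * (1 - fu) + (aU + bU * (tt - t1)) * fu
  }
  best <- NULL
  for (dCpStart in dCpStarts) {
    res <- tryCatch(
      minpack.lm::nlsLM(
        fl ~ model(aF, bF, aU, bU, tmv, dH, dcp),
        start = list(aF = b@fMin, bF = 0, aU = b@fMax, bU = 0,
                     tmv = fit@tm, dH = fit@dHvH, dcp = dCpStart),
        lower = c(-Inf, -Inf, -Inf, -Inf, min(tt), 1, 0),
        upper = c(Inf, Inf, Inf, Inf, max(tt), 2000, 100),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(res)) next
    rss <- sum(stats::residuals(res)^2)
    if (is.null(best) || rss < best$rss) best <- list(co = coef(res), rss = rss)
  }
  if (is.null(best)) return(fallback)
  co <- best$co
  list(tm = unname(co["tmv"]), dH = unname(co["dH"]), dCp = unname(co["dcp"]),
       aF = unname(co["aF"]), bF = unname(co["bF"]), aU = unname(co["aU"]),
       bU = unname(co["bU"]), rss = best$rss, converged = TRUE)
}

#' Kirchhoff fit: heat-capacity change from dH vs Tm
#'
#' Weighted least-squares line of the van't Hoff enthalpy against the
#' melting temperature across a denaturant series; the slope is the
#' unfolding heat-capacity change dCp = d(dH)/dTm, its reported uncertainty
#' the standard error of the slope. Weights are inverse variances
#' (1/stderr^2); when any stderr is zero or missing (e.g. noiseless or
#' single-replicate data) the fit falls back to equal weights.
#'
#' @param tmValues melting temperatures, K (>= 3 distinct values)
#' @param dHValues van't Hoff enthalpies, kcal/mol
#' @param stderrValues per-point enthalpy standard errors (optional)
#' @return list with \code{dCp}, \code{stderr}, \code{intercept},
#'   \code{nPoints}
#' @export
kirchhoffFit <- function(tmValues, dHValues, stderrValues = NULL) {
  n <- length(tmValues)
  if (length(dHValues) != n) usageError("tmValues and dHValues lengths differ")
  ok <- is.finite(tmValues) & is.finite(dHValues)
  tmValues <- tmValues[ok]; dHValues <- dHValues[ok]
  if (!is.null(stderrValues)) stderrValues <- stderrValues[ok]
  if (length(tmValues) < 3L) dataError("Kirchhoff fit needs at least 3 points")
  if (diff(range(tmValues)) == 0) dataError("Kirchhoff fit is singular: identical Tm values")
  w <- NULL
  if (!is.null(stderrValues) && all(is.finite(stderrValues)) && all(stderrValues > 0)) {
    w <- 1 / stderrValues^2
  }
  fit <- lm(dHValues ~ tmValues, weights = w)
  ## exact collinear input (stderr 0) is legitimate here; silence only the
  ## perfect-fit warning from summary.lm
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  list(dCp = coef(fit)[["tmValues"]],
       stderr = sm$coefficients["tmValues", "Std. Error"],
       intercept = coef(fit)[["(Intercept)"]],
       nPoints = length(tmValues))
}

#' Gibbs-Helmholtz unfolding free energy
#'
#' dG(T) = dHm (1 - T/Tm) - dCp [(Tm - T) + T ln(T/Tm)], the standard
#' extrapolation of stability away from the melting point; dG(Tm) = 0
#' exactly and dCp = 0 reduces to the linear form dHm (1 - T/Tm).
#'
#' @param params a \linkS4class{StabilityParams}, or a melting temperature
#'   in K (then \code{dHm} and \code{dCp} must be given)
#' @param T evaluation temperature(s), K
#' @param dHm unfolding enthalpy at Tm, kcal/mol
#' @param dCp heat-capacity change, kcal mol-1 K-1
#' @return dG of unfolding, kcal/mol
#' @examples
#' gibbsHelmholtz(336.73, 300, dHm = 159.15, dCp = 7.12)
#' @export
gibbsHelmholtz <- function(params, T, dHm = NULL, dCp = NULL) {
  if (methods::is(params, "StabilityParams")) {
    tmv <- params@tm; dHm <- params@dHm; dCp <- params@dCp
  } else {
    tmv <- params
    if (is.null(dHm) || is.null(dCp)) usageError("supply dHm and dCp with a numeric Tm")
  }
  if (any(T <= 0)) usageError("temperature must be positive (Kelvin)")
  dHm * (1 - T / tmv) - dCp * ((tmv - T) + T * log(T / tmv))
}
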
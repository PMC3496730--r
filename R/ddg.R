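## Replicate aggregation, Gibbs-Helmholtz stability curves, relative ligand
## ddG with first-order uncertainty propagation, and the competitive-binding
## molar-ratio helper.

ddgConvention <- "ddG = dG_unfold(A) - dG_unfold(B); positive = ligand A binds more tightly; assumes the ligand does not bind the denatured state"

#' Aggregate replicate van't Hoff fits into stability parameters
#'
#' Melting temperature and enthalpy are replicate means at the reference
#' condition with SEM = sd/sqrt(n); the heat-capacity change and its
#' standard error pass through from the Kirchhoff fit.
#'
#' @param fits list of \linkS4class{VantHoffFit} for one complex at the
#'   reference (0 M denaturant) condition; flagged fits are dropped
#' @param kirchhoff result of [kirchhoffFit()] for the same complex
#' @return a \linkS4class{StabilityParams}
#' @export
aggregateReplicates <- function(fits, kirchhoff) {
  keep <- Filter(Negate(isFlagged), fits)
  if (length(keep) < 2L) {
    lab <- if (length(fits)) {
      sprintf("%s:%s at %g M", fits[[1]]@protein, fits[[1]]@ligand, fits[[1]]@urea)
    } else "empty condition"
    dataError(sprintf(
      "need >= 2 unflagged replicate fits to aggregate (%s has %d)",
      lab, length(keep)))
  }
  tms <- vapply(keep, function(f) f@tm, numeric(1))
  dhs <- vapply(keep, function(f) f@dHvH, numeric(1))
  n <- length(keep)
  StabilityParams(keep[[1]]@protein, keep[[1]]@ligand,
                  tm = mean(tms), tmSem = sd(tms) / sqrt(n),
                  dHm = mean(dhs), dHmSem = sd(dhs) / sqrt(n),
                  dCp = kirchhoff$dCp, dCpStderr = kirchhoff$stderr,
                  nReplicates = n)
}

#' Gibbs-Helmholtz stability curve on a temperature grid
#'
#' @param params a \linkS4class{StabilityParams}
#' @param tGrid increasing temperatures in (0, 2 Tm), K
#' @return a \linkS4class{GibbsCurve}
#' @export
stabilityCurve <- function(params, tGrid) {
  stopifnot(methods::is(params, "StabilityParams"))
  if (any(tGrid <= 0) || any(tGrid >= 2 * params@tm)) {
    usageError("temperature grid must lie in (0, 2 Tm)")
  }
  methods::new("GibbsCurve", temperature = as.numeric(tGrid),
               dG = gibbsHelmholtz(params, tGrid), params = params)
}

## analytic partial derivatives of the Gibbs-Helmholtz expression
ghPartials <- function(params, T) {
  tmv <- params@tm; dHm <- params@dHm; dCp <- params@dCp
  list(dHm = 1 - T / tmv,
       dCp = -((tmv - T) + T * log(T / tmv)),
       tm = dHm * T / tmv^2 - dCp * (1 - T / tmv))
}

#' First-order uncertainty of a ddG value
#'
#' Delta-method propagation through the Gibbs-Helmholtz expression treating
#' the six inputs (Tm, dHm, dCp of each complex) as independent, with
#' analytic partial derivatives:
#' d(dG)/d(dHm) = 1 - T/Tm, d(dG)/d(dCp) = -[(Tm - T) + T ln(T/Tm)],
#' d(dG)/d(Tm) = dHm T/Tm^2 - dCp (1 - T/Tm). The covariances induced by
#' the shared Kirchhoff fit are not recoverable from per-parameter summaries
#' and are neglected.
#'
#' @param paramsA,paramsB \linkS4class{StabilityParams} of the two complexes
#' @param T evaluation temperature, K
#' @return propagated standard deviation, kcal/mol
#' @export
propagateUncertainty <- function(paramsA, paramsB, T) {
  contrib <- function(p) {
    g <- ghPartials(p, T)
    (g$dHm * p@dHmSem)^2 + (g$dCp * p@dCpStderr)^2 + (g$tm * p@tmSem)^2
  }
  sqrt(contrib(paramsA) + contrib(paramsB))
}

#' Relative stability (ddG) of two ligand complexes
#'
#' ddG(T) = dG_unfold(A, T) - dG_unfold(B, T). With A the alpha-tocopherol
#' complex and B the gamma complex this follows the convention that a
#' positive value indicates higher affinity for the A ligand. The result is
#' antisymmetric in its arguments. Equal to the relative binding free energy
#' under the assumption that the ligand binds only the native state (noted
#' in the output convention string).
#'
#' @param paramsA,paramsB \linkS4class{StabilityParams} of the two complexes
#'   (must share a protein label)
#' @param T evaluation temperature, K (default 300)
#' @return a \linkS4class{DDGResult}
#' @examples
#' a <- StabilityParams("WT", "alpha-T", 336.73, 159.15, 7.12,
#'                      tmSem = 0.72, dHmSem = 2.90, dCpStderr = 0.79)
#' g <- StabilityParams("WT", "gamma-T", 334.65, 138.28, 10.45,
#'                      tmSem = 0.87, dHmSem = 11.94, dCpStderr = 1.33)
#' deltaDeltaG(a, g, T = 300)
#' @export
deltaDeltaG <- function(paramsA, paramsB, T = 300) {
  stopifnot(methods::is(paramsA, "StabilityParams"),
            methods::is(paramsB, "StabilityParams"))
  stopifnotScalarNum(T, "T")
  methods::new("DDGResult", protein = paramsA@protein,
               ligandA = paramsA@ligand, ligandB = paramsB@ligand,
               temperature = T,
               ddg = gibbsHelmholtz(paramsA, T) - gibbsHelmholtz(paramsB, T),
               sigma = propagateUncertainty(paramsA, paramsB, T),
               convention = ddgConvention)
}

#' Competitive-binding molar ratio from peak areas
#'
#' ratio = (area A / area B) * response factor, formatted with the dominant
#' species first: \code{"x:1"} when A dominates, \code{"1:y"} otherwise
#' (one decimal).
#'
#' @param peakAreaA,peakAreaB chromatographic peak areas (> 0), a.u.
#' @param responseFactor relative detector response (default 1: areas taken
#'   as concentration-proportional)
#' @return list with \code{ratio} (numeric, A per B) and \code{label}
#' @examples
#' bindingRatio(5.3, 1.0)$label   # "5.3:1"
#' bindingRatio(1.0, 1.5)$label   # "1:1.5"
#' @export
bindingRatio <- function(peakAreaA, peakAreaB, responseFactor = 1) {
  if (peakAreaA <= 0 || peakAreaB <= 0) dataError("peak areas must be positive")
  ratio <- peakAreaA / peakAreaB * responseFactor
  label <- if (ratio >= 1) sprintf("%.1f:1", ratio) else sprintf("1:%.1f", 1 / ratio)
  list(ratio = ratio, label = label)
}
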
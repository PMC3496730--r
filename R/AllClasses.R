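#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats coef lm median quantile runmed sd setNames uniroot var
#'   rnorm runif mad approx
#' @importFrom utils read.csv write.table read.delim
NULL

## ---------------------------------------------------------------------------
## Plate container
## ---------------------------------------------------------------------------

#' DSFPlate: a plate of thermal melting curves
#'
#' A \linkS4class{SummarizedExperiment} whose single assay
#' (\code{"fluorescence"}) holds one column per well and one row per
#' temperature step. \code{rowData} carries the common temperature grid in
#' Kelvin (\code{temperature}); \code{colData} carries the plate layout
#' (\code{well}, \code{protein}, \code{ligand}, \code{urea}, \code{replicate}).
#'
#' Temperatures are Kelvin everywhere inside the package; degrees Celsius are
#' accepted only at the file-reading boundary.
#'
#' @seealso [DSFPlate()], [readPlateCsv()], [meltingCurve()]
#' @export
setClass("DSFPlate", contains = "SummarizedExperiment")

layoutCols <- c("well", "protein", "ligand", "urea", "replicate")

setValidity("DSFPlate", function(object) {
  msg <- character()
  tt <- SummarizedExperiment::rowData(object)$temperature
  if (is.null(tt)) {
    return("rowData must contain a 'temperature' column (Kelvin)")
  }
  if (length(tt) < 20L) msg <- c(msg, "a melting curve needs at least 20 temperature points")
  if (any(diff(tt) <= 0)) msg <- c(msg, "temperatures must be strictly increasing")
  if (any(tt <= 0)) msg <- c(msg, "temperatures must be absolute (Kelvin)")
  if (!"fluorescence" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'fluorescence' is required")
  }
  if (!all(is.finite(SummarizedExperiment::assay(object, "fluorescence")))) {
    msg <- c(msg, "all fluorescence values must be finite")
  }
  cd <- SummarizedExperiment::colData(object)
  missingCols <- setdiff(layoutCols, colnames(cd))
  if (length(missingCols)) {
    return(paste0("layout columns missing from colData: ",
                  paste(missingCols, collapse = ", ")))
  }
  if (anyDuplicated(cd$well)) msg <- c(msg, "well ids must be unique")
  if (any(cd$urea < 0)) msg <- c(msg, "urea concentrations must be >= 0 M")
  if (any(cd$replicate < 1)) msg <- c(msg, "replicate indices must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a DSFPlate
#'
#' @param fluorescence numeric matrix, temperatures in rows, wells in columns;
#'   column names are well ids.
#' @param temperature numeric vector of temperatures in Kelvin, one per row.
#' @param layout data.frame with columns \code{well}, \code{protein},
#'   \code{ligand}, \code{urea} (M), \code{replicate}; one row per well,
#'   matched to the matrix columns by \code{well}.
#' @return a \linkS4class{DSFPlate}
#' @examples
#' tt <- seq(293.15, 372.15, by = 1)
#' f <- matrix(1000 / (1 + exp(-(tt - 330) / 2)) + 100, ncol = 1,
#'             dimnames = list(NULL, "A1"))
#' layout <- data.frame(well = "A1", protein = "WT", ligand = "alpha-T",
#'                      urea = 0, replicate = 1L)
#' DSFPlate(f, tt, layout)
#' @export
DSFPlate <- function(fluorescence, temperature, layout) {
  if (!is.matrix(fluorescence)) fluorescence <- as.matrix(fluorescence)
  if (is.null(colnames(fluorescence))) {
    usageError("fluorescence matrix must have well ids as column names")
  }
  layout <- as.data.frame(layout)
  missingCols <- setdiff(layoutCols, colnames(layout))
  if (length(missingCols)) {
    usageError(paste0("layout is missing columns: ",
                      paste(missingCols, collapse = ", ")))
  }
  idx <- match(colnames(fluorescence), layout$well)
  if (anyNA(idx)) {
    dataError(paste0("wells missing from layout: ",
                     paste(colnames(fluorescence)[is.na(idx)], collapse = ", ")))
  }
  layout <- layout[idx, layoutCols, drop = FALSE]
  rownames(layout) <- layout$well
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fluorescence = fluorescence),
    rowData = S4Vectors::DataFrame(temperature = as.numeric(temperature)),
    colData = S4Vectors::DataFrame(layout)
  )
  methods::new("DSFPlate", se)
}

## ---------------------------------------------------------------------------
## Single-curve and fit classes
## ---------------------------------------------------------------------------

#' MeltingCurve: one well's melting trace with its condition
#'
#' @slot wellId well label
#' @slot temperature strictly increasing Kelvin grid (>= 20 points)
#' @slot fluorescence same-length finite signal (arbitrary units)
#' @slot protein,ligand condition labels
#' @slot urea denaturant concentration (M)
#' @slot replicate replicate index (>= 1)
#' @export
setClass("MeltingCurve",
  representation(wellId = "character", temperature = "numeric",
                 fluorescence = "numeric", protein = "character",
                 ligand = "character", urea = "numeric",
                 replicate = "integer"))

setValidity("MeltingCurve", function(object) {
  msg <- character()
  if (length(object@temperature) < 20L) msg <- c(msg, "need >= 20 points")
  if (length(object@temperature) != length(object@fluorescence)) {
    msg <- c(msg, "temperature and fluorescence lengths differ")
  }
  if (any(diff(object@temperature) <= 0)) {
    msg <- c(msg, "temperatures must be strictly increasing")
  }
  if (!all(is.finite(object@fluorescence))) {
    msg <- c(msg, "fluorescence must be finite")
  }
  if (length(object@urea) && object@urea < 0) msg <- c(msg, "urea must be >= 0")
  if (length(msg)) msg else TRUE
})

#' BaselineEstimate: folded/unfolded fluorescence plateau levels
#'
#' @slot fMin folded-state (low) plateau level, a.u.
#' @slot fMax unfolded-state (high) plateau level, a.u.
#' @slot flag \code{"ok"} or \code{"no_transition"} when the amplitude is
#'   indistinguishable from noise; flagged curves are excluded downstream.
#' @export
setClass("BaselineEstimate",
  representation(fMin = "numeric", fMax = "numeric", flag = "character"),
  prototype(flag = "ok"))

setValidity("BaselineEstimate", function(object) {
  if (identical(object@flag, "ok") && !(object@fMax > object@fMin)) {
    "fMax must exceed fMin for an unflagged estimate"
  } else TRUE
})

#' VantHoffFit: per-curve melting midpoint and van't Hoff enthalpy
#'
#' Result of the linear fit of ln K against 1/T around the melting midpoint.
#' The enthalpy is minus the slope times the gas constant.
#'
#' @slot wellId,protein,ligand,urea,replicate condition metadata
#' @slot tm melting temperature, K (f_u = 0.5 crossing)
#' @slot dHvH van't Hoff unfolding enthalpy at Tm, kcal/mol
#' @slot dHvHStderr standard error of the enthalpy (from the slope), kcal/mol
#' @slot slopeStderr standard error of the ln K vs 1/T slope, K
#' @slot nPoints number of points in the fit window
#' @slot rSquared coefficient of determination of the fit
#' @slot window temperature window (low, high), K
#' @slot flag "ok", or a failure/warning marker ("no_transition", "no_tm",
#'   "too_few_points", "low_r2", "noncooperative")
#' @export
setClass("VantHoffFit",
  representation(wellId = "character", protein = "character",
                 ligand = "character", urea = "numeric", replicate = "integer",
                 tm = "numeric", dHvH = "numeric", dHvHStderr = "numeric",
                 slopeStderr = "numeric", nPoints = "integer",
                 rSquared = "numeric", window = "numeric", flag = "character"),
  prototype(flag = "ok"))

#' StabilityParams: aggregated thermodynamic parameters for one complex
#'
#' Replicate-averaged melting temperature and unfolding enthalpy (mean and
#' SEM) at the reference condition, plus the unfolding heat-capacity change
#' from the weighted Kirchhoff fit across the denaturant series (slope and
#' its standard error).
#'
#' @slot protein,ligand complex labels
#' @slot tm,tmSem melting temperature and SEM, K
#' @slot dHm,dHmSem unfolding enthalpy at Tm and SEM, kcal/mol
#' @slot dCp,dCpStderr heat-capacity change and slope standard error,
#'   kcal mol-1 K-1
#' @slot nReplicates replicates averaged at the reference condition
#' @export
setClass("StabilityParams",
  representation(protein = "character", ligand = "character",
                 tm = "numeric", tmSem = "numeric",
                 dHm = "numeric", dHmSem = "numeric",
                 dCp = "numeric", dCpStderr = "numeric",
                 nReplicates = "integer"))

setValidity("StabilityParams", function(object) {
  if (object@tm <= 0) "tm must be positive (Kelvin)" else TRUE
})

#' Construct StabilityParams directly
#'
#' Convenience constructor for supplying published or externally determined
#' parameters (e.g. when computing ddG from a table of fitted values).
#'
#' @param protein,ligand complex labels
#' @param tm,tmSem melting temperature and its SEM, K
#' @param dHm,dHmSem unfolding enthalpy at Tm and its SEM, kcal/mol
#' @param dCp,dCpStderr heat-capacity change and its standard error,
#'   kcal mol-1 K-1
#' @param nReplicates number of replicates behind the averages
#' @return a \linkS4class{StabilityParams}
#' @examples
#' StabilityParams("WT", "alpha-T", tm = 336.73, tmSem = 0.72,
#'                 dHm = 159.15, dHmSem = 2.90, dCp = 7.12, dCpStderr = 0.79)
#' @export
StabilityParams <- function(protein, ligand, tm, dHm, dCp,
                            tmSem = 0, dHmSem = 0, dCpStderr = 0,
                            nReplicates = NA_integer_) {
  methods::new("StabilityParams", protein = as.character(protein),
               ligand = as.character(ligand), tm = as.numeric(tm),
               tmSem = as.numeric(tmSem), dHm = as.numeric(dHm),
               dHmSem = as.numeric(dHmSem), dCp = as.numeric(dCp),
               dCpStderr = as.numeric(dCpStderr),
               nReplicates = as.integer(nReplicates))
}

#' GibbsCurve: a Gibbs-Helmholtz stability curve on a temperature grid
#'
#' @slot temperature increasing grid, K
#' @slot dG unfolding free energy at each grid point, kcal/mol
#' @slot params the \linkS4class{StabilityParams} the curve was built from
#' @export
setClass("GibbsCurve",
  representation(temperature = "numeric", dG = "numeric",
                 params = "StabilityParams"))

setValidity("GibbsCurve", function(object) {
  if (length(object@temperature) != length(object@dG)) {
    return("temperature and dG lengths differ")
  }
  if (any(diff(object@temperature) <= 0)) {
    return("temperature grid must be increasing")
  }
  TRUE
})

#' DDGResult: relative stability of two ligand complexes
#'
#' ddG(T) = dG_unfold(complex A, T) - dG_unfold(complex B, T); under the
#' assumption that the ligand binds only the native state this equals the
#' relative binding free energy. Positive values mean ligand A stabilises
#' the protein more (binds more tightly) than ligand B.
#'
#' @slot protein protein label
#' @slot ligandA,ligandB the two ligand labels (A minus B)
#' @slot temperature evaluation temperature, K
#' @slot ddg relative free energy, kcal/mol
#' @slot sigma first-order propagated uncertainty, kcal/mol
#' @slot convention human-readable sign-convention note
#' @export
setClass("DDGResult",
  representation(protein = "character", ligandA = "character",
                 ligandB = "character", temperature = "numeric",
                 ddg = "numeric", sigma = "numeric", convention = "character"))

setValidity("DDGResult", function(object) {
  if (length(object@sigma) && is.finite(object@sigma) && object@sigma < 0) {
    "sigma must be >= 0"
  } else TRUE
})

## ---------------------------------------------------------------------------
## Synthetic generator spec
## ---------------------------------------------------------------------------

#' SyntheticSpec: ground-truth description of a simulated DSF plate
#'
#' Per-complex stability surfaces (Gibbs-Helmholtz parameters plus a linear
#' denaturant m-value), the plate design (urea series, replicates,
#' temperature ramp) and the fluorescence signal model (baselines, slopes,
#' Gaussian noise). All randomness derives from the single integer seed.
#'
#' @slot complexes data.frame with columns protein, ligand, tm0 (K), dHm0
#'   (kcal/mol at tm0), dCp (kcal mol-1 K-1), mUrea (kcal mol-1 M-1)
#' @slot ureaLevels distinct urea concentrations, M
#' @slot replicates replicates per condition
#' @slot tStart,tEnd,tStep temperature ramp, K
#' @slot fFoldedBase,fUnfoldedBase baseline fluorescence intercepts, a.u.
#' @slot slopeFolded,slopeUnfolded baseline slopes, a.u./K
#' @slot noiseSigma Gaussian noise s.d., a.u.
#' @slot decayRate optional post-transition dye-signal decay rate (1/K); 0
#'   disables the decay (the default)
#' @slot decayOnset temperature above which decay applies, K
#' @slot seed master seed
#' @export
setClass("SyntheticSpec",
  representation(complexes = "data.frame", ureaLevels = "numeric",
                 replicates = "integer", tStart = "numeric", tEnd = "numeric",
                 tStep = "numeric", fFoldedBase = "numeric",
                 fUnfoldedBase = "numeric", slopeFolded = "numeric",
                 slopeUnfolded = "numeric", noiseSigma = "numeric",
                 decayRate = "numeric", decayOnset = "numeric",
                 seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  need <- c("protein", "ligand", "tm0", "dHm0", "dCp", "mUrea")
  missingCols <- setdiff(need, colnames(object@complexes))
  if (length(missingCols)) {
    return(paste0("complexes is missing columns: ",
                  paste(missingCols, collapse = ", ")))
  }
  if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (anyDuplicated(object@ureaLevels)) msg <- c(msg, "urea levels must be distinct")
  if (any(object@ureaLevels < 0)) msg <- c(msg, "urea levels must be >= 0")
  if (any(object@complexes$tm0 <= object@tStart) ||
      any(object@complexes$tm0 >= object@tEnd)) {
    msg <- c(msg, "each tm0 must lie inside (tStart, tEnd)")
  }
  if (object@tStep <= 0 || object@tEnd <= object@tStart) {
    msg <- c(msg, "temperature ramp must be increasing")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Toy alchemical systems
## ---------------------------------------------------------------------------

#' ToyAlchemicalSystem: two end-state Hamiltonians on a common configuration
#' space
#'
#' Dual-topology bookkeeping reduced to its essence: two full potential
#' energy functions H_A(x) and H_B(x) (kcal/mol) over the same configuration
#' vector, mixed linearly by the coupling parameter lambda.
#'
#' @slot hA,hB energy functions taking a numeric configuration vector
#' @slot dimension configuration-space dimension
#' @slot temperature K (RT = RGAS * temperature, kcal/mol)
#' @export
setClass("ToyAlchemicalSystem",
  representation(hA = "function", hB = "function", dimension = "integer",
                 temperature = "numeric"))

setValidity("ToyAlchemicalSystem", function(object) {
  msg <- character()
  if (object@dimension < 1L) msg <- c(msg, "dimension must be >= 1")
  if (object@temperature <= 0) msg <- c(msg, "temperature must be positive")
  x0 <- rep(0, object@dimension)
  if (!is.finite(object@hA(x0)) || !is.finite(object@hB(x0))) {
    msg <- c(msg, "energy functions must be finite at the origin")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a toy alchemical system
#'
#' @param hA,hB energy functions of a numeric configuration vector, kcal/mol
#' @param dimension configuration-space dimension (default 1)
#' @param temperature temperature in K; use \code{1/RGAS} for RT = 1
#' @return a \linkS4class{ToyAlchemicalSystem}
#' @examples
#' sys <- toySystem(function(x) sum(x^2) / 2, function(x) 2 * sum(x^2),
#'                  temperature = 1 / RGAS)
#' @export
toySystem <- function(hA, hB, dimension = 1L, temperature = 300) {
  methods::new("ToyAlchemicalSystem", hA = hA, hB = hB,
               dimension = as.integer(dimension),
               temperature = as.numeric(temperature))
}

#' One-dimensional harmonic-to-harmonic alchemical system
#'
#' H_A = k0 x^2 / 2, H_B = k1 x^2 / 2. The exact alchemical free energy is
#' (RT/2) log(k1/k0), which makes this the reference system for validating
#' thermodynamic integration.
#'
#' @param k0,k1 force constants (kcal mol-1 per squared configuration unit)
#' @param temperature K; \code{1/RGAS} gives RT = 1
#' @return a \linkS4class{ToyAlchemicalSystem}
#' @export
harmonicSystem <- function(k0, k1, temperature = 1 / RGAS) {
  stopifnotScalarNum(k0, "k0"); stopifnotScalarNum(k1, "k1")
  if (k0 <= 0 || k1 <= 0) usageError("force constants must be positive")
  force(k0); force(k1)
  toySystem(function(x) 0.5 * k0 * sum(x^2), function(x) 0.5 * k1 * sum(x^2),
            dimension = 1L, temperature = temperature)
}

#' TIResult: a forward/backward thermodynamic-integration transformation
#'
#' @slot lambda the lambda schedule (0 to 1)
#' @slot dhdlForward,dhdlForwardSe per-lambda mean dH/dlambda and standard
#'   error for the forward (A to B) leg, kcal/mol
#' @slot dhdlBackward,dhdlBackwardSe same for the backward (B to A) leg
#' @slot dGForward,dGBackward integrated free energies of the two legs
#' @slot dGCombined hysteresis-balanced estimate (forward - backward)/2
#' @slot hysteresis |dGForward + dGBackward|, kcal/mol
#' @slot dGStderr quadrature-propagated Monte-Carlo standard error of
#'   dGCombined
#' @slot temperature K
#' @export
setClass("TIResult",
  representation(lambda = "numeric", dhdlForward = "numeric",
                 dhdlForwardSe = "numeric", dhdlBackward = "numeric",
                 dhdlBackwardSe = "numeric", dGForward = "numeric",
                 dGBackward = "numeric", dGCombined = "numeric",
                 hysteresis = "numeric", dGStderr = "numeric",
                 temperature = "numeric"))

setValidity("TIResult", function(object) {
  if (length(object@hysteresis) && object@hysteresis < 0) {
    "hysteresis must be >= 0"
  } else TRUE
})
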
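#' Accessors for dsfddg classes
#'
#' Small accessor generics so user code never touches slots directly:
#' \code{temperatures()} (Kelvin grid), \code{fluorescence()} (signal matrix
#' or vector), \code{plateLayout()} (condition table), \code{wellIds()},
#' \code{tm()}, \code{dHm()}, \code{dCp()} (thermodynamic parameters),
#' \code{ddg()} and \code{ddgSigma()} (relative free energy and its
#' propagated uncertainty), \code{fitFlag()} and \code{isFlagged()} (QC
#' status of per-curve results).
#'
#' @param x a dsfddg object
#' @return the requested component
#' @name accessors
NULL

#' @rdname accessors
setMethod("temperatures", "DSFPlate", function(x) {
  SummarizedExperiment::rowData(x)$temperature
})

#' @rdname accessors
setMethod("temperatures", "MeltingCurve", function(x) x@temperature)

#' @rdname accessors
setMethod("fluorescence", "DSFPlate", function(x) {
  SummarizedExperiment::assay(x, "fluorescence")
})

#' @rdname accessors
setMethod("fluorescence", "MeltingCurve", function(x) x@fluorescence)

#' @rdname accessors
setMethod("plateLayout", "DSFPlate", function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
})

#' @rdname accessors
setMethod("wellIds", "DSFPlate", function(x) {
  as.character(SummarizedExperiment::colData(x)$well)
})

#' Extract one well as a MeltingCurve
#'
#' @param plate a \linkS4class{DSFPlate}
#' @param well well id (e.g. \code{"A1"})
#' @return a \linkS4class{MeltingCurve}
#' @export
meltingCurve <- function(plate, well) {
  stopifnot(methods::is(plate, "DSFPlate"))
  j <- match(well, wellIds(plate))
  if (is.na(j)) dataError(sprintf("well '%s' is not on the plate", well))
  cd <- plateLayout(plate)[j, ]
  methods::new("MeltingCurve", wellId = as.character(well),
               temperature = temperatures(plate),
               fluorescence = as.numeric(fluorescence(plate)[, j]),
               protein = as.character(cd$protein),
               ligand = as.character(cd$ligand),
               urea = as.numeric(cd$urea),
               replicate = as.integer(cd$replicate))
}

#' Extract every well of a plate as a list of MeltingCurve objects
#'
#' @param plate a \linkS4class{DSFPlate}
#' @return named list of \linkS4class{MeltingCurve}
#' @export
meltingCurves <- function(plate) {
  ids <- wellIds(plate)
  setNames(lapply(ids, meltingCurve, plate = plate), ids)
}

#' @rdname accessors
setMethod("tm", "StabilityParams", function(x) x@tm)

#' @rdname accessors
setMethod("tm", "VantHoffFit", function(x) x@tm)

#' @rdname accessors
setMethod("dHm", "StabilityParams", function(x) x@dHm)

#' @rdname accessors
setMethod("dCp", "StabilityParams", function(x) x@dCp)

#' @rdname accessors
setMethod("ddg", "DDGResult", function(x) x@ddg)

#' @rdname accessors
setMethod("ddgSigma", "DDGResult", function(x) x@sigma)

#' @rdname accessors
setMethod("fitFlag", "VantHoffFit", function(x) x@flag)

#' @rdname accessors
setMethod("fitFlag", "BaselineEstimate", function(x) x@flag)

#' @rdname accessors
setMethod("isFlagged", "VantHoffFit", function(x) !identical(x@flag, "ok") &&
            !identical(x@flag, "low_r2"))

#' @rdname accessors
setMethod("isFlagged", "BaselineEstimate", function(x) !identical(x@flag, "ok"))

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "DSFPlate", function(object) {
  tt <- temperatures(object)
  cat(sprintf("DSFPlate: %d wells, %d temperature points (%.2f-%.2f K)\n",
              ncol(object), length(tt), min(tt), max(tt)))
  lay <- plateLayout(object)
  cat(sprintf("  complexes: %s\n",
              paste(unique(paste(lay$protein, lay$ligand, sep = ":")),
                    collapse = ", ")))
  cat(sprintf("  urea levels (M): %s; replicates: %s\n",
              paste(sort(unique(lay$urea)), collapse = ", "),
              paste(sort(unique(lay$replicate)), collapse = ",")))
})

setMethod("show", "MeltingCurve", function(object) {
  cat(sprintf("MeltingCurve %s [%s:%s, %.2g M urea, rep %d]: %d points, %.2f-%.2f K\n",
              object@wellId, object@protein, object@ligand, object@urea,
              object@replicate, length(object@temperature),
              min(object@temperature), max(object@temperature)))
})

setMethod("show", "VantHoffFit", function(object) {
  cat(sprintf("VantHoffFit %s [%s:%s, %.2g M urea, rep %d]\n", object@wellId,
              object@protein, object@ligand, object@urea, object@replicate))
  if (identical(object@flag, "ok") || identical(object@flag, "low_r2")) {
    cat(sprintf("  Tm = %.2f K, dH_vH = %.2f +/- %.2f kcal/mol (n = %d, r2 = %.4f)\n",
                object@tm, object@dHvH, object@dHvHStderr, object@nPoints,
                object@rSquared))
  }
  if (!identical(object@flag, "ok")) cat(sprintf("  flag: %s\n", object@flag))
})

setMethod("show", "StabilityParams", function(object) {
  cat(sprintf("StabilityParams %s:%s\n", object@protein, object@ligand))
  cat(sprintf("  Tm   = %8.2f +/- %.2f K (SEM, n = %s)\n", object@tm,
              object@tmSem, object@nReplicates))
  cat(sprintf("  dHm  = %8.2f +/- %.2f kcal/mol (SEM)\n", object@dHm,
              object@dHmSem))
  cat(sprintf("  dCp  = %8.2f +/- %.2f kcal/mol/K (slope stderr)\n",
              object@dCp, object@dCpStderr))
})

setMethod("show", "DDGResult", function(object) {
  cat(sprintf("DDGResult %s: ddG(%s - %s) at %.1f K = %.2f +/- %.2f kcal/mol\n",
              object@protein, object@ligandA, object@ligandB,
              object@temperature, object@ddg, object@sigma))
  cat(sprintf("  %s\n", object@convention))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: %d complex(es), %d urea level(s), %d replicate(s), seed %d\n",
              nrow(object@complexes), length(object@ureaLevels),
              object@replicates, object@seed))
  cat(sprintf("  ramp %.2f-%.2f K by %.2f K; noise sigma %.3g a.u.\n",
              object@tStart, object@tEnd, object@tStep, object@noiseSigma))
})

setMethod("show", "TIResult", function(object) {
  cat(sprintf("TIResult (%d lambda points, T = %.4g K)\n",
              length(object@lambda), object@temperature))
  cat(sprintf("  dG forward  = %8.4f kcal/mol\n", object@dGForward))
  cat(sprintf("  dG backward = %8.4f kcal/mol\n", object@dGBackward))
  cat(sprintf("  dG combined = %8.4f +/- %.4f kcal/mol (hysteresis %.4f)\n",
              object@dGCombined, object@dGStderr, object@hysteresis))
})
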
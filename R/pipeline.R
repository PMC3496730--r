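## Plate-level orchestration and the file-based pipeline stages
## (simulate | fit | ddg | alchemy). Each stage is a plain R function over
## files so runs are scriptable and reproducible; inst/scripts/dsfddg wraps
## them for the shell.

#' Fit every curve of a plate and aggregate per complex
#'
#' Per well: baseline estimation, midpoint detection and van't Hoff fit;
#' with \code{refine = TRUE} (default) the per-curve melting temperature and
#' enthalpy used for aggregation are then re-estimated by the full-trace
#' model fit of [fitCurveTwoState()], which is unbiased for marginally
#' stable complexes whose folded plateau retains residual unfolding. Per
#' complex (protein:ligand): condition-level replicate means feed the
#' weighted Kirchhoff fit of enthalpy against melting temperature across the
#' denaturant series (condition weights are the SEMs of the replicate
#' enthalpies), and the reference-condition (lowest urea) replicates are
#' averaged into \linkS4class{StabilityParams}. Conditions whose median
#' fitted amplitude falls below \code{ampRatioFloor} of the reference
#' amplitude are excluded as truncated transitions; all exclusions are
#' listed in the returned QC table.
#'
#' @param plate a \linkS4class{DSFPlate}
#' @param config list from [analysisConfig()]
#' @return list with \code{fits} (list of \linkS4class{VantHoffFit}, the
#'   plateau/ln K path), \code{refined} (data.frame of full-trace estimates,
#'   when enabled), \code{params} (list of \linkS4class{StabilityParams}),
#'   \code{qc} (data.frame of flagged wells/conditions), \code{kirchhoff}
#'   (per-complex fit summaries)
#' @export
fitPlate <- function(plate, config = analysisConfig()) {
  stopifnot(methods::is(plate, "DSFPlate"))
  curves <- meltingCurves(plate)
  fits <- vector("list", length(curves))
  amps <- numeric(length(curves))
  aggTm <- aggDH <- numeric(length(curves))
  refined <- NULL
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    b <- estimateBaselines(cv, plateauFraction = config$plateauFraction)
    f <- vantHoffFit(cv, b, config = config)
    fits[[i]] <- f
    amps[i] <- if (isFlagged(b)) NA_real_ else b@fMax - b@fMin
    aggTm[i] <- f@tm; aggDH[i] <- f@dHvH
    if (config$refine) {
      r <- fitCurveTwoState(cv, b, f)
      if (r$converged) {
        aggTm[i] <- r$tm; aggDH[i] <- r$dH
        amps[i] <- (r$aU + r$bU * (r$tm - temperatures(cv)[1])) -
                   (r$aF + r$bF * (r$tm - temperatures(cv)[1]))
      }
      refined <- rbind(refined, data.frame(
        well = cv@wellId, protein = cv@protein, ligand = cv@ligand,
        urea = cv@urea, replicate = cv@replicate, tm = r$tm, dH = r$dH,
        dCp = r$dCp, converged = r$converged, stringsAsFactors = FALSE))
    }
  }
  names(fits) <- names(curves)

  meta <- data.frame(
    protein = vapply(fits, function(f) f@protein, character(1)),
    ligand = vapply(fits, function(f) f@ligand, character(1)),
    urea = vapply(fits, function(f) f@urea, numeric(1)),
    flag = vapply(fits, function(f) f@flag, character(1)),
    amplitude = amps, stringsAsFactors = FALSE)
  meta$complex <- paste(meta$protein, meta$ligand, sep = ":")
  qc <- data.frame(well = names(fits)[meta$flag != "ok"],
                   reason = meta$flag[meta$flag != "ok"],
                   stringsAsFactors = FALSE)

  params <- list()
  kirchhoffs <- list()
  for (cpx in unique(meta$complex)) {
    rows <- which(meta$complex == cpx)
    refUrea <- min(meta$urea[rows])
    refAmp <- median(amps[rows][meta$urea[rows] == refUrea], na.rm = TRUE)
    condTm <- condDH <- condSe <- numeric(0)
    refRows <- integer(0)
    for (u in sort(unique(meta$urea[rows]))) {
      cond <- rows[meta$urea[rows] == u]
      ok <- cond[!vapply(fits[cond], isFlagged, logical(1)) & is.finite(aggTm[cond])]
      condAmp <- median(amps[cond], na.rm = TRUE)
      if (is.finite(condAmp) && is.finite(refAmp) &&
          condAmp < config$ampRatioFloor * refAmp) {
        qc <- rbind(qc, data.frame(
          well = paste0(cpx, "@", u, "M"),
          reason = "truncated_transition", stringsAsFactors = FALSE))
        next
      }
      if (length(ok) < 1L) next
      if (u == refUrea) refRows <- ok
      condTm <- c(condTm, mean(aggTm[ok]))
      condDH <- c(condDH, mean(aggDH[ok]))
      condSe <- c(condSe, if (length(ok) > 1L) sd(aggDH[ok]) / sqrt(length(ok)) else NA_real_)
    }
    if (length(condTm) < 3L) {
      qc <- rbind(qc, data.frame(well = cpx, reason = "too_few_conditions_for_kirchhoff",
                                 stringsAsFactors = FALSE))
      next
    }
    se <- if (all(is.finite(condSe)) && all(condSe > 0)) condSe else NULL
    kh <- kirchhoffFit(condTm, condDH, se)
    ## the regression stderr understates the slope error when the weights are
    ## themselves estimated from few replicates and the abscissae carry fit
    ## noise; a leave-one-condition-out jackknife is robust to both, so the
    ## larger of the two is reported
    if (length(condTm) >= 4L) {
      jk <- vapply(seq_along(condTm), function(i) {
        kirchhoffFit(condTm[-i], condDH[-i], se[-i])$dCp
      }, numeric(1))
      nj <- length(jk)
      jkSe <- sqrt((nj - 1) / nj * sum((jk - mean(jk))^2))
      kh$stderr <- max(kh$stderr, jkSe)
    }
    kirchhoffs[[cpx]] <- kh
    if (length(refRows) < 2L) {
      qc <- rbind(qc, data.frame(well = cpx, reason = "too_few_reference_replicates",
                                 stringsAsFactors = FALSE))
      next
    }
    n <- length(refRows)
    params[[cpx]] <- StabilityParams(
      meta$protein[refRows[1]], meta$ligand[refRows[1]],
      tm = mean(aggTm[refRows]), tmSem = sd(aggTm[refRows]) / sqrt(n),
      dHm = mean(aggDH[refRows]), dHmSem = sd(aggDH[refRows]) / sqrt(n),
      dCp = kh$dCp, dCpStderr = kh$stderr, nReplicates = n)
  }
  list(fits = fits, refined = refined, params = params, qc = qc,
       kirchhoff = kirchhoffs)
}

#' Pairwise ddG for every protein on a parameter table
#'
#' For each protein with exactly two complexes, computes ddG(A - B) at the
#' given temperature with A and B in the stated order (default: ligand
#' labels in alphabetical order, so "alpha-..." minus "gamma-...").
#'
#' @param params list of \linkS4class{StabilityParams}
#' @param T evaluation temperature, K
#' @param ligandA optional ligand label to use as A for every protein
#' @return list of \linkS4class{DDGResult}
#' @export
ddgTable <- function(params, T = 300, ligandA = NULL) {
  prot <- vapply(params, function(p) p@protein, character(1))
  lig <- vapply(params, function(p) p@ligand, character(1))
  if (anyDuplicated(paste(prot, lig))) dataError("duplicate complex labels in parameter set")
  out <- list()
  for (pr in unique(prot)) {
    i <- which(prot == pr)
    if (length(i) < 2L) dataError(sprintf("protein '%s' has fewer than 2 complexes", pr))
    if (length(i) > 2L) dataError(sprintf("protein '%s' has more than 2 complexes; ddG pairs are ambiguous", pr))
    i <- i[order(lig[i])]
    if (!is.null(ligandA) && ligandA %in% lig[i]) i <- i[order(lig[i] != ligandA)]
    out[[pr]] <- deltaDeltaG(params[[i[1]]], params[[i[2]]], T = T)
  }
  out
}

## ---------------------------------------------------------------------------
## File-based stages
## ---------------------------------------------------------------------------

writeRunConfig <- function(outDir, stage, settings) {
  settings$stage <- stage
  settings$package_version <- as.character(utils::packageVersion("dsfddg"))
  yaml::write_yaml(settings, file.path(outDir, "run_config.yaml"))
}

#' Stage 1: simulate a plate to disk
#'
#' Writes \code{curves.csv}, \code{layout.csv} and \code{truth.json} (the
#' generator ground truth) into \code{outDir}.
#'
#' @param spec a \linkS4class{SyntheticSpec}, or the path of a YAML/JSON
#'   file with fields matching [syntheticSpec()] arguments
#' @param outDir output directory (created if missing)
#' @return invisibly, the generated plate
#' @export
runSimulate <- function(spec, outDir) {
  if (is.character(spec)) spec <- specFromFile(spec)
  stopifnot(methods::is(spec, "SyntheticSpec"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  gen <- generatePlate(spec)
  writePlateCsv(gen$plate, file.path(outDir, "curves.csv"),
                file.path(outDir, "layout.csv"))
  jsonlite::write_json(gen$truth, file.path(outDir, "truth.json"),
                       dataframe = "rows", digits = NA)
  writeRunConfig(outDir, "simulate",
                 list(seed = spec@seed, wells = ncol(gen$plate)))
  message(sprintf("simulated %d wells (seed %d) -> %s", ncol(gen$plate),
                  spec@seed, outDir))
  invisible(gen$plate)
}

specFromFile <- function(path) {
  vals <- if (grepl("[.]json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  if (!is.null(vals$complexes)) vals$complexes <- as.data.frame(vals$complexes)
  tryCatch(do.call(syntheticSpec, vals),
           error = function(e) usageError(sprintf("invalid synthetic spec '%s': %s",
                                                  path, conditionMessage(e))))
}

configFromFile <- function(path) {
  if (is.null(path)) return(analysisConfig())
  vals <- if (grepl("[.]json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  ## accept the documented snake_case keys
  map <- c(plateau_fraction = "plateauFraction", fu_window = "fuWindow",
           r2_floor = "r2Floor", epsilon_clamp = "epsilonClamp",
           min_points = "minPoints", amp_ratio_floor = "ampRatioFloor",
           reference_temperature = "referenceTemperature")
  names(vals) <- ifelse(names(vals) %in% names(map), map[names(vals)], names(vals))
  do.call(analysisConfig, vals)
}

#' Stage 2: fit a plate from disk
#'
#' Writes \code{vant_hoff.tsv} (per-curve fits), \code{stability_params.tsv}
#' (per-complex parameters) and \code{qc.tsv} (flagged wells/conditions).
#'
#' @param curvesPath,layoutPath plate CSV files (see [readPlateCsv()])
#' @param outDir output directory
#' @param configPath optional YAML/JSON analysis settings
#' @return invisibly, the [fitPlate()] result
#' @export
runFit <- function(curvesPath, layoutPath, outDir, configPath = NULL) {
  config <- configFromFile(configPath)
  plate <- readPlateCsv(curvesPath, layoutPath)
  res <- fitPlate(plate, config = config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeFitTable(unname(res$fits), file.path(outDir, "vant_hoff.tsv"),
                kind = "VantHoffFit")
  writeFitTable(unname(res$params), file.path(outDir, "stability_params.tsv"),
                kind = "StabilityParams")
  writeTsv(res$qc, file.path(outDir, "qc.tsv"))
  writeRunConfig(outDir, "fit", config)
  message(sprintf("fitted %d wells -> %d complex parameter set(s); %d QC entries",
                  length(res$fits), length(res$params), nrow(res$qc)))
  invisible(res)
}

#' Stage 3: ddG between ligand complexes from a parameter table
#'
#' Reads \code{stability_params.tsv} (as written by [runFit()] or typed in
#' by hand from published values) and writes \code{ddg.tsv} with one row per
#' protein.
#'
#' @param paramsPath stability-parameter TSV
#' @param outDir output directory
#' @param temperature evaluation temperature, K
#' @param ligandA optional ligand label to place first in the difference
#' @return invisibly, the list of \linkS4class{DDGResult}
#' @export
runDdg <- function(paramsPath, outDir, temperature = 300, ligandA = NULL) {
  records <- readFitTable(paramsPath)
  if (!identical(attr(records, "kind"), "StabilityParams")) {
    usageError(sprintf("'%s' is not a stability-parameter table", paramsPath))
  }
  if (length(records) < 2L) dataError("need at least 2 complexes for a ddG")
  res <- ddgTable(records, T = temperature, ligandA = ligandA)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeFitTable(unname(res), file.path(outDir, "ddg.tsv"), kind = "DDGResult")
  writeRunConfig(outDir, "ddg",
                 list(temperature = temperature, ligand_a = ligandA))
  invisible(res)
}

#' Stage 4: toy alchemical transformation to disk
#'
#' Runs a forward/backward thermodynamic integration on a harmonic toy
#' system and writes per-lambda traces (\code{ti_trace.tsv}) and the summary
#' (\code{ti_result.tsv}).
#'
#' @param sys a \linkS4class{ToyAlchemicalSystem}, or the path of a YAML
#'   file with fields \code{k0}, \code{k1} and optionally \code{temperature}
#' @param outDir output directory
#' @param nLambda number of lambda points
#' @param nSteps Metropolis steps per lambda
#' @param seed master seed
#' @return invisibly, the \linkS4class{TIResult}
#' @export
runAlchemy <- function(sys, outDir, nLambda = 7L, nSteps = 10000L, seed = 1L) {
  if (is.character(sys)) {
    vals <- yaml::read_yaml(sys)
    if (is.null(vals$k0) || is.null(vals$k1)) {
      usageError("alchemy system file needs fields k0 and k1")
    }
    sys <- harmonicSystem(vals$k0, vals$k1,
                          temperature = vals$temperature %||% (1 / RGAS))
  }
  res <- runTransformation(sys, lambdaSchedule(nLambda), nSteps = nSteps,
                           seed = seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  trace <- data.frame(lambda = fmtNum(res@lambda),
                      dhdl_forward = fmtNum(res@dhdlForward),
                      dhdl_forward_se = fmtNum(res@dhdlForwardSe),
                      dhdl_backward = fmtNum(res@dhdlBackward),
                      dhdl_backward_se = fmtNum(res@dhdlBackwardSe))
  writeTsv(trace, file.path(outDir, "ti_trace.tsv"))
  summaryDf <- data.frame(dg_forward = fmtNum(res@dGForward),
                          dg_backward = fmtNum(res@dGBackward),
                          dg_combined = fmtNum(res@dGCombined),
                          dg_stderr = fmtNum(res@dGStderr),
                          hysteresis = fmtNum(res@hysteresis))
  writeTsv(summaryDf, file.path(outDir, "ti_result.tsv"))
  writeRunConfig(outDir, "alchemy",
                 list(n_lambda = nLambda, n_steps = nSteps, seed = seed))
  invisible(res)
}
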
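## Plate-reader CSV reading/writing and deterministic fit tables.
##
## Curve files are wide CSVs: first column the temperature ramp, one column
## per well. The temperature unit is declared in the header: a first column
## named "temperature_C" (degrees Celsius) or "temperature_K" (Kelvin).
## Everything downstream of this boundary is Kelvin.

#' Read a plate of melting curves from CSV
#'
#' @param curvePath wide CSV: first column \code{temperature_C} or
#'   \code{temperature_K}, then one column per well.
#' @param layoutPath CSV mapping wells to conditions; columns \code{well},
#'   \code{protein}, \code{ligand}, \code{urea}, \code{replicate} in any
#'   order.
#' @return a \linkS4class{DSFPlate} containing the wells present in both
#'   files. Wells listed in the layout but absent from the curve file are
#'   reported as warnings.
#' @examples
#' spec <- syntheticSpec(replicates = 1L, ureaLevels = 0)
#' paths <- file.path(tempdir(), c("curves.csv", "layout.csv"))
#' writePlateCsv(generatePlate(spec)$plate, paths[1], paths[2])
#' plate <- readPlateCsv(paths[1], paths[2])
#' @export
readPlateCsv <- function(curvePath, layoutPath) {
  curves <- read.csv(curvePath, check.names = FALSE)
  if (ncol(curves) < 2L) dataError("curve file must have a temperature column and at least one well")
  unitCol <- names(curves)[1]
  tt <- as.numeric(curves[[1]])
  if (identical(unitCol, "temperature_C")) {
    tt <- tt + 273.15
  } else if (!identical(unitCol, "temperature_K")) {
    dataError(sprintf(
      "unknown temperature unit header '%s' (expected 'temperature_C' or 'temperature_K')",
      unitCol))
  }
  if (anyNA(tt)) dataError("temperature column contains non-numeric values")
  if (any(diff(tt) <= 0)) {
    dataError("temperature column is not strictly increasing")
  }
  wells <- names(curves)[-1]
  fmat <- as.matrix(curves[, -1, drop = FALSE])
  storage.mode(fmat) <- "double"
  bad <- wells[colSums(!is.finite(fmat)) > 0]
  if (length(bad)) {
    dataError(paste0("missing or non-finite fluorescence (length mismatch) in well(s): ",
                     paste(bad, collapse = ", ")))
  }

  layout <- read.csv(layoutPath, check.names = FALSE)
  missingCols <- setdiff(layoutCols, colnames(layout))
  if (length(missingCols)) {
    dataError(paste0("layout file is missing columns: ",
                     paste(missingCols, collapse = ", ")))
  }
  layout <- layout[, layoutCols]  # reader independent of layout column order
  layout$well <- as.character(layout$well)
  if (anyDuplicated(layout$well)) dataError("duplicate well ids in layout")

  orphans <- setdiff(layout$well, wells)
  if (length(orphans)) {
    warning(sprintf("wells in layout but absent from curve file: %s",
                    paste(orphans, collapse = ", ")), call. = FALSE)
  }
  unknown <- setdiff(wells, layout$well)
  if (length(unknown)) {
    warning(sprintf("wells in curve file but absent from layout (dropped): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
  keep <- intersect(wells, layout$well)
  if (!length(keep)) dataError("no well appears in both curve and layout files")
  DSFPlate(fmat[, keep, drop = FALSE], tt, layout)
}

#' Write a plate to curve + layout CSV files
#'
#' Inverse of [readPlateCsv()]; temperatures are written in Kelvin with a
#' \code{temperature_K} header, at full precision.
#'
#' @param plate a \linkS4class{DSFPlate}
#' @param curvePath,layoutPath output file paths
#' @return invisibly, the two paths
#' @export
writePlateCsv <- function(plate, curvePath, layoutPath) {
  stopifnot(methods::is(plate, "DSFPlate"))
  fmat <- fluorescence(plate)
  df <- data.frame(temperature_K = fmtNum(temperatures(plate)),
                   check.names = FALSE)
  for (w in colnames(fmat)) df[[w]] <- fmtNum(fmat[, w])
  write.csv2ish(df, curvePath)
  write.csv2ish(plateLayout(plate), layoutPath)
  invisible(c(curvePath, layoutPath))
}

## plain deterministic CSV writer (no quoting surprises, no row names)
write.csv2ish <- function(df, path) {
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
}

## ---------------------------------------------------------------------------
## Fit tables (TSV)
## ---------------------------------------------------------------------------

## Fixed column orders; numbers serialised at full double precision so that a
## write -> read -> write cycle is byte-identical.
fitTableSchema <- list(
  VantHoffFit = c("protein", "ligand", "urea", "replicate", "well", "tm_K",
                  "dH_vH_kcal_mol", "dH_vH_stderr", "slope_stderr_K",
                  "n_points", "r_squared", "window_low_K", "window_high_K",
                  "flag"),
  StabilityParams = c("protein", "ligand", "tm_K", "tm_sem_K",
                      "dHm_kcal_mol", "dHm_sem", "dCp_kcal_mol_K",
                      "dCp_stderr", "n_replicates"),
  DDGResult = c("protein", "ligand_a", "ligand_b", "temperature_K",
                "ddg_kcal_mol", "sigma_kcal_mol", "convention")
)

recordRow <- function(x) {
  if (methods::is(x, "VantHoffFit")) {
    data.frame(protein = x@protein, ligand = x@ligand, urea = x@urea,
               replicate = x@replicate, well = x@wellId, tm_K = x@tm,
               dH_vH_kcal_mol = x@dHvH, dH_vH_stderr = x@dHvHStderr,
               slope_stderr_K = x@slopeStderr, n_points = x@nPoints,
               r_squared = x@rSquared,
               window_low_K = x@window[1], window_high_K = x@window[2],
               flag = x@flag, stringsAsFactors = FALSE)
  } else if (methods::is(x, "StabilityParams")) {
    data.frame(protein = x@protein, ligand = x@ligand, tm_K = x@tm,
               tm_sem_K = x@tmSem, dHm_kcal_mol = x@dHm, dHm_sem = x@dHmSem,
               dCp_kcal_mol_K = x@dCp, dCp_stderr = x@dCpStderr,
               n_replicates = x@nReplicates, stringsAsFactors = FALSE)
  } else if (methods::is(x, "DDGResult")) {
    data.frame(protein = x@protein, ligand_a = x@ligandA,
               ligand_b = x@ligandB, temperature_K = x@temperature,
               ddg_kcal_mol = x@ddg, sigma_kcal_mol = x@sigma,
               convention = x@convention, stringsAsFactors = FALSE)
  } else {
    usageError(sprintf("unsupported record class '%s'", class(x)[1]))
  }
}

#' Write a homogeneous collection of fit records to a TSV file
#'
#' Columns follow a fixed, documented order per record kind; numeric values
#' are written at full double precision; rows are sorted by protein, ligand,
#' urea and replicate (where present) so output is deterministic. An empty
#' collection still needs a declared \code{kind} to emit the header.
#'
#' @param records list of \linkS4class{VantHoffFit},
#'   \linkS4class{StabilityParams} or \linkS4class{DDGResult} objects (all of
#'   one kind)
#' @param path output TSV path
#' @param kind record kind for empty collections; ignored (inferred)
#'   otherwise
#' @return invisibly, the written data.frame
#' @export
writeFitTable <- function(records, path, kind = NULL) {
  if (methods::is(records, "VantHoffFit") || methods::is(records, "StabilityParams") ||
      methods::is(records, "DDGResult")) {
    records <- list(records)
  }
  if (!length(records)) {
    if (is.null(kind) || !kind %in% names(fitTableSchema)) {
      usageError("empty collection: supply kind = 'VantHoffFit', 'StabilityParams' or 'DDGResult'")
    }
    df <- as.data.frame(setNames(rep(list(character(0)), length(fitTableSchema[[kind]])),
                                 fitTableSchema[[kind]]))
    writeTsv(df, path)
    return(invisible(df))
  }
  classes <- unique(vapply(records, function(x) class(x)[1], character(1)))
  if (length(classes) != 1L) {
    usageError(paste0("mixed record kinds in one table: ",
                      paste(classes, collapse = ", ")))
  }
  df <- do.call(rbind, lapply(records, recordRow))
  ord <- do.call(order, lapply(intersect(c("protein", "ligand", "urea", "replicate"),
                                         colnames(df)),
                               function(cn) df[[cn]]))
  df <- df[ord, , drop = FALSE]
  out <- df
  for (cn in colnames(out)) {
    if (is.numeric(out[[cn]]) && !is.integer(out[[cn]])) out[[cn]] <- fmtNum(out[[cn]])
  }
  writeTsv(out, path)
  invisible(df)
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
}

#' Read a fit table written by [writeFitTable()]
#'
#' The record kind is inferred from the header.
#'
#' @param path TSV path
#' @return list of record objects (possibly empty), with attribute
#'   \code{kind}
#' @export
readFitTable <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  kind <- NULL
  for (k in names(fitTableSchema)) {
    if (identical(colnames(df), fitTableSchema[[k]])) kind <- k
  }
  if (is.null(kind)) dataError(sprintf("unrecognised fit-table header in '%s'", path))
  records <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    switch(kind,
      VantHoffFit = methods::new("VantHoffFit", wellId = as.character(r$well),
        protein = as.character(r$protein), ligand = as.character(r$ligand),
        urea = as.numeric(r$urea), replicate = as.integer(r$replicate),
        tm = as.numeric(r$tm_K), dHvH = as.numeric(r$dH_vH_kcal_mol),
        dHvHStderr = as.numeric(r$dH_vH_stderr),
        slopeStderr = as.numeric(r$slope_stderr_K),
        nPoints = as.integer(r$n_points), rSquared = as.numeric(r$r_squared),
        window = c(as.numeric(r$window_low_K), as.numeric(r$window_high_K)),
        flag = as.character(r$flag)),
      StabilityParams = StabilityParams(r$protein, r$ligand,
        tm = r$tm_K, tmSem = r$tm_sem_K, dHm = r$dHm_kcal_mol,
        dHmSem = r$dHm_sem, dCp = r$dCp_kcal_mol_K, dCpStderr = r$dCp_stderr,
        nReplicates = r$n_replicates),
      DDGResult = methods::new("DDGResult", protein = as.character(r$protein),
        ligandA = as.character(r$ligand_a), ligandB = as.character(r$ligand_b),
        temperature = as.numeric(r$temperature_K),
        ddg = as.numeric(r$ddg_kcal_mol), sigma = as.numeric(r$sigma_kcal_mol),
        convention = as.character(r$convention)))
  })
  attr(records, "kind") <- kind
  records
}
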
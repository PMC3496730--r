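## Synthetic DSF plate generator with known ground truth.
##
## Stability model per complex: Gibbs-Helmholtz surface anchored at the 0 M
## melting point plus a linear-extrapolation denaturant term,
##   dG(T, c) = dHm0 (1 - T/Tm0) - dCp [(Tm0 - T) + T ln(T/Tm0)] - m c (T/Tm0).
## The denaturant term scales with T (purely entropic destabilisation) so the
## van't Hoff enthalpy stays exactly Kirchhoff-consistent at every urea level,
## dH(Tm(c)) = dHm0 + dCp (Tm(c) - Tm0); m equals the m-value exactly at Tm0.
## Signal model: two drifting linear baselines mixed by the fraction
## unfolded, plus i.i.d. Gaussian noise; optional post-transition dye decay.

#' Build a synthetic plate specification
#'
#' Defaults emulate a two-complex tocopherol-binding study design: a 96-well
#' plate scanned 20-99 degC at 1 degC steps, 8 urea levels (0-3 M), 4
#' replicates per condition, and ground-truth stability parameters for a
#' wild-type protein bound to alpha- or gamma-tocopherol (Tm 336.73/334.65 K,
#' dHm 159.15/138.28 kcal/mol, dCp 7.12/10.45 kcal/mol/K). The default noise
#' s.d. is 1\% of the signal amplitude. The denaturant m-values (1.0 and 0.4
#' kcal/mol/M) are chosen so that every condition keeps a folded baseline
#' within the scan: each complex's maximum stability (5.2 and 2.7 kcal/mol
#' near 315/322 K) caps how much destabilisation the plate design can absorb
#' while remaining two-state-analysable.
#'
#' @param complexes data.frame with columns \code{protein}, \code{ligand},
#'   \code{tm0} (K), \code{dHm0} (kcal/mol), \code{dCp} (kcal/mol/K),
#'   \code{mUrea} (kcal/mol/M)
#' @param ureaLevels urea concentrations, M
#' @param replicates replicates per condition
#' @param tStart,tEnd,tStep temperature ramp, K
#' @param fFoldedBase,fUnfoldedBase baseline intercepts at \code{tStart}, a.u.
#' @param slopeFolded,slopeUnfolded baseline slopes, a.u./K
#' @param noiseSigma Gaussian noise s.d., a.u.
#' @param decayRate post-transition dye-decay rate, 1/K (0 = off)
#' @param decayOnset decay onset temperature, K
#' @param seed master seed; every well derives its own stream from it
#' @return a \linkS4class{SyntheticSpec}
#' @export
syntheticSpec <- function(
    complexes = data.frame(
      protein = c("WT", "WT"),
      ligand = c("alpha-T", "gamma-T"),
      tm0 = c(336.73, 334.65),
      dHm0 = c(159.15, 138.28),
      dCp = c(7.12, 10.45),
      mUrea = c(1.0, 0.4)),
    ureaLevels = c(0, 0.25, 0.5, 1, 1.5, 2, 2.5, 3),
    replicates = 4L,
    tStart = 293.15, tEnd = 372.15, tStep = 1,
    fFoldedBase = 100, fUnfoldedBase = 1100,
    slopeFolded = 0.5, slopeUnfolded = 0.2,
    noiseSigma = 0.01 * (fUnfoldedBase - fFoldedBase),
    decayRate = 0, decayOnset = 360,
    seed = 20120913L) {
  methods::new("SyntheticSpec", complexes = as.data.frame(complexes),
               ureaLevels = as.numeric(ureaLevels),
               replicates = as.integer(replicates),
               tStart = tStart, tEnd = tEnd, tStep = tStep,
               fFoldedBase = fFoldedBase, fUnfoldedBase = fUnfoldedBase,
               slopeFolded = slopeFolded, slopeUnfolded = slopeUnfolded,
               noiseSigma = noiseSigma, decayRate = decayRate,
               decayOnset = decayOnset, seed = as.integer(seed))
}

complexRow <- function(spec, complex) {
  key <- paste(spec@complexes$protein, spec@complexes$ligand, sep = ":")
  i <- match(complex, key)
  if (is.na(i)) usageError(sprintf("unknown complex '%s' (have: %s)", complex,
                                   paste(key, collapse = ", ")))
  spec@complexes[i, ]
}

#' Ground-truth unfolding free energy of a synthetic complex
#'
#' dG(T, c) = dHm0 (1 - T/Tm0) - dCp [(Tm0 - T) + T ln(T/Tm0)] - m c (T/Tm0).
#' The denaturant term is linear in concentration (constant m-value at the
#' reference melting point) and proportional to T, i.e. the destabilisation
#' is entropic and leaves the unfolding enthalpy untouched.
#'
#' @param spec a \linkS4class{SyntheticSpec}
#' @param complex complex key, \code{"protein:ligand"}
#' @param T temperature(s), K
#' @param urea denaturant concentration, M
#' @return dG of unfolding, kcal/mol
#' @export
trueStability <- function(spec, complex, T, urea = 0) {
  cx <- complexRow(spec, complex)
  if (any(T <= 0)) usageError("temperature must be positive (Kelvin)")
  gibbsHelmholtz(cx$tm0, T, dHm = cx$dHm0, dCp = cx$dCp) -
    cx$mUrea * urea * (T / cx$tm0)
}

#' Ground-truth melting point of a synthetic complex at a urea level
#'
#' Root of dG(T, c) = 0 on the heat-transition side, bracketed from the 0 M
#' melting point downward.
#'
#' @inheritParams trueStability
#' @return Tm(c) in K, or NA if the folded state never dominates (no root)
#' @export
trueTm <- function(spec, complex, urea = 0) {
  cx <- complexRow(spec, complex)
  f <- function(T) trueStability(spec, complex, T, urea)
  upper <- cx$tm0 + 1
  ## temperature of maximum stability (dS = 0): below it is the cold branch
  tMaxStab <- cx$tm0 * exp(-cx$dHm0 / (cx$tm0 * cx$dCp))
  if (f(tMaxStab) <= 0) return(NA_real_)
  uniroot(f, lower = tMaxStab, upper = upper, tol = 1e-9)$root
}

#' Ground-truth van't Hoff enthalpy at the shifted melting point
#'
#' Kirchhoff consistency of the generator: dH(Tm(c)) = dHm0 + dCp (Tm(c) -
#' Tm0), which is what the van't Hoff fit recovers on noiseless curves.
#'
#' @inheritParams trueStability
#' @return enthalpy in kcal/mol (NA when no melting point exists)
#' @export
trueDH <- function(spec, complex, urea = 0) {
  cx <- complexRow(spec, complex)
  tmc <- trueTm(spec, complex, urea)
  cx$dHm0 + cx$dCp * (tmc - cx$tm0)
}

#' Simulate one melting curve
#'
#' Deterministic given (seed, complex, urea, replicate): the well's RNG
#' stream is derived by hashing those identifiers with the master seed, so
#' regenerating any single well reproduces it exactly.
#'
#' @param spec a \linkS4class{SyntheticSpec}
#' @param complex complex key \code{"protein:ligand"}
#' @param urea denaturant concentration, M
#' @param replicate replicate index
#' @param wellId well label for the curve (default derived from indices)
#' @return a \linkS4class{MeltingCurve}
#' @export
simulateCurve <- function(spec, complex, urea, replicate, wellId = NULL) {
  cx <- complexRow(spec, complex)
  tt <- seq(spec@tStart, spec@tEnd, by = spec@tStep)
  dg <- trueStability(spec, complex, tt, urea)
  K <- exp(-dg / (RGAS * tt))
  fu <- K / (1 + K)
  fFolded <- spec@fFoldedBase + spec@slopeFolded * (tt - spec@tStart)
  fUnfolded <- spec@fUnfoldedBase + spec@slopeUnfolded * (tt - spec@tStart)
  if (spec@decayRate > 0) {
    fUnfolded <- fUnfolded * exp(-spec@decayRate * pmax(0, tt - spec@decayOnset))
  }
  signal <- fFolded * (1 - fu) + fUnfolded * fu
  noise <- if (spec@noiseSigma > 0) {
    streamSeed <- deriveSeed(spec@seed, sprintf("%s|%.6g|%d", complex, urea, replicate))
    withSeed(streamSeed, rnorm(length(tt), 0, spec@noiseSigma))
  } else 0
  methods::new("MeltingCurve",
               wellId = wellId %||% sprintf("%s_u%g_r%d", complex, urea, replicate),
               temperature = tt, fluorescence = signal + noise,
               protein = as.character(cx$protein),
               ligand = as.character(cx$ligand), urea = as.numeric(urea),
               replicate = as.integer(replicate))
}

#' Generate a full synthetic plate with ground truth
#'
#' One curve per (complex x urea x replicate), laid out row-major on a
#' 96-well plate (A1..H12). Alongside the plate, a ground-truth table gives
#' the true melting point and enthalpy at every condition for use as a test
#' oracle.
#'
#' @param spec a \linkS4class{SyntheticSpec}
#' @return list with \code{plate} (a \linkS4class{DSFPlate}) and
#'   \code{truth} (data.frame: protein, ligand, urea, tmTrue, dHTrue)
#' @export
generatePlate <- function(spec) {
  stopifnot(methods::is(spec, "SyntheticSpec"))
  methods::validObject(spec)
  nWells <- nrow(spec@complexes) * length(spec@ureaLevels) * spec@replicates
  if (nWells > 96L) {
    dataError(sprintf("design needs %d wells; a plate has 96", nWells))
  }
  wellNames <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, times = 8))
  curves <- vector("list", nWells)
  layout <- vector("list", nWells)
  truth <- list()
  k <- 0L
  for (i in seq_len(nrow(spec@complexes))) {
    cx <- spec@complexes[i, ]
    complex <- paste(cx$protein, cx$ligand, sep = ":")
    for (u in spec@ureaLevels) {
      truth[[length(truth) + 1L]] <- data.frame(
        protein = cx$protein, ligand = cx$ligand, urea = u,
        tmTrue = trueTm(spec, complex, u), dHTrue = trueDH(spec, complex, u))
      for (r in seq_len(spec@replicates)) {
        k <- k + 1L
        curves[[k]] <- simulateCurve(spec, complex, u, r, wellId = wellNames[k])
        layout[[k]] <- data.frame(well = wellNames[k], protein = cx$protein,
                                  ligand = cx$ligand, urea = u, replicate = r)
      }
    }
  }
  fmat <- vapply(curves, fluorescence, numeric(length(temperatures(curves[[1]]))))
  colnames(fmat) <- vapply(curves, function(cv) cv@wellId, character(1))
  list(plate = DSFPlate(fmat, temperatures(curves[[1]]), do.call(rbind, layout)),
       truth = do.call(rbind, truth))
}
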
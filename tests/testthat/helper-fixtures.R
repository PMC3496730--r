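# Shared fixtures, all generated in code.

# Published-style stability parameters for the two proteins, used wherever a
# known parameter set is needed (ddG checks, Gibbs-Helmholtz identities).
table1Params <- function() {
  list(
    wtAlpha = StabilityParams("WT", "alpha-T", tm = 336.73, dHm = 159.15,
                              dCp = 7.12, tmSem = 0.72, dHmSem = 2.90,
                              dCpStderr = 0.79, nReplicates = 4L),
    wtGamma = StabilityParams("WT", "gamma-T", tm = 334.65, dHm = 138.28,
                              dCp = 10.45, tmSem = 0.87, dHmSem = 11.94,
                              dCpStderr = 1.33, nReplicates = 4L),
    mutAlpha = StabilityParams("A156L", "alpha-T", tm = 335.15, dHm = 136.15,
                               dCp = 7.21, tmSem = 0.25, dHmSem = 2.61,
                               dCpStderr = 0.65, nReplicates = 4L),
    mutGamma = StabilityParams("A156L", "gamma-T", tm = 334.53, dHm = 172.29,
                               dCp = 7.51, tmSem = 0.13, dHmSem = 1.98,
                               dCpStderr = 0.88, nReplicates = 4L))
}

# An ideal noiseless sigmoid between flat plateaus: the local two-state model
# with constant enthalpy, flat baselines fLow/fHigh.
idealCurve <- function(tmTrue = 330, dH = 150, fLow = 100, fHigh = 1100,
                       tStart = 293.15, tEnd = 372.15, tStep = 1,
                       noise = 0, seed = 1L) {
  tt <- seq(tStart, tEnd, by = tStep)
  lnK <- -dH / dsfddg::RGAS * (1 / tt - 1 / tmTrue)
  fu <- 1 / (1 + exp(-lnK))
  f <- fLow * (1 - fu) + fHigh * fu
  if (noise > 0) {
    f <- f + withr::with_seed(seed, rnorm(length(tt), 0, noise))
  }
  methods::new("MeltingCurve", wellId = "A1", temperature = tt,
               fluorescence = f, protein = "P", ligand = "L", urea = 0,
               replicate = 1L)
}

# Single-complex generator spec (WT:alpha-T ground truth).
alphaOnlySpec <- function(seed = 1L, noiseSigma = 10, ureaLevels = 0,
                          replicates = 4L) {
  syntheticSpec(
    complexes = data.frame(protein = "WT", ligand = "alpha-T", tm0 = 336.73,
                           dHm0 = 159.15, dCp = 7.12, mUrea = 1.0),
    ureaLevels = ureaLevels, replicates = replicates,
    noiseSigma = noiseSigma, seed = seed)
}
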
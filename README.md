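# dsfddg

Thermodynamic analysis of protein thermal-shift (differential scanning
fluorimetry, DSF) experiments, from raw plate-reader melting curves to the
relative binding free energy between two ligand complexes — plus a
desk-scale thermodynamic-integration module that validates the alchemical
free-energy formalism on systems with closed-form answers.

**Who it is for.** Anyone ranking ligands of a purified protein by thermal
shift: the motivating system is a tocopherol (vitamin E) transfer protein
whose selectivity between the alpha and gamma congeners is quantified by
comparing the stability of the two complexes.

## The science in brief

Each melting curve is treated as a two-state unfolding equilibrium reported
by a thiol-reactive dye. With baseline levels `F_min`/`F_max`, the fraction
unfolded is `f_u = (F - F_min)/(F_max - F_min)`, the equilibrium constant
`K = f_u/(1 - f_u)`, and

- **Tm** — the `K = 1` midpoint, interpolated;
- **van't Hoff enthalpy** — `dH = -R * slope` of `ln K` vs `1/T` over the
  transition window (`f_u` in [0.2, 0.8]);
- **heat-capacity change** — the weighted slope of `dH` against `Tm` across
  a series of urea-shifted melting points (Kirchhoff relation);
- **Gibbs-Helmholtz extrapolation** —
  `dG(T) = dHm (1 - T/Tm) - dCp [(Tm - T) + T ln(T/Tm)]`;
- **ddG** — `dG_A(T) - dG_B(T)` at a reference temperature (default 300 K),
  with first-order error propagation. Positive values mean ligand A binds
  more tightly (assuming the ligand does not bind the denatured state).

A synthetic plate generator with exactly known ground truth (96-well design,
20-99 °C ramp, 8 urea levels, 4 replicates, 1% noise) makes every stage
testable without instrument data, and a toy alchemical module implements
linear-coupling thermodynamic integration with Metropolis sampling,
forward/backward hysteresis balancing and the binding thermodynamic cycle,
validated against `(RT/2) ln(k1/k0)` for harmonic systems.

## Worked example

Published-style parameters in, relative binding free energy out:

```r
library(dsfddg)
a <- StabilityParams("WT", "alpha-T", tm = 336.73, dHm = 159.15, dCp = 7.12,
                     tmSem = 0.72, dHmSem = 2.90, dCpStderr = 0.79)
g <- StabilityParams("WT", "gamma-T", tm = 334.65, dHm = 138.28, dCp = 10.45,
                     tmSem = 0.87, dHmSem = 11.94, dCpStderr = 1.33)
deltaDeltaG(a, g, T = 300)
#> DDGResult WT: ddG(alpha-T - gamma-T) at 300.0 K = 7.66 +/- 3.30 kcal/mol
#>   ddG = dG_unfold(A) - dG_unfold(B); positive = ligand A binds more tightly; ...
```

The 7.66 kcal/mol says the alpha complex is the more stable (tighter-binding)
one at 300 K; the +/- 3.30 is dominated by extrapolating ~35 K below the
melting points.

Full pipeline on a simulated plate (64 wells, two complexes):

```r
gen <- generatePlate(syntheticSpec(seed = 42L))   # ground truth known
res <- fitPlate(gen$plate)
res$params[["WT:alpha-T"]]
#> StabilityParams WT:alpha-T
#>   Tm   =   336.72 +/- 0.01 K (SEM, n = 4)
#>   dHm  =   158.53 +/- 0.37 kcal/mol (SEM)
#>   dCp  =     7.14 +/- 0.18 kcal/mol/K (slope stderr)
ddgTable(res$params, T = 300)[["WT"]]
#> DDGResult WT: ddG(alpha-T - gamma-T) at 300.0 K = 7.77 +/- 1.09 kcal/mol
```

The generator's true parameters were Tm 336.73 K, dHm 159.15 kcal/mol,
dCp 7.12 kcal/mol/K, and the true ddG(300 K) of the simulated pair is
7.66 kcal/mol — recovered within the stated uncertainty.

From the shell, the same stages are scriptable
(`inst/scripts/dsfddg simulate | fit | ddg | alchemy`; exit codes 0/1/2 for
success / usage error / data error), each run writing its resolved
configuration alongside its outputs.

## Package layout

- `R/` — S4 classes (`DSFPlate` extends `SummarizedExperiment`;
  `MeltingCurve`, `VantHoffFit`, `StabilityParams`, `DDGResult`,
  `SyntheticSpec`, `ToyAlchemicalSystem`, `TIResult`) and the analysis,
  generator and TI code
- `vignettes/dsf-thermodynamics.Rmd` — the model, every tunable parameter
  with units and defaults, the generator's scope, numerical choices and
  limitations
- `tests/testthat/` — unit, property and end-to-end recovery tests
- `scripts/acceptance.R` — see above
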
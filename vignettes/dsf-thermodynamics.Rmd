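---
title: "Two-state DSF thermodynamics and toy alchemical free energies: methods"
author: "dsfddg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state DSF thermodynamics and toy alchemical free energies: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsfddg)
```

# The problem

Differential scanning fluorimetry (DSF) follows protein unfolding along a
temperature ramp through a dye whose fluorescence rises as buried residues
(here, cysteine thiols) become solvent-exposed. For a ligand-binding protein,
the stabilisation that a ligand confers on the native state shifts the melting
transition; comparing the unfolding free energies of two ligand complexes at a
common temperature yields their relative binding free energy, provided the
ligand does not bind the denatured state. This package implements that
analysis chain for plate-reader melting curves, a synthetic plate generator
with known ground truth, and a small thermodynamic-integration module that
validates the alchemical free-energy formalism against closed-form results.

# The two-state model

Each well is modelled as a two-state (folded/unfolded) equilibrium reported by
two fluorescence baselines. With plateau levels $F_{\min}$ and $F_{\max}$ the
fraction unfolded is

$$f_u(T) = \frac{F(T) - F_{\min}}{F_{\max} - F_{\min}},\qquad
K(T) = \frac{f_u}{1 - f_u},$$

clamped to $[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-6}$ so
logarithms stay finite. The melting temperature $T_m$ is the $K = 1$
crossing. The van't Hoff relation gives the unfolding enthalpy from the local
temperature dependence of $K$,

$$\ln K = \mathrm{const} - \frac{\Delta H_{vH}}{R}\cdot\frac{1}{T},$$

fitted by ordinary least squares over the transition window. Across a series
of denaturant-shifted melting points, the Kirchhoff relation
$\Delta C_p = \mathrm{d}\Delta H/\mathrm{d}T_m$ is estimated as the slope of
the weighted line of $\Delta H_{vH}$ against $T_m$. Stability away from the
melting point follows the Gibbs-Helmholtz expression

$$\Delta G(T) = \Delta H_m\left(1 - \frac{T}{T_m}\right)
  - \Delta C_p\left[(T_m - T) + T\ln\frac{T}{T_m}\right],$$

which vanishes at $T_m$ exactly. The relative stability of two complexes is
$\Delta\Delta G(T) = \Delta G_A(T) - \Delta G_B(T)$, with ligand A by default
the alphabetically first label so that an alpha-tocopherol complex minus a
gamma-tocopherol complex is positive when the alpha ligand binds more
tightly. All temperatures are Kelvin internally (Celsius is converted at the
file boundary) and the gas constant is fixed at
$R = 1.987204\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$ so every energy is in
kcal/mol.

```{r ddg-example}
a <- StabilityParams("WT", "alpha-T", tm = 336.73, dHm = 159.15, dCp = 7.12,
                     tmSem = 0.72, dHmSem = 2.90, dCpStderr = 0.79)
g <- StabilityParams("WT", "gamma-T", tm = 334.65, dHm = 138.28, dCp = 10.45,
                     tmSem = 0.87, dHmSem = 11.94, dCpStderr = 1.33)
deltaDeltaG(a, g, T = 300)
```

# Design choices in the curve analysis

**Baselines.** $F_{\min}$ is the median over a window of points centred on the
minimum of the median-smoothed trace; $F_{\max}$ is the median of the points
whose signal lies in the top `plateauFraction` (default 0.2) of the observed
range, restricted to temperatures past that minimum. Neither plateau is tied
to the ends of the scan, for two reasons. First, thiol-dye traces often decay
after the unfolding peak, so the last temperatures can undershoot the
unfolded plateau. Second, a marginally stable protein can be partially
cold-denatured at the start of the ramp: the parameter sets used as
generator defaults here imply maximum stabilities of only a few kcal/mol
near 315-322 K, so the folded plateau sits in the middle of the scan, not at
its left edge. A curve whose amplitude does not exceed six times the robust
point-to-point noise is flagged `no_transition` and excluded downstream.

**Midpoint.** `detectTm()` takes the *last* upward crossing of $f_u = 0.5$,
linearly interpolated between the bracketing samples, so the heat transition
is reported even when a trace starts above the midpoint (cold-denatured
tail). The instrument-style derivative-maximum estimate is available as a
cross-check (`method = "derivative"`); for symmetric transitions the two
agree within one temperature step.

**Van't Hoff window.** The fit uses the contiguous run of samples around the
detected midpoint with $f_u \in [0.2, 0.8]$ — contiguity prevents a
cold-denaturation branch from leaking into the fit. $\ln K$ diverges at the
plateaus, and the local constant-enthalpy approximation holds only near
$T_m$, hence the conventional window. With 1 K sampling and enthalpies near
160 kcal/mol the window spans only ~4 K, so when fewer than `minPoints`
(default 5) samples fall inside it the window expands symmetrically to the
five samples nearest the midpoint. Fits with $r^2$ below 0.95 are marked
`low_r2`; non-positive enthalpies are flagged `noncooperative`.

**Accuracy classes and the full-trace refinement.** Because $\Delta C_p$
curves $\ln K$ in $1/T$, the discrete 5-point window fit carries a 1-3%
enthalpy bias even on noiseless data, and plateau-level baselines are biased
whenever the folded state never fully dominates (residual $f_u$ of 2-9% for
the gamma-complex defaults). Both effects are harmless near $T_m$ but are
amplified ~2 kcal/mol per percent enthalpy error when extrapolating 35 K down
to 300 K. `fitCurveTwoState()` therefore refits each whole trace by nonlinear
least squares (Levenberg-Marquardt, via minpack.lm) against linear
folded/unfolded baselines mixed by Gibbs-Helmholtz occupancy in
$(T_m, \Delta H, \Delta C_p)$, started from the plateau-path estimates and
restarted from several $\Delta C_p$ values (2, 8, 16 kcal/mol/K) because the
per-curve likelihood can be multimodal for strongly cold-denaturing traces;
the lowest-residual solution wins. On noiseless generator plates this
estimator is exact to four decimals. `fitPlate()` uses it for aggregation by
default (`refine = TRUE`); the plateau + $\ln K$ path remains the exported
primary interface and is reported per curve in `vant_hoff.tsv`.

**Kirchhoff weighting and its uncertainty.** Condition-level replicate means
of $(T_m, \Delta H)$ enter the Kirchhoff regression with inverse-variance
weights from the replicate SEMs (falling back to equal weights when any SEM
is zero or undefined, e.g. noiseless or single-replicate data). The reported
slope uncertainty is the larger of the regression standard error and a
leave-one-condition-out jackknife: with only four replicates the estimated
weights are noisy and the abscissae carry fit error, both of which make the
naive regression stderr optimistic (about 40% too small in calibration runs),
while the jackknife restores 2-sigma coverage to ~95%.

**Condition QC.** Within a complex, a urea level whose median fitted
amplitude falls below `ampRatioFloor` (default 0.8) of the reference-level
amplitude is excluded as a truncated transition — the signature of a
denaturant concentration that has begun to abolish the folded state outright.
All per-well flags and condition exclusions are written to `qc.tsv`.

**Uncertainty of the final ddG.** First-order (delta-method) propagation
through the Gibbs-Helmholtz expression with analytic partial derivatives,
treating the six inputs ($T_m$, $\Delta H_m$, $\Delta C_p$ per complex) as
independent:
$\partial\Delta G/\partial\Delta H_m = 1 - T/T_m$,
$\partial\Delta G/\partial\Delta C_p = -[(T_m - T) + T\ln(T/T_m)]$,
$\partial\Delta G/\partial T_m = \Delta H_m T/T_m^2 - \Delta C_p(1 - T/T_m)$.
The estimates are in truth correlated through the shared Kirchhoff fit, but a
covariance structure cannot be reconstructed from per-parameter summaries, so
independence is assumed and stated here; published uncertainties produced by
an unspecified propagation are correspondingly not a quantity this package
tries to reproduce. The evaluation temperature defaults to 300 K and is
configurable; extrapolating 30+ K below the melting points is the dominant
driver of the uncertainty, which is why these error bars dwarf the
uncertainty of $T_m$ itself.

# The synthetic plate generator

`syntheticSpec()` describes a plate the way the assay is actually run: a
96-well layout scanned 20-99 °C at 1 °C steps, eight urea levels (0, 0.25,
0.5, 1, 1.5, 2, 2.5, 3 M), four replicates per condition and two ligand
complexes per protein. Ground truth per complex is a Gibbs-Helmholtz surface
anchored at the 0 M melting point plus a linear-extrapolation denaturant
term:

$$\Delta G(T, c) = \Delta H_{m,0}\Bigl(1 - \tfrac{T}{T_{m,0}}\Bigr)
 - \Delta C_p\Bigl[(T_{m,0} - T) + T\ln\tfrac{T}{T_{m,0}}\Bigr]
 - m\,c\,\frac{T}{T_{m,0}}.$$

The denaturant term is linear in concentration with a constant coefficient
$m$ (equal to the m-value exactly at $T_{m,0}$) and proportional to $T$,
i.e. the destabilisation is treated as purely entropic. This choice keeps the
surface exactly Kirchhoff-consistent at every urea level —
$\Delta H(T_m(c)) = \Delta H_{m,0} + \Delta C_p\,(T_m(c) - T_{m,0})$ — so the
apparent slope of enthalpy against melting temperature *is* $\Delta C_p$. A
temperature-independent $\Delta G$ offset would instead leak $-mc$ into the
van't Hoff enthalpy and inflate the apparent Kirchhoff slope by
$\Delta S(T_m)$, about 6% here, an identifiability subtlety worth knowing
about when interpreting real denaturant series.

The signal model mixes two drifting linear baselines (defaults: 100 and
1100 a.u. intercepts, slopes +0.5 and +0.2 a.u./K) by the equilibrium
occupancy and adds i.i.d. Gaussian noise with s.d. 1% of the amplitude, the
noise class that reproduces replicate scatter of the order seen in real
parameter tables. An optional post-transition exponential dye decay exists
(off by default) so baseline-estimation behaviour can be studied separately
from decay handling.

Default ground-truth parameters are the wild-type alpha- and
gamma-tocopherol complex values ($T_m$ 336.73/334.65 K, $\Delta H_m$
159.15/138.28 kcal/mol, $\Delta C_p$ 7.12/10.45 kcal/mol/K). The m-values
(1.0 and 0.4 kcal mol$^{-1}$ M$^{-1}$) were chosen once from the stability
surfaces themselves: each complex can only absorb as much destabilisation as
its maximum stability (5.2 and 2.7 kcal/mol respectively) before the folded
baseline disappears, so these values are the realistic range that keeps all
eight urea levels two-state-analysable while spreading the melting points
over several Kelvin. They are smaller than typical protein urea m-values —
a direct consequence of taking the published $\Delta C_p$ at face value.

Every well derives its own RNG stream by hashing (master seed, complex,
urea, replicate), so any single well can be regenerated bit-identically and
no global RNG state leaks between wells or into the caller.

What the generator does *not* emulate — and what passing recovery tests
therefore cannot certify on real data: dye-binding kinetics and
inner-filter effects, irreversible aggregation, scan-rate dependence,
well-position effects (replicate noise is the only replicate-to-replicate
difference), and three-state or non-two-state unfolding.

```{r generator-example}
gen <- generatePlate(syntheticSpec(seed = 42L))
gen$plate
head(gen$truth, 3)
```

# The toy alchemical module

The free-energy formalism used for ligand-swap calculations is implemented
on toy systems where every quantity has a closed form. Two end-state
Hamiltonians are mixed linearly, $H(\lambda) = (1-\lambda)H_A + \lambda H_B$
(dual-topology bookkeeping reduced to two full energy functions; no
soft-core is needed because toy systems have no endpoint singularities), so
$\partial H/\partial\lambda = H_B - H_A$. Equilibrium averages at fixed
$\lambda$ come from a Metropolis chain targeting $e^{-H(\lambda,x)/RT}$ with
isotropic Gaussian proposals, step size tuned during burn-in to 30-50%
acceptance and then frozen; the standard error of the mean uses ~30 batch
means, which inflates the naive error for autocorrelation. Thermodynamic
integration is trapezoidal over a uniform 7-point lambda schedule (the
conventional per-leg point count; the schedule and quadrature are
config-exposed since neither is canonical). Each transformation is run
forward (A to B) and backward (B to A, end states swapped); the combined
estimate $(\Delta G_f - \Delta G_b)/2$ balances hysteresis bias and
$|\Delta G_f + \Delta G_b|$ is reported as a convergence diagnostic. The
relative binding free energy closes the thermodynamic cycle:
`cycleDdg(dGProtein, dGWater)`.

For the 1-D harmonic pair $H_A = k_0x^2/2$, $H_B = k_1x^2/2$ the exact
answer is $(RT/2)\ln(k_1/k_0)$, and
$\langle\partial H/\partial\lambda\rangle_\lambda
= \tfrac{1}{2}(k_1-k_0)\,RT/((1-\lambda)k_0 + \lambda k_1)$ gives an exact
per-lambda oracle as well. One numerical property matters in testing: the
trapezoid rule on 7 points carries a fixed bias ($\approx 0.01\,RT$ for
$k_1/k_0 = 4$), so as sampling grows the Monte-Carlo error eventually drops
below the quadrature bias and a "within 3 stderr" comparison must either
stay in the sampling-dominated regime (gentler $k_1/k_0$ or moderate chain
lengths, as the tests do) or add the quadrature-error bound explicitly.

```{r ti-example}
res <- runTransformation(harmonicSystem(1, 4), lambdaSchedule(7),
                         nSteps = 5000, seed = 1)
res
0.5 * log(4)  # closed form at RT = 1
```

# Numerical conventions and degenerate inputs

Fraction unfolded is clamped at $10^{-6}$; flat or noise-only curves are
flagged rather than fitted; Kirchhoff fits require at least three distinct
melting points and refuse singular (all-equal) designs; replicate
aggregation requires at least two unflagged replicates (SEM is undefined for
one); lambda schedules must run strictly from 0 to 1; Metropolis chains that
never accept a move are flagged. Text outputs are fully deterministic: fixed
column orders, full-precision (`%.17g`) numbers, rows sorted by protein,
ligand, urea and replicate, so byte-identical inputs give byte-identical
files.

# Problem sizes used by the test-suite

The suite validates recovery at the design scale of the assay itself (64-well
two-complex plates, 4 replicates, 8 urea levels) and keeps Monte-Carlo
studies at sizes where the checked property is sampling-dominated: 50 seeded
plates for the 2-sigma ddG coverage study, 20 seeded transformations
(4000 steps per lambda, $k_1/k_0 = 2$) for the 3-stderr closed-form
comparison, and 8 seeds per sampling level for the hysteresis-shrinkage
check. These sizes are the package's choices for keeping each property test
sharp; all scale up without code changes.

# Known limitations

The analysis is strictly two-state; three-state unfolding, irreversible
aggregation and scan-rate effects are out of scope. The ddG equals a binding
free-energy difference only under the native-state-binding assumption, which
is stated in the output convention string. The delta-method uncertainty
ignores parameter covariances (see above). The plateau + $\ln K$ path is a
few-percent-class enthalpy estimator by construction; quantitative
extrapolations should rely on the default refined pipeline. The toy
alchemical module validates the formalism, not molecular systems: no force
fields, no solvation, no per-residue decompositions.
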
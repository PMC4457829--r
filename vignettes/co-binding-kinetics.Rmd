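---
title: "Modelling CO binding kinetics in a two-conformation protoglobin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling CO binding kinetics in a two-conformation protoglobin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgbkinetics)
```

## The kinetic scheme

Protoglobin from *Methanosarcina acetivorans* switches between two
tertiary conformations: a reactive **r** state that binds CO tightly and
releases it slowly, and a **t** state with the opposite character. The
CO-bound protein favours r (equilibrium constant $K_1 = k_1/k_{-1}
\approx 0.3$, with $k_1$ the r$\to$t rate), while the unliganded protein
favours t ($K_3 = k_3/k_{-3} \approx 3$). Ligand binding therefore
drives a conformational relaxation, and the rebinding kinetics after a
photolysis flash carries the signature of that switch.

The model is an eight-state first-order network. For each conformation
x $\in$ {r, t} there are four species: the CO-bound protein, the ligand
in a primary internal docking site, the ligand in a secondary docking
site (reachable only from the primary site, with no direct solvent
exit), and the unliganded protein with CO in the solvent. The steps are

* conformational exchange: $k_1/k_{-1}$ (bound), $k_2/k_{-2}$
  (primary-docked), $k_3/k_{-3}$ (unliganded); secondary-docked species
  do not interconvert;
* geminate chemistry at the primary site: bond formation $k_{g,x}$ and
  thermal dissociation $k_{diss,x}$;
* docking-site migration: $k_c/k_{-c}$ (r), $k_{d2}/k_{-d2}$ (t);
* solvent exchange: escape $k_{out}$ (one value for both conformations)
  and pseudo-first-order entry $k_{in,x}\,[\mathrm{CO}]$, with CO in
  excess so its concentration is a constant of each experiment.

Two naming choices avoid a collision in the conventional symbols: the
t-state site-migration rates are called `kd2`/`k_d2`, and the thermal
dissociation rates `kdiss_r`/`kdiss_t`.

With these steps the populations obey $\dot x = A x$ where $A$ is built
by `build_rate_matrix()`; every elementary step adds a positive
off-diagonal entry and subtracts it from the source diagonal, so columns
sum to zero and total protein is conserved exactly, not approximately.

## Experiments as initial-value problems

**Flash photolysis.** Before the flash the protein is fully bound with
$\mathrm{R{\cdot}CO}:\mathrm{T{\cdot}CO} = 1 : K_1$. The flash moves a
fraction `photolysis_yield` (default 1.0; no yield is reported for the
emulated experiments) of each bound conformer into its primary docking
site. The observable is the unliganded fraction
$N(t) = 1 - (\mathrm{R{\cdot}CO} + \mathrm{T{\cdot}CO})$, which equals
the yield at $t = 0$.

**NO displacement.** `simulate_no_displacement()` starts from the bound
equilibrium and propagates with the entry fluxes switched off
(`scavenger_mode`): free CO is captured by excess NO and never returns.
On the seconds time scale each thermal dissociation event resolves in
nanoseconds into either geminate recapture (probability
$k_g/(k_g + k_{out})$) or escape, giving apparent rates
$k_{OFF,x} = k_{diss,x}\,k_{out}/(k_{out} + k_{g,x})$. This relation is
also used in reverse to pin the poorly-sensed $k_{diss}$ values to
measured $k_{OFF}$ during fitting.

A point we surface rather than hide: with the published
$k_1, k_{-1} \sim 10^5\ \mathrm{s^{-1}}$ the bound conformers
re-equilibrate in ~10 µs, which would make a seconds-scale dissociation
effectively mono-exponential at the population-weighted rate, whereas
the emulated experiments report biphasic dissociation. The simulator
therefore exposes `freeze_interconversion`, which keeps the pre-mix
equilibrium split but zeroes $k_1, k_{-1}, k_2, k_{-2}$ during the
decay; with it the decay is biexponential at exactly the branching
rates. How the two observations are reconciled physically is left open.
Similarly, which apparent dissociation phase belongs to which
conformation is not derivable from the data; the default maps the
majority slow phase to the majority bound conformer r
(`koff_assignment = "slow_r"` in `pgb_rates()`), and the choice is
configurable.

## Numerical choices

The network is stiff (rates span $10^{-2}$ to $10^8\ \mathrm{s^{-1}}$),
so propagation uses `deSolve::ode` with `lsoda`, the analytic constant
Jacobian ($A$ itself), `rtol = 1e-8`, `atol = 1e-12`, on a logarithmic
grid from 10 ns to 1 s at 200 points per decade by default. Tests hold
the solution to within $10^{-6}$ of an independent matrix-exponential
propagation and population conservation to $10^{-9}$ at every output
time. CO solubility defaults to 1.0 mM/atm at 20 °C (configurable; the
emulated experiments state pressures, not concentrations).

## Global fitting

`global_fit()` minimises the summed squared residuals between simulated
and measured $N(t)$ over all traces simultaneously (traces at 1.0 and
0.1 atm CO share every rate parameter). Design choices:

* **Parameterisation.** Free parameters are optimised as $\log_{10}$
  values: rates are positive and uncertain on ratio scales.
* **Weighting.** Residuals are taken at the trace's own time points and
  weighted by $\sqrt{\Delta\log_{10} t}$, so each decade of the ns–s
  range carries equal weight however densely it was sampled. For
  log-spaced data this is the same weighting as resampling on a uniform
  log grid, but it is exact at the data points — refitting a simulated
  trace from the truth returns a residual of zero rather than the
  interpolation error of a resampler.
* **Constraints.** A `fit_spec` supports fixed parameters, ties
  ($k_2 := k_3$, $k_{-2} := k_{-3}$, since the docked-state exchange is
  not separately resolvable), and derived parameters ($k_{diss,x}$
  recomputed from measured $k_{OFF,x}$ and the *current* $k_{out}$,
  $k_{g,x}$ at every evaluation, so the constraint holds at the optimum
  whatever those rates become).
* **Optimiser.** Levenberg–Marquardt (`minpack.lm::nls.lm`), optionally
  from several jittered initialisations keeping the best optimum; the
  noisy-data landscape has local minima along strongly correlated
  parameter directions and a single start is not reliable there. The
  jitter seed defaults to 1234.
* **Errors.** `scan_errors()` scans the fitness along each free
  parameter (others held at the optimum, 81 log-spaced points over ±1
  decade by default) and reports the half-width where the fitness
  reaches 1.1× its minimum, with crossings located by linear
  interpolation; on a quadratic fitness $f_0(1 + ((p-p_0)/w)^2)$ this
  is $w\sqrt{0.1}$. The asymptotic error-matrix estimate from
  $J^\top J$ is attached as a cross-check. A parameter whose fitness
  rises by less than 10% when doubled or halved is flagged as weakly
  identified — by construction that is exactly "scan error wider than a
  factor of two".

## What the synthetic data emulate — and what they don't

`generate_traces()` adds i.i.d. Gaussian noise ($\sigma = 0.005$ by
default) to simulated traces under the emulated design: 1.0 and 0.1 atm
CO, 20 °C, 10 ns–1 s log grid. `generate_spectra()` builds a
wavelengths × delays matrix from two basis difference spectra — by
default a Soret deoxy-minus-carboxy shape (negative Gaussian at 419 nm,
positive at 436 nm, widths 8 nm; conventional band positions, not
measured ones) plus a smaller 427 nm band standing for an intermediate —
multiplied by two simulated time courses ($N(t)$ and the t-state
unliganded population), so the noise-free matrix has rank exactly 2.
Not modelled: shot noise, instrument response, wavelength-dependent
noise, drifting baselines, or spectral shapes beyond two components.
Passing tests therefore demonstrate correctness of the machinery and
identifiability under idealised noise, not robustness to instrumental
artefacts.

## Identifiability: what recovery can and cannot mean

The recovery harness (`recovery_experiment()`) generates noisy
two-pressure traces from known rates, perturbs the starting point
log-uniformly within a factor 1.5, refits, and compares. Its default
template frees nine parameters — $k_{in,r}, k_{in,t}, k_{out}, k_3,
k_{-3}$ plus the four docking-migration rates — and holds the
geminate-phase rates $k_{g,r}, k_{g,t}$ and the bound-state exchange
$k_1, k_{-1}$ at their known values, with $k_2, k_{-2}$ tied and
$k_{diss}$ derived.

The reason for holding $k_{g,t}$ deserves stating plainly, because it is
a structural property of the scheme, not a convenience. The t-pathway
bimolecular rate is $k_{in,t}\,k_{g,t}/(k_{g,t}+k_{out})$ — only this
product is visible in the slow phase — and the t-state geminate
amplitude that would separate the factors is
$\frac{K_1}{1+K_1}\cdot\frac{k_{g,t}}{k_{g,t}+k_{out}} \approx 0.8\%$,
below a 0.5% noise floor. Empirically, fixing $k_{in,t}$ at twice its
true value and refitting the remaining parameters on noise-free data
reaches a residual 6000× below the noise floor: with $k_{g,t}$ free,
$k_{in,t}$ is not identifiable at realistic noise, for any optimiser.
Conditional on the geminate rates, all five headline parameters are
recovered within 20% (typically within 5–10%) across seeds, while the
docking-migration rates $k_c, k_{-c}, k_{d2}, k_{-d2}$ come out flagged
weak — their processes contribute only small-amplitude features, as the
emulated analysis itself reports. `derive_constants()` reports the
association constants both ways (branching formula and the numerical
slope of apparent rate vs [CO]) because the two published second-order
values are not all consistent with the branching formula applied to the
published microscopic rates; both estimators agree to 2% on every set we
generate.

Problem sizes used throughout validation: 200 points per decade over
10 ns–1 s for recovery traces (the estimator's variance grows with the
log-grid spacing under equal-decade weighting, so sparse grids inflate
recovery error), five noise seeds, four optimiser starts per fit.

## SVD of time-resolved difference spectra

`svd_decompose()` is an exact SVD with a sign convention (largest
spectral element positive). Components are selected by
`select_components()` when the singular value is significant
($s_i/s_1 \ge 0.01$) **and** both the spectral and the amplitude vector
are smooth (lag-1 autocorrelation $\sum_j v_j v_{j+1} \ge 0.8$ for
unit-norm $v$). Both conditions are required: white-noise components can
carry sizeable singular values but have autocorrelation near zero, and
the reported smoothness of accepted components (corr ≈ 0.99) states no
cutoff, so 0.8 is a deliberately loose default. Smoothness is measured
as lag-1 autocorrelation; correlating amplitude vectors against a
reference kinetic trace (e.g. the 436 nm recovery) is a noted
alternative that this package does not implement. Rank-$k$
reconstruction satisfies the Eckart–Young identity to $10^{-9}$, which
the tests verify against brute-force low-rank search on small instances.

## Known limitations

* Single temperature; no van 't Hoff / Eyring analysis.
* Inputs are normalized fractions; raw absorbance or voltage traces must
  be normalized upstream.
* The NO-displacement simulation treats the scavenger as perfect
  (no NO-binding kinetics of its own).
* Least-squares point estimates with scan/error-matrix errors; no
  posterior sampling.
* The component-selection autocorrelation threshold is a heuristic; on
  heavily smoothed noise it will admit spurious components.
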
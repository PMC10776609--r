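---
title: "Methods: reduced-order simulation of anti-solvent jet crystallization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reduced-order simulation of anti-solvent jet crystallization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jetcryst)
```

## The process and the model

Lovastatin is crystallized continuously by impinging a jet of
lovastatin–methanol solution against a jet of water.  Water is an
anti-solvent: it is miscible with methanol but dissolves almost no
lovastatin, so mixing drives the solubility $C^*$ down by orders of
magnitude and the supersaturation ratio $S = C/C^*$ up, which switches on
nucleation and growth.  The product quality metrics are the crystal size
distribution (CSD) at the outlet — its mass-weighted mean and spread — and
the crystal production rate.

`jetcryst` simulates this process on a network of well-mixed compartments
instead of a resolved 3-D flow field.  Four coupled sub-models are solved
simultaneously in every compartment:

1. **Population balance** over the crystal size coordinate $r$, discretized
   into uniform classes and advanced with a high-resolution finite-volume
   semi-discrete central scheme (minmod-limited MUSCL reconstruction).
2. **Micromixing** by a three-environment presumed-PDF model: environment 1
   is unmixed feed solution ($\xi = 1$), environment 2 unmixed anti-solvent
   ($\xi = 0$), environment 3 the mixed fluid in which crystallization
   occurs.  Engulfment rates are driven by the scalar dissipation rate
   $\varepsilon_\xi = C_\Phi \langle \xi'^2\rangle\, \varepsilon/k$ with
   $C_\Phi = 2$.
3. **Crystallization kinetics** of lovastatin: closed-form solubility
   $C^*(w_{as}, T)$, primary nucleation
   $B = B_{hom} + B_{het}$ and size-independent growth $G(S)$, all
   evaluated at the environment-3 composition.
4. **Enthalpy balance**: a heat source from solvent/anti-solvent mixing and
   (weakly) from crystallization, released as material is engulfed into
   environment 3.

Momentum, turbulence closure and 3-D geometry are outside the model's
scope: the per-compartment turbulence frequency $\varepsilon/k$ and the
compartment volumes are inputs.

## Population balance discretization

The number density $f(r)$ (crystals per m$^3$ of suspension per m of size)
is stored as class averages $f_j$ on a uniform grid.  For growth the
semi-discrete update is the conservative flux difference

$$\frac{df_j}{dt} = -\frac{H_{j+1/2} - H_{j-1/2}}{\Delta r},\qquad
H_{j+1/2} = G\,\Big(f_j + \tfrac{\Delta r}{2}(f_r)_j\Big),$$

with the slope $(f_r)_j$ limited by
$\mathrm{minmod}\{\theta \Delta_- f, \tfrac12(\Delta_- f + \Delta_+ f),
\theta \Delta_+ f\}/\Delta r$, $\theta = 1.5$.  For a linear flux the
central-scheme face flux reduces exactly to this upwind-biased form;
dissolution uses the mirrored (downwind-cell) reconstruction.  Nucleation
enters the smallest class as a discrete delta source $B/\Delta r$; the
nuclei size is taken at the bottom of the grid, the smallest resolvable
size.  The outer face is zero-flux, with the would-be overgrowth rate kept
as an audit quantity.

Two numerical details are worth recording:

* **End-class slopes.** One-sided differences at the first and last class
  are clamped so the reconstructed edge value stays within $[0, 2 f_j]$.
  Without the clamp, a large second class next to a nearly empty first
  class drives the first class negative (undershoots of several percent of
  the peak on rough profiles); with it the scheme is positivity-preserving
  for CFL $\le 0.5$ and the clamp is inactive wherever the profile is
  resolved.
* **Mass recast.** The mass held in class $j$ is the third moment
  $f_{w,j} = \rho_c k_v f_j\,[(r_{j+1/2})^4 - (r_{j-1/2})^4]/4$ (kg/m$^3$).
  A $1/\Delta r$ factor sometimes written in this conversion applies only
  when $f_j$ denotes the class *count* per m$^3$ rather than the density
  per m$^4$; carrying it with a density overstates crystal mass by
  $1/\Delta r$ and, through the solute sink, pushes the reactor into a
  spurious fully-depleted regime.  The volume shape factor $k_v$ is not
  fixed by the kinetics source; the default is $\pi/6$ (volume-equivalent
  spheres), and it only rescales mass-basis outputs.

### Verification strategy

Every numerical claim is checked against an oracle that shares no code with
the production path:

* constant-growth advection against the exact translation
  $f(r, t) = f_0(r - Gt)$, evaluated by Gauss quadrature;
* the mixed-suspension steady state against
  $f(r) = (B/G)\,e^{-r/(G\tau)}$;
* a deliberately first-order upwind scheme as a control for the order
  estimator.

The smooth-profile convergence study uses a Gaussian with $\sigma = 10$ um
on a 0–120 um domain, advected 20 um, at $\Delta r = 4, 2, 1, 0.5$ um.  The
width is chosen so the *coarsest* grid already resolves the profile
($\sigma/\Delta r = 2.5$); order measured across grids that under-resolve
the data says nothing about the scheme.  In that regime the observed L1
order is about 1.83.  On discontinuous data the observed order is about
0.72, consistent with the theoretical $O(\Delta r^{2/3})$ rate of TVD
limiters at contact discontinuities.  The TVD property itself (no new
extrema, no negative densities) is asserted on randomized non-negative
profiles advanced with the SSP two-stage Runge–Kutta integrator under CFL
0.4.

## Micromixing model

The three environment probabilities and the environment-3 weighted
composition $s_3 = P_3 \Phi_3$ evolve by engulfment sources

$$G(P_1) = -\gamma P_1(1-P_1),\quad G(P_2) = -\gamma P_2(1-P_2),\quad
G(P_3) = \gamma[P_1(1-P_1) + P_2(1-P_2)],$$

$$M(s_3) = \gamma[P_1(1-P_1)\Phi_1 + P_2(1-P_2)\Phi_2],\qquad
\gamma = \frac{\varepsilon_\xi}
{P_1(1-P_1)(1-\langle\xi\rangle_3^2) + P_2(1-P_2)\langle\xi\rangle_3^2},$$

plus spurious-dissipation corrections proportional to
$\gamma_s = 2D_t |\nabla\langle\xi\rangle_3|^2 /
[(1-\langle\xi\rangle_3)^2 + \langle\xi\rangle_3^2]$, which vanish in 0-D
compartments where no resolved gradient exists.  The sources conserve
$\sum_n P_n = 1$ and the species means exactly (they are linear invariants,
so any consistent ODE integrator preserves them to machine precision); both
closures are asserted in the tests.  Degenerate states
($P_1, P_2 \to 0$) zero the sources below a $10^{-14}$ denominator
threshold — physically, nothing remains to engulf.  Probability
conservation is taken as authoritative where descriptions of $P_3$
conflict, i.e. $P_3 = 1 - P_1 - P_2$.

Environments 1 and 2 carry the fixed feed compositions; all reaction and
the crystal population live in environment 3.  Its mixture fraction
$\langle\xi\rangle_3$ is maintained as the transported scalar $P_3
\langle\xi\rangle_3$ divided by $P_3$, clamped to $[0,1]$, with a flagged
default of $0.5$ at $P_3 = 0$.

## Kinetics

Solubility (kg lovastatin per kg solvents):

$$C^* = 0.001\,e^{15.45763\,(1 - 1/\theta)}\;\mathrm{poly}(w_{as}),\qquad
\theta = T/296\,\mathrm{K},$$

with a cubic in the water weight percent $w_{as}$ below 45.67 and a linear
form above.  The source prints the upper branch as $1.7884\,w + 1.7888$,
which is discontinuous with the cubic by a factor of ~86 at the boundary;
reading the slope as $-1.7884\times10^{-2}$ makes the two branches agree to
0.034%.  The package defaults to the continuity-restored slope
(`branch_mode = "continuity_restored"`) and keeps the literal form
available (`"as_printed"`); continuity at the boundary is strong evidence
of a sign/exponent misprint, but the choice is exposed rather than silent.

Nucleation and growth (correlations at 23 °C):

$$B_{hom} = 6.97\times10^{14} e^{-15.8/(\ln S)^2},\quad
B_{het} = 2.18\times10^{8} e^{-0.994/(\ln S)^2}\ \ \#/(\mathrm{m^3 s}),$$
$$G = 8.33\times10^{-30}\,(2.46\times10^{3}\ln S)^{6.7}\ \mathrm{m/s}.$$

For $S \le 1$ all rates are zero — the $S \to 1^+$ limit of the formulas —
rather than evaluating at non-positive $\ln S$.  No temperature correction
is available for the rate constants; they are applied at all temperatures,
and the configuration exposes the kinetics block so temperature-dependent
laws can be substituted.  The inlet supersaturation ratio of a feed is
defined against the solubility at the feed's own composition and
temperature (pure methanol, 25 °C for the solution stream).

The growth law is steep: between $S = 5$ and $S = 100$, $G$ spans
$10^{-5}$ to $10^{-2}$ m/s.  This matters for reactor design below.

## Reactor coupling and the choice of operating regime

Each compartment carries state
$(P_1, P_2, P_3, P_3\langle\xi\rangle_3, s_3^{solute}, s_3^{MeOH},
s_3^{H_2O}, T, f_1 \ldots f_N)$.  Inter-compartment volumetric flows
exchange all transported scalars; the stiff coupled system is integrated
with `deSolve::lsoda`, in chunks of one residence time until the maximum
scaled state change per residence time falls below `steady_tol`
(default $10^{-5}$).  The solute sink in environment 3 equals the total
crystal mass production rate, so dissolved + crystalline solute is a linear
invariant of the right-hand side; the enthalpy source is
$S_h = \dot m_{mix}(-\Delta H_{mix}) + \dot m_{crys}(-\Delta H_{crys})$.

Two energy parameters are calibrated, not measured, and are labelled so:
no numeric heats are printed in the source study, so $\Delta H_{mix} =
-3.9\times10^4$ J per kg of solvents mixed is set to reproduce the reported
~+10 K adiabatic temperature rise at solution/anti-solvent mass ratio 1
(with $c_p = 3400$ J/(kg K) and a solvent mass fraction of 0.877 at that
operating point), and $\Delta H_{crys} = -30$ J/kg is small, as reported
for lovastatin.

### Compartment defaults

The impinging-jet template is an impingement compartment followed by three
chamber compartments in series.  Its defaults encode a deliberate modelling
decision:

* **Active volume $1.5\times10^{-9}$ m$^3$** (1.5 uL, millisecond
  residence at the base flows).  The compartments represent the active
  impingement/mixing zone of a 0.65 mm jet pair — a few jet diameters
  cubed — not the whole vessel.  The reported operating tables imply that
  only ~0.4% of the fed solute leaves as crystal, i.e. the device operates
  kinetics-limited.  A large well-mixed volume cannot reproduce that: with
  the steep growth law above, any residence time long enough to approach
  solubility equilibrium converts >90% of the solute, the outlet crystal
  flow then simply tracks throughput, and the velocity and mass-ratio
  trends invert.  With the millisecond active zone the simulated outlet
  flows land within a factor of ~2 of the reported ones across all three
  case-study sweeps.
* **Turbulence frequency $\varepsilon/k = (2\times10^4, 5\times10^3,
  2\times10^3, 10^3)$ 1/s** down the chain, scaled by $v/1.5$ with the
  mean inlet velocity.  Jet-impingement scaling ($\varepsilon \sim v^3/d$,
  $k \sim (0.2 v)^2$ with $d = 0.65$ mm) gives $\varepsilon/k$ of order
  $10^4$ 1/s at 1.5 m/s; these values also make micromixing nearly
  complete at the outlet ($P_3 > 0.95$), as observed in the resolved-field
  study.  Velocity scaling keeps mixing completeness roughly constant
  across the velocity sweep, which is the reported behaviour.
* **Size grid 0–120 um, 60 classes** ($\Delta r = 2$ um, the validated
  class width).  A compartment chain has exponential residence-time tails,
  so a minority of crystals grows past 60 um; the grid span follows the
  principle that it must hold all sizes produced.  The class-width
  sensitivity procedure (means and spreads compared across
  $\Delta r = 4, 2, 1$ um) shows the 2 → 1 um change (≈0.9% in the mean,
  ≈1.6% in the spread) is much smaller than the 4 → 2 um change, the same
  convergence pattern reported for the resolved model.
* **Nozzle area $3.334\times10^{-7}$ m$^2$**, fixed so that the reference
  anti-solvent mass flow of $498.6\times10^{-6}$ kg/s corresponds to
  1.5 m/s.

Compartments start filled with quiescent anti-solvent at 25 °C.

### What the simulator reproduces, and what it does not

Directionally, the three operating sweeps behave as reported: mass-weighted
mean size, CSD spread and outlet crystal mass flow all *increase* with
inlet supersaturation (6.8 → 8.8), *decrease* with inlet velocity
(1 → 4 m/s), and *decrease* with solution/anti-solvent mass ratio
(0.5 → 2); the outlet temperature rises ~10 K in every case, dominated by
the heat of mixing.  Outlet mass flows additionally land near the reported
magnitudes (velocity sweep: 4.4 / 0.63 / 0.087 mg/s simulated vs
3.79 / 0.51 / 0.084 mg/s reported).  Quantitative interior fields do not
transfer: a compartment model has no spatial supersaturation structure, so
its volume-averaged $S$ reflects the mixed composition rather than a
weighted average over partially mixed regions, and mean sizes come out
larger than the resolved-model tables.  Aggregation and breakage are
neglected throughout, matching the source model's assumption.

## Synthetic data and what passing tests show

All test inputs are generated in code: named CSD profiles (Gaussian, step,
empty, exponential) with deterministic class-average evaluation, randomized
non-negative profiles under fixed seeds for the TVD property, and run
configurations built from the defaults above.  They emulate the *shapes*
the solver must transport and the operating window of the case studies;
they do not emulate measured CSDs, polydisperse feeds, or encrustation and
aggregation phenomena absent from the model.  A green suite therefore
certifies the numerics (orders, conservation, oracle agreement) and the
model's internal consistency, not predictive accuracy for a physical
crystallizer.

## Numerical choices and degenerate inputs

* Steady state is declared per residence time on scaled state changes;
  per-type scales (probabilities 1, concentrations $10^3$ kg/m$^3$,
  temperature 300 K, densities the field maximum) stop near-empty size
  classes from dominating the residual.
* `lsoda` tolerances: `rtol` $10^{-6}$ with per-type absolute tolerances;
  negative densities after a step are clipped to zero and counted
  (`run$clips`), never silently.
* Empty CSDs are flagged (`empty = TRUE`) with `NA` means rather than
  0/0; $P_3 = 0$ yields a flagged default mixture fraction; the $\gamma$
  denominator below $10^{-14}$ zeroes all micromixing sources.
* Simulation sizes in the shipped tests (30–120 size classes, 1–4
  compartments, millisecond-scale transients, 100-profile TVD batteries)
  are chosen so the whole verification battery is a few minutes of
  single-core compute.

## Known limitations

* No aggregation/breakage term; no dissolution law (the growth correlation
  has no $S < 1$ branch, so crystals never shrink — the dissolution
  discretization is exercised only with imposed rates).
* Kinetic correlations are 23 °C values applied at all temperatures.
* The compartment topology is serial; recirculation structures would need
  an explicit flow matrix (supported by the network container, not by the
  shipped templates).
* $\Delta H_{mix}$ is composition-independent, a single calibrated value.
* The upper solubility branch is a correction of a printed form; if the
  original correlation differed in both sign and exponent in some other
  way, both modes here would be wrong, though continuity and magnitude
  make that unlikely.
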
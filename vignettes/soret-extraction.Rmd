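---
title: "Methods: forward-modelled Soret-coefficient extraction from MST traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forward-modelled Soret-coefficient extraction from MST traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soretfit)
```

## Overview

`soretfit` infers the Soret coefficient S_T of fluorescent colloids from
MicroScale Thermophoresis (MST) time courses. The inference is
forward-model based: we simulate what the instrument should observe for a
given S_T, and select the S_T whose simulated observable best explains the
measured trace after the intrinsic fluorophore decay has been
deconvoluted. This vignette documents the model, its assumptions, the
numerical choices, and what the synthetic-data test bench does and does
not establish.

## Laser heating

The heat load is modelled as a Gaussian transverse profile attenuated
axially by Beer–Lambert absorption,

$$q(r,z) \;=\; A\,
\exp\!\Big(-\tfrac{r^2}{2\sigma^2}\Big)\,
e^{-A_c (z + L)},$$

on an axisymmetric $(r, z)$ domain: capillary radius $R = 0.2$ mm, axial
half-length $L = 0.2$ mm, focus at $r = 0, z = 0$. The normalization $A$ is
chosen so the discrete volume integral equals the absorbed power
$Q_0 (1 - R_c)\big(1 - e^{-2 A_c L}\big)$ — about $9.4\times10^{-4}$ W at
the defaults. Defaults and their provenance:

| parameter | default | meaning |
|---|---|---|
| $Q_0$ | 0.05 W | laser input power (instrument setting) |
| $R_c$ | 0.05 | lumped wall reflection coefficient |
| $A_c$ | 50 m⁻¹ (0.50 cm⁻¹) | absorption coefficient of the sample |
| beam diameter | 10 µm | interpreted as the 1/e² intensity diameter, so $\sigma = 2.5$ µm (the common laser convention; configurable) |
| medium | water: k = 0.6 W/(m·K), ρ = 998 kg/m³, c_p = 4182 J/(kg·K) | sample thermal properties |
| ambient | 293.15 K | Dirichlet boundary temperature |

The exact ambient temperature behind the instrument's focal temperature is
not a measured quantity here; we default to room temperature (293.15 K),
which puts the computed focal temperature near 298 K, and treat only
temperature *rises* as physically meaningful. The glass wall is not meshed;
reflection and absorption enter only through the lumped $R_c, A_c$.
Convection is deliberately omitted — the measurement geometry is chosen by
the technique precisely to avoid convective artifacts, and the millikelvin-
per-micron gradients at these powers make buoyant flow negligible on the
20 s time scale.

Steady conduction $k\nabla^2 T + q = 0$ and transient conduction
$\rho c_p \partial_t T = k\nabla^2 T + q(t)$ are solved with a conservative
finite-volume discretization (node-centred, axisymmetric cell volumes
$2\pi r\,\Delta r\,\Delta z$) and implicit Euler stepping
(Δt = 0.01 s for the first second after a switching event, 0.05 s
otherwise — the establishment transient is sub-second, so the fine phase
resolves it and the coarse phase merely tracks the plateau). The default
grid grades the radial spacing: 0.5 µm across the beam waist (≥ 8 nodes
inside 2σ), 1.5 µm out to 20 µm, then geometric coarsening to the wall;
axial spacing 10 µm. The test suite verifies discrete energy balance,
the maximum principle, convergence of the transient to the steady solve,
and < 2 % change of both the peak rise and the establishment time under
2× refinement.

## Particle transport

Particle migration obeys the drift–diffusion equation

$$\partial_t c = -\nabla\cdot J, \qquad
J = -D \nabla c - c\, D_T \nabla T, \qquad D_T = D\, S_T,$$

with $D = 2.25\times10^{-12}$ m²/s, uniform initial concentration
1 mol/m³, and no-flux outer boundaries (mass is conserved; the suite
checks a relative drift < 10⁻⁶ over 20 s). Coupling is one-way: the
temperature field is frozen per transport step (heat establishes in
≲ 0.15 s versus the ~20 s mass-transport scale, and particle heat release
is negligible).

**Face fluxes are Scharfetter–Gummel.** For a face between nodes $i,j$ the
flux is $\frac{D A}{h}\big[B(-\mathrm{Pe})\,c_i - B(\mathrm{Pe})\,c_j\big]$
with $B(x) = x/(e^x - 1)$ and drift Péclet number
$\mathrm{Pe} = S_T (T_i - T_j)$. At the default parameters
$|\mathrm{Pe}| \ll 1$ and the scheme reduces to central differencing, but
the exponential fitting buys two structural properties worth having at any
Péclet number: the update matrix is an M-matrix (no negative
concentrations, no oscillations), and the *discrete* zero-flux steady state
is exactly $c \propto e^{-S_T (T - T_\mathrm{ref})}$ node-for-node. The
acceptance suite exploits the latter: a long-horizon run on a frozen
temperature field must match the closed-form Boltzmann profile within 1 %
pointwise for $S_T \in [-2, 2]$ K⁻¹, a discriminating oracle that plain
central differencing fails at the steeper gradients.

**The observable.** Conc(t) is the mean concentration over an optical
probe region centred on the focus, normalized to its value at laser-on
(only the *shape* is identified — the trace model's amplitude absorbs any
scale, so fixing Conc(0) = 1 simply makes the amplitude interpretable as
the initial intensity). Three reductions are provided:

* `circle` (default fitting observable): area-weighted mean over a 130 µm
  diameter circle in the focal plane;
* `disk`: volume-weighted mean over a 130 µm × 20 µm disk — the suite
  verifies circle and disk agree within 5 % at all times, which is why the
  cheaper 2-D reduction is a valid fitting observable;
* `line`: unweighted radial line integral over the 130 µm span. The line
  weighting emphasises the depleted core (no $2\pi r$ factor), so its
  depletion depth is several-fold larger and visibly non-linear in time,
  matching the familiar presentation of simulated mass change.

Because the enrichment ring that forms around the depleted core lies
*inside* a 65 µm-radius probe, the area-weighted Conc(t) changes only
through the slow flux across the probe boundary: depletion depths are
small (about 10⁻³ at S_T = 0.07 K⁻¹, two orders larger at the extremes of
the library range) and nearly proportional to S_T in the linear-response
regime — the suite checks proportionality and +/− sign symmetry within 2 %
at |S_T| ≤ 0.1 K⁻¹. This makes noiseless identification easy but means
real-world identifiability is noise-limited; the fit flags that regime
(below).

**The library.** `build_conc_library()` runs the solver once per S_T on a
grid (default 51 points over [−2.5, 2.5] K⁻¹, generous headroom around all
values validated in the tests) and stores the curves with a provenance
hash of every setting that influences them; an optional on-disk cache is
reused only on an exact hash match and rebuilt with a warning otherwise.
Off-grid curves come from monotone Hermite interpolation across S_T at
each time sample — exact at grid points, always bracketed by the
neighbouring curves, and within 0.5 % of a direct solver run at the
default grid spacing (tested).

## Two-stage trace fit

Stage 1 fits the free-fluorophore trace over the laser-on window (time
re-zeroed at laser-on) with

$$I_\mathrm{FF}(t) = B + C\,e^{k t},$$

by Levenberg–Marquardt with endpoint-heuristic starts (B ← tail mean,
C ← head − tail, k ← log-ratio slope). `k` is the *signed* exponent
coefficient: a decaying trace has k < 0, and the value conventionally
quoted as the decay constant (e.g. −0.22) is used directly as k in s⁻¹ —
writing the model as $e^{kt}$ rather than $e^{-kt}$ removes any sign
ambiguity about which way a negative printed constant acts. A constant
trace is returned as the degenerate fit (C = 0, k = NA) flagged
`k-unidentifiable` instead of failing.

Stage 2 fixes k (the particle's fluorophore decays identically — this
carry-over is the modelling assumption of the deconvolution, and the
package never refits k on particle traces) and fits

$$I_\mathrm{PS}(t) = d_0 + e_0\, e^{k t}\, \mathrm{Conc}_{S_T}(t).$$

For a candidate S_T the model is linear in $(d_0, e_0)$, so each library
grid point costs one 2×2 closed-form least-squares solve (tested to agree
with a generic `lm()` oracle to 10⁻¹⁰ relative). The coarse SSE profile
over the full grid is kept for diagnostics; the minimum is refined on a
5× finer interpolated grid across the bracketing interval and polished
with a parabola through the three lowest points (tie-break: if the
quadratic curvature is non-positive, the discrete minimum is kept; the
vertex is clamped to the bracketing triplet). Two flags mark
non-identifiable outcomes rather than guessing:

* `range-limited` — the coarse minimum sits on the library boundary; no
  extrapolation is attempted.
* `weakly-identified` — the best-fit Conc(t) deviates from 1 by less than
  three times the residual noise level (or below 10⁻⁵ absolute): the
  fluorophore decay dominates and the data barely constrain S_T. This is
  the regime that produces large replicate SDs; the flag propagates but
  the estimate is still reported.

`extract_soret()` averages k over the fluorophore replicates, fits every
particle replicate, and reports mean ± sample SD (n − 1 denominator) with
n, in the standard validation-table layout via `soret_report()`.

**Naming.** The particle-trace background and amplitude are called
`background_d0`/`amplitude_e0` (rather than single capital letters) so
that D can unambiguously remain the diffusion coefficient throughout the
package.

## Synthetic traces and what the tests show

`trace_recipe()` + the generators produce the canonical trace morphology:
5 s flat baseline at background + amplitude, the forward-model decay over
a 20 s on-phase, and a plateau after switch-off. The post-off recovery is
deliberately *not* modelled quantitatively (the fit never uses it); the
plateau simply keeps the file shaped like an instrument export. Noise is
additive Gaussian with SD expressed as a fraction of the amplitude —
adequate for the high count rates of these instruments, where shot noise
is well into its Gaussian regime; realistic magnitudes are a calibration
choice, not a measured quantity, and the tests therefore treat noise
amplitude as a swept parameter rather than a fixed truth. Every trace is
seeded and bit-reproducible; replicate sets use consecutive seeds.

The central contract — generator + fitter = identity on all parameters for
noiseless traces — is what the acceptance checks exercise at the validated
literature values (0.05, 0.18, 0.66 K⁻¹), the worked-example pair
(k = −0.22 s⁻¹, S_T = 0.07 K⁻¹), and the signed conditions (−0.15,
−1.86 K⁻¹). Passing these demonstrates that the pipeline is self-consistent
and that the optimizer finds the true optimum of the stated model; it does
*not* demonstrate that the forward model captures every physical effect in
a real instrument (aggregation, convection at high powers, concentration-
dependent D or S_T, TRIC/bleaching deviations from a single exponential are
all outside the model). The QC screen covers the first of these: rolling-
median detrending, MAD-standardized residuals, spikes at |z| > 5. A
one-window guard band around the switching events is excluded — the trace
has genuine kinks there, and without the guard a perfectly clean trace
would flag its own laser-on edge.

## Electrokinetics

Independent of the solver stack, the package provides the standard
charged-sphere relations used to interpret S_T trends across buffer
conditions: Debye length
$\lambda = \sqrt{\varepsilon_0\varepsilon_r k_B T / (2 N_A e^2 I)}$ (I in
mol/m³; refused at I = 0 where screening is infinite), the Debye–Hückel
conversion $Q = 4\pi\varepsilon_0\varepsilon_r R (1+\kappa R)\,\zeta$
(warned above |ζ| ≈ 50 mV where the linearization degrades), surface
charge density $\sigma = Q / 4\pi R^2$ in e/µm², and the scaling
$S_T \propto \sigma^2 \lambda$ exposed as a *ratio* between two conditions
— the theory fixes no absolute prefactor, so the package never converts
σ²λ into an absolute S_T. "Ionic concentration" is taken as the
user-supplied ionic strength; buffer speciation equilibria are out of
scope and must be resolved by the caller. ε always means
$\varepsilon_0\varepsilon_r$ internally; users supply $\varepsilon_r$.

## Problem sizes and runtime

The default grid has ~1 300 nodes (31 radial × 41 axial); a transient heat
solve with 150 stored snapshots takes a few seconds, one 200-step
transport solve ~0.1–0.3 s, and the full 51-point library a few seconds on
one core — the acceptance script completes in well under a minute. The
test suite uses a 21-point library over the same range; since both the
generator and the fitter interpolate the same library, round-trip accuracy
is set by the refinement step, not the coarse spacing, and the suite
additionally checks interpolated-vs-direct-solve agreement so the coarse
library is a faithful stand-in.

## Known limitations

* One-way heat→mass coupling and frozen per-step temperature (excellent
  here; would need revisiting for strongly absorbing samples).
* No particle–particle interactions, no concentration dependence of D or
  S_T: valid for the dilute suspensions the measurement is designed for.
* The thermoelectric (Seebeck) contribution of buffer ions — the proposed
  mechanism behind sign flips between buffers — is discussed only through
  the σ²λ scaling; no ion-transport model is included.
* The fluorophore decay is a single lumped exponential; TRIC and
  photobleaching are not separated.
* Absolute temperatures depend on the configurable ambient; only rises are
  validated.
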
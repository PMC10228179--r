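# soretfit

Quantitative extraction of the Soret coefficient of colloidal particles from
MicroScale Thermophoresis (MST) traces.

## The problem

MST instruments heat a microscopic spot in a capillary with an IR laser and
record the fluorescence of the sample through the laser-on/off cycle. The
intensity decay during the on-phase mixes two effects:

1. intrinsic fluorophore decay — temperature-related intensity change (TRIC)
   and photobleaching, and
2. thermophoretic migration of the fluorescent particles along the
   temperature gradient.

`soretfit` separates the two with a physics-based forward model and a
two-stage deconvolution, turning MST traces into the Soret coefficient
S_T = D_T / D (units 1/K): positive S_T means thermophobic particles that
deplete from the hot focus, negative means thermophilic enrichment. It is
aimed at people using a commercial MST instrument as a quantitative
thermophoresis platform rather than only as a binding-affinity readout.

## The model

**Forward simulation.** The laser heat load is a Gaussian beam
(1/e² diameter 10 µm, power 0.05 W, wall reflection 0.05) attenuated by
Beer–Lambert absorption (0.50 cm⁻¹) in an axisymmetric water-filled
capillary (radius 0.2 mm), solved with a conservative finite-volume scheme.
The resulting temperature field T(r, z, t) — a focal rise of a few kelvin
established well within 1 s — drives the particle drift–diffusion equation

    ∂c/∂t = −∇·J,    J = −D ∇c − c D_T ∇T,    D_T = D · S_T

with no-flux walls, D = 2.25 × 10⁻¹² m²/s and uniform c(0) = 1 mol/m³.
Face fluxes use Scharfetter–Gummel exponential fitting, so the discrete
steady state is exactly the Boltzmann profile c ∝ exp(−S_T (T − T_ref)).
Averaging c over the optical probe region (default: a 130 µm circle in the
focal plane; a 130 × 20 µm disk and a radial line are also available) gives
the normalized observable Conc(t), simulated once per S_T value and cached
in a library.

**Two-stage fit.** Stage 1 fits the free-fluorophore trace with
`B + C·exp(k·t)` (nonlinear least squares; `k` is the signed decay rate, e.g.
−0.22 s⁻¹). Stage 2 carries `k` over unchanged and fits the particle trace
with `d0 + e0·exp(k·t)·Conc_ST(t)`; for each library S_T the problem is
linear in (d0, e0) and solved in closed form, and the SSE-minimizing S_T is
refined on a 5× finer interpolated grid with a final parabolic polish.
Replicates are aggregated as mean ± sample SD.

Also included: a seeded synthetic-trace generator (the ground-truth test
bench for every fitting stage), aggregation-spike QC ("bumpiness"
screening), and electrokinetic side-calculations — Debye length,
Debye–Hückel zeta-to-charge conversion Q = 4πε₀ε_r R (1 + κR) ζ, surface
charge density in e/µm², and the theoretical scaling S_T ∝ σ²λ.

## Worked example

```r
library(soretfit)

cfg <- default_run_config()                      # instrument defaults
lib <- soret_library(cfg, soret_grid = seq(-0.5, 1, length.out = 16))
print(lib)

ff  <- generate_replicate_set(trace_recipe("fluorophore", decay_rate_k = -0.22),
                              n = 2, base_seed = 1)
ps  <- generate_replicate_set(trace_recipe("particle", soret_ST = 0.18,
                                           decay_rate_k = -0.22,
                                           noise_sigma = 2e-4),
                              n = 8, base_seed = 200, library = lib)
res <- extract_soret(ff, ps, lib)
print(res)
soret_report(list("100 nm PS" = res), literature_ST = c("100 nm PS" = 0.18))
```

prints

```
Conc(t) library: 16 S_T values in [-0.5, 1] 1/K, 201 times over [0, 20] s
  probe: circle, 0.00013 m diameter; depletion depth range [0, 0.011]
  provenance: 73675f66b844752710af13853ab7cc3f
Soret extraction: S_T = 0.1851 +/- 0.03534 1/K (n = 8; fluorophore k = -0.22 1/s)
  condition literature_ST_per_K n mean_ST_per_K sd_ST_per_K flags
1 100 nm PS                0.18 8      0.185054  0.03533958
```

The library holds one simulated Conc(t) curve per S_T; the extraction
recovers the generator's ground truth 0.18 K⁻¹ within the replicate scatter
(the SD is what the injected 0.02 % noise propagates into S_T for this
probe), and the report row is the standard validation-table layout.
With `noise_sigma = 0` the recovery is exact to the grid-refinement
tolerance (≪ 0.001 K⁻¹).

A thin command-line wrapper (`inst/cli/soretfit`) exposes the same pipeline
as subcommands `simulate-temp`, `build-library`, `synth`, `fit`, `qc` and
`electro`, each writing CSV outputs plus a run log with the config hash and
seed.

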
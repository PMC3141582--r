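# ibcms

Desk-scale immersed-boundary simulation of cardiovascular chamber
flows, with the hemodynamic diagnostics used to analyze them.

## What it is for

Flow inside the left ventricle carries diagnostically useful structure:
the early-filling (E-wave) jet rolls up into a pair of oppositely
signed vortices, the kinetic energy of the chamber traces three peaks
per beat (E-wave, atrial A-wave, systolic S-wave), and the inflow and
outflow ports exchange volume with the circulation according to
reservoir pressures. `ibcms` provides the full numerical machinery to
reproduce these mechanisms on a desk-scale synthetic geometry, for
method development, teaching, and testing of flow diagnostics that will
later be pointed at clinical velocity data:

* an incompressible Navier–Stokes solver on a periodic Cartesian grid
  (2-D or 3-D): fractional-step projection, skew-symmetric centered
  advection, Crank–Nicolson spectral viscosity, FFT pressure solve
  whose Laplacian symbol is the composed discrete divergence∘gradient,
  so the projection is discretely exact;
* the immersed boundary coupling: elastic fiber networks (springs with
  time-modulated stiffness `k(t)` and rest length `L0(t)`, tethers,
  tension-only chordae), force spreading and velocity interpolation
  through the four-point regularized delta kernel
  `f(x) = Σ F_m δ_h(x − X_m) ds_m`, `dX/dt = u(X, t)`, advanced by the
  classic two-stage time-centered (Crank–Nicolson) FSI cycle;
* reservoir pressure boundary conditions (RPBC): localized source/sink
  ports with `Q_k = (P_reservoir − p̄_k)/R_k`, treated implicitly
  against the projection pressure (the explicit update is unstable),
  with exact global mass balance on the periodic domain;
* synthetic fixtures: relaxing ellipse membrane, tethered cylinder in a
  port-driven stream (vortex-street validation), and a two-chamber
  ventricle with chorded valve flaps, PV (15 mmHg) and aortic (80 mmHg)
  reservoirs and an E/A/S activation schedule;
* diagnostics: z-vorticity (`ω_z = ∂v/∂x − ∂u/∂y`), slice kinetic
  energy (max and total of `½ρ|u|²`), shoelace chamber area and stroke
  volume, flow-rate non-dimensionalization `Q* = Q·T/V_stroke`, signed
  vortex-core counting, and KE peak detection. The same diagnostics
  accept externally supplied dense velocity arrays (PC-MRI-like)
  through `load_velocity_volume()`.

Units are CGS throughout (cm, s, g, dyn/cm²); port pressures are
quoted in mmHg (1 mmHg = 1333.22 dyn/cm²).

## A worked example

Run one cardiac cycle of the two-chamber ventricle on a 64² grid
(6.4 cm box, `h` = 0.1 cm, `dt` = 2×10⁻⁵ s). The packaged protocol
starts quiescent in early diastole, so the E-wave is the first filling
jet driven by the pulmonary-vein reservoir head, followed by the atrial
kick and systolic ejection within the same cycle:

```r
library(ibcms)

run <- ventricle_protocol(grid_spec(64, extent = 6.4))
cycle_ke_peaks(run)
```

```
     phase       ke
1 0.143594  5121.33
2 0.521406  3717.80
3 0.928281 15458.43
```

Three kinetic-energy peaks in the left-ventricle interior: the E-wave
filling jet near phase 0.14, the atrial A-wave at the 0.5 pulse center,
and the largest during systolic ejection — with the E-peak above the
A-peak, the ordering seen in beat-resolved chamber flow data. The
fixture is a synthetic desk-scale chamber, so the peak *phases* are its
own; the structure (three peaks, E above A) is the result. At peak
E-wave inflow the vorticity field inside the ventricle shows the
canonical two-signed vortex pair flanking the transmitral jet:

```r
ewave_vortex_cores(run)$cores
#> n_positive n_negative
#>          1          1
```

Port series in `run$cycle` (`Q_PV`, `Q_AO`, cm²/s, positive = inflow)
show pulmonary-vein inflow during early filling, aortic outflow during
ejection (beat-resolved peak about −7 cm²/s against the 80 mmHg
reservoir), and the systolic mitral-regurgitation-driven negative PV
phase that diffuse-interface heart models share. The stroke area of
the cycle is about 3.2 cm².

A YAML-configured interface (`run_simulation()`, `default_run_config()`)
writes a run container (config echo with hash, per-step diagnostics
CSV, VTK field snapshots, restartable checkpoint); `inst/cli/ibcms` is
a thin command-line front end (`ibcms run / fixture / diagnose`).

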
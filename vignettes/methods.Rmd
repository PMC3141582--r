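---
title: "Immersed-boundary chamber flows: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immersed-boundary chamber flows: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ibcms)
```

## The model

`ibcms` simulates incompressible Newtonian flow coupled to massless
elastic fiber boundaries — the immersed boundary formulation of
cardiovascular chamber flow. The fluid satisfies the Navier–Stokes
equations on a uniform periodic Cartesian grid,

$$\rho\left(\frac{\partial \mathbf u}{\partial t}
  + \mathbf u\cdot\nabla\mathbf u\right)
  = -\nabla p + \mu\nabla^2\mathbf u + \mathbf f, \qquad
  \nabla\cdot\mathbf u = q,$$

where $\mathbf f$ is the body force spread from the boundary and $q$ is a
prescribed divergence field realizing reservoir inflow/outflow ports
(zero away from ports). The boundary is a network of Lagrangian points
$X(s,t)$ joined by springs; its force density follows a generalized
Hooke's law, tension $T = k(t)\,(\ell - L_0(t))$ per spring, with both
the stiffness $k$ and the rest length $L_0$ modulated over the cardiac
cycle by an activation schedule — this modulation is what contracts and
relaxes the chamber walls. Boundary and fluid exchange force and motion
through a regularized delta function:

$$\mathbf f(\mathbf x) = \sum_m \mathbf F_m\,\delta_h(\mathbf x - X_m)\,ds_m,
 \qquad \frac{dX_m}{dt} = \sum_{\mathbf x} \mathbf u(\mathbf x)\,
 \delta_h(\mathbf x - X_m)\,h^{d}.$$

All units are CGS: cm, s, g, dyn/cm², with blood modeled as
$\rho = 1\ \mathrm{g/cm^3}$, $\nu = 0.03125\ \mathrm{cm^2/s}$. Pressures
at the reservoir ports are quoted in mmHg (1 mmHg = 1333.22 dyn/cm²);
the reference reservoir values for the five openings of a whole-heart
model are SVC/IVC 100, PV 15, PA 5 and aorta 80 mmHg, held constant
through the cycle.

## Discretization

**Grid.** Collocated, cell-centered, periodic in every direction; nodes
at $(i+\tfrac12)h$. Spatial derivatives are centered second-order
differences.

**Projection.** Each momentum step is followed by a pressure solve whose
Laplacian symbol is the *composition* of the discrete divergence and
gradient, inverted by FFT. This makes the projection exact in the
discrete sense: after projection, the centered-difference divergence
equals the prescribed source field to near machine precision. The few
Fourier modes on which the composed symbol vanishes (the constant mode
and the per-axis Nyquist combinations) carry no representable
divergence; source fields are filtered onto the solvable space, which
for the mean mode is exactly the uniform-background compensation that
keeps $\int q\,dV = 0$ on the periodic domain. The Nyquist symbols are
evaluated with `sinpi` so they vanish exactly rather than to rounding.

**Advection and diffusion.** Advection is explicit, centered, and in
skew-symmetric form (mean of advective and divergence forms), which
conserves discrete kinetic energy; a Courant guard refuses steps with
$\max|u|\,\Delta t/h > 0.9$. The viscous term is Crank–Nicolson with the
exact spectral Laplacian, hence unconditionally stable.

**FSI cycle.** A two-stage, time-centered scheme: forces at $X^n$ drive
a half step; forces re-evaluated at $X^{n+1/2}$ drive the full step,
with advection evaluated at the half-step velocity and the boundary
moved by the time-centered velocity $\tfrac12(u^n + u^{n+1})$
interpolated at $X^{n+1/2}$. The scheme is formally second-order in
time; the Taylor–Green tests in the suite confirm the observed decay
rate converges at second order.

**Kernel.** The standard four-point regularized delta. It satisfies the
discrete partition of unity and the zero-first-moment condition, so
spreading conserves total force, interpolation reproduces linear fields
exactly, and the pair is adjoint (verified to $10^{-12}$ relative in the
suite) — the property that makes the coupling energy-consistent.

**Implementation.** The two 2-D momentum solves share one complex
transform (real spectral factors), and the production path fuses
momentum, pressure solve, port coupling and projection into a single
spectral pass; a test asserts this path agrees with the composed
reference operators to machine precision. Kernel spreading and
interpolation loops are in C++ (Rcpp), as is the 2-D FFT backend
(Armadillo).

## Reservoir pressure ports

Each port exchanges volume with a fixed-pressure external reservoir
through a resistance, $Q_k = (P_k - \bar p_k)/R_k$, where $\bar p_k$ is
the kernel-weighted mean pressure over the port support and $Q_k$
enters the flow as a prescribed-divergence blob of unit integral. The
net residual $\sum_k Q_k$ is removed as a uniform background divergence
(the simplest choice preserving periodic solvability).

Treating this relation explicitly is violently unstable: the projection
pressure responds to a change of source strength at $O(\rho/\Delta t)$,
so an explicit update overshoots by orders of magnitude at any practical
time step. The port coupling is therefore implicit: the pressure
response to unit port rate is linear and precomputable (one Green's
field per port), so a small dense system
$(\mathrm{diag}(R) + M)\,Q = P - \bar p_0$ yields rates that satisfy the
defining reservoir law *exactly against the end-of-stage pressure*; a
test asserts that identity. Rates respond to pressure exactly as the
explicit law dictates at quasi-steady state; only the impulsive
transient is regularized.

## The synthetic fixtures

The package's test geometries are generated in code, deterministically,
with no randomness anywhere in the core.

**Ellipse membrane.** A closed spring ring; eccentric initial shape
relaxes toward a circle conserving enclosed area (the incompressibility
oracle), and a pressurized circular ring reproduces the 2-D Laplace law
$\Delta p = T/r$ to a few percent at 64².

**Tethered cylinder.** A stiffly tethered ring in a uniform stream
created by two balanced strip ports (a wide, smooth source upstream and
sink downstream — narrow strips interact badly with arriving wake
vortices). At $Re \approx 100$ the wake develops a time-periodic vortex
street; at $Re \approx 20$ it stays steady. Periodicity is detected from
the autocorrelation of a transverse-velocity probe two diameters
downstream.

**Two-chamber ventricle.** The primary fixture: an elastic atrium and a
conical-sack ventricle joined by a mitral channel with two valve flaps,
plus an aortic sinus pocket with a second flap pair, a pulmonary-vein
port (15 mmHg) in the atrium and an aortic port (80 mmHg) in the sinus.
Its design encodes several lessons that were learned the hard way and
are worth recording:

* *Walls are double sheets.* A single sheet of the diffuse four-point
  kernel is measurably porous under pressure heads of tens of mmHg; two
  sheets offset by $h/4$ with 2.5–3 points per meshwidth hold 80 mmHg
  with leak below 0.1 cm²/s. The anti-leakage rule (point spacing at
  most $h/2$) holds along every fiber.
* *Valve orifices span ~10 meshwidths.* Valves inside a 6-cell channel
  are numerically gummed shut by the overlap of wall kernels.
* *Leaflets are tension-only.* With ordinary (two-sided) Hooke springs
  the closed flap pair props itself across the orifice as a compressed
  arch and never opens; floppy (tension-only) leaflets behave like real
  tissue.
* *Chordae close the valve.* A free flap hinged at one end cannot hold
  an adverse pressure gradient. Each leaflet tip is caged by two
  tension-only chords anchored on the side the adverse gradient comes
  from (both anchors, so no sideways escape is possible), with a
  mid-leaflet chord against bowing through, and a tip-to-tip retainer
  that limits the opening angle so the closing backflow can always fold
  the leaflets back (leaflets that stream flat against the walls never
  re-close). Closure is still approximate — there is no contact
  algorithm — so some mitral regurgitation and a negative PV flow phase
  during systole are expected features of the model, as they are of the
  anatomical-heart computations this fixture stands in for.
* *Mitral leaflets overlap; aortic leaflets meet edge-to-edge.* The
  closed mitral is a doubled, vertically staggered sheet (far tighter
  than a butt joint) and opens by peeling as both leaflets swing the
  same way. The aortic valve cannot overlap: overlapped sheets would
  have to slide apart to open, and the squeeze film between two sheets
  a fraction of a meshwidth apart is unresolvable, cementing the valve
  shut against forward flow. Its leaflets therefore meet edge-to-edge
  and carry a weak, always-taut opening preload toward the sinus — a
  nearly-closed pair self-seals through the Bernoulli suction of its
  own leak slit, and the preload breaks that equilibrium at systole
  while remaining negligible against the adverse diastolic gradient.
* *Leaflets start open.* The run begins quiescent in early diastole
  with the mitral leaflets in their natural hanging position; a closed
  floppy valve under a static favorable gradient can wedge itself shut
  (the same slit-suction equilibrium), making the first filling
  erratic.
* *Contraction is rest-length driven.* Systole multiplies the
  ventricular rest length by 0.26 under nearly constant stiffness
  (k multiplier 1.3); modulating stiffness strongly raises the elastic
  eigenfrequency mid-cycle and destabilizes the explicit coupling long
  before it adds realism. The atrial pulse is a cosine bump at 0.5 T
  (stiffness x2, rest length x0.62 at peak, half-width 0.12 T).

The activation schedule follows the standard phase convention: diastole
0–0.75 T with the E-wave in early diastole and the atrial pulse centered
at 0.5 T, systole 0.75–1.0 T; the cycle period is $T = 0.8$ s. The
contraction ramps up over 0.10 T at systole onset, holds through the
cycle wrap, and releases over 0.03–0.10 T. All ramps are
piecewise-cosine and $C^1$.

The packaged analysis protocol starts the run quiescent with the
activation clock at the end of the release ramp (phase 0.10) — starting
inside the plateau would slam the walls at $t = 0$ — and analyzes the
first full cycle: the E-wave is the first filling jet driven into a
pristine chamber by the pulmonary-vein head, which is also how bench
models of ventricular filling (a flexible conical sack filled through a
valve) produce their vortex pair. The waveform analysis window ends at
the onset of the next release, which belongs to the following beat.

Two analysis conventions keep the diagnostics instrument-like rather
than solver-like. First, waveform series (kinetic energy, port rates)
are beat-resampled into 32 phase bins before peak detection — clinical
cine acquisitions resolve a beat into a few dozen frames, and per-step
samples additionally carry grid-scale solver ringing no instrument
would see. Second, snapshot fields are analyzed at a physical
resolution of $\sigma = 0.2$ cm (about the in-plane voxel size of the
velocity mapping used to verify such models), with the wall-adjacent
kernel layer plus a 0.2 cm margin excluded; this removes the
collocated-scheme checkerboard noise and the boundary layer where
fields mix wall and fluid dynamics. Both conventions are fixed
constants of the analysis, independent of the grid.

Stiffness inputs are *tension moduli* $K$ (dyn/cm): per-segment spring
constants are $K/\ell_0$, so the line tension at a given strain is
independent of the fiber discretization and the same physical fixture
emerges at every grid resolution. The moduli (ventricle and atrium
$2\times10^5$, leaflets $3\times10^5$, chords $6\times10^5$ dyn/cm) were
chosen so diastolic strains are ~10 % at filling pressures and systolic
wall tension supports left-ventricular pressures above the 80 mmHg
aortic reservoir — the condition for an ejection phase with aortic
outflow. Port resistances (0.22 and 0.35 mmHg·s/cm²) make the
reservoirs stiff pressure clamps relative to the residual numerical
porosity of the walls, and fast enough that the passive filling wave
peaks and decays before the atrial pulse.

What the fixture does *not* emulate: anatomical fiber architecture,
three-dimensional vortex ring dynamics (the primary fixtures are 2-D; a
3-D ellipsoid shell exists as a smoke test only), transmural wall
mechanics, and turbulence (the flow is laminar by assumption; at the
physiological Reynolds numbers of a real heart a 64² desk grid could
not resolve the boundary layers anyway). Passing tests therefore show
that the method reproduces the *mechanisms* — recoil-driven E-wave
filling with a two-signed vortex pair flanking the transmitral jet, an
E/A/S kinetic-energy peak structure with E above A, reservoir-driven
port exchange with the observed sign structure — not that the fixture
is quantitatively a heart.

## Time steps and problem sizes

The explicit fiber force limits the step: the stiffest spring must
satisfy $\omega\,\Delta t \lesssim 1$ with
$\omega \approx \sqrt{2k_{\rm seg}/\rho h^2}$. For the default ventricle
moduli this gives $\Delta t = 2\times10^{-5}$ s at $h = 0.1$ cm, scaled
as $h^{3/2}$ on finer grids (the per-segment constant grows as
$1/\ell_0$ while the fluid added mass shrinks as $h^2$). A cycle of
0.8 s is then 40 000 steps at 64². The packaged analyses run one full
cycle from quiescence; the grid-refinement comparison runs both
resolutions through the identical protocol up to the early-diastolic
vortex pair and compares the signed core counts at the same instant.
These sizes keep a full analysis cycle in minutes on one core while
resolving the valve orifices with ~10 cells.

## Numerical choices and degenerate inputs

* Pressure gauge: zero spatial mean, fixed in every solve.
* Coincident spring endpoints contribute zero force (the defined limit)
  and are flagged with a warning.
* Fiber positions are stored unwrapped; periodicity is applied only
  inside kernel evaluation, so spring lengths are well defined across
  the seam.
* Vortex-core counting uses |ω| above 0.2 of the field maximum,
  8-neighbor connectivity with periodic wrapping, discarding components
  under 4 cells; KE peak detection uses prominence ≥ 0.1 of the series
  maximum. These thresholds are documented defaults — the choice is the
  package's own.
* Chamber area uses the shoelace rule on the ordered wall loop, closed
  by a chord across the valve openings; self-intersection raises.
* Runs are bitwise deterministic: there is no randomness in the core,
  and restart from a checkpoint continues to the identical state.

## Known limitations

The diffuse-interface kernel leaks slightly under sustained large
pressure differences even through double walls; port resistances are
chosen so reservoirs dominate this leak. Valve closure is approximate
(no contact forces), so regurgitant flows are larger than physiological.
The collocated centered scheme supports local odd–even pressure
oscillations near sharp force layers; they carry no net flux and do not
affect the integral diagnostics, but they are visible in point probes.
The 2-D fixtures conserve area rather than volume, so flow rates are in
cm²/s; the non-dimensionalization by stroke "volume" and cycle period
makes the waveforms comparable to volumetric data.
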
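---
title: "Thermal modelling of an infection-sensing vascular graft: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal modelling of an infection-sensing vascular graft}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(graftherm)
```

## The problem

A vascular graft replacing a segment of the descending aorta can become
infected; bacteria metabolize and release heat, so a heat-flux sensor
embedded in the graft wall could in principle detect an infection long before
systemic symptoms.  Whether that works hinges on two coupled questions:

1. How efficiently does the blood flow drain heat from the wall?  This is the
   blood-side heat-transfer coefficient `h(z, t)`, which depends on the flow
   regime, the distance `z` from the inlet of the modelled segment, and the
   pulsatility of the flow.
2. Given `h`, how much of the heat released by an infection of a given size,
   position and metabolic density actually crosses the sensor, and does that
   flux exceed the resolution of a real heat-flux sensor (0.41 W/m²)?

`graftherm` implements both stages as desk-scale numerical models, plus the
surrounding arithmetic: flow-regime classification, synthetic aortic pressure
waveforms, biofilm power densities, and a hexagonal sensor-array design.

## Flow regimes

The classification uses the standard pipe-flow numbers: Reynolds
`Re = rho v D / mu`, Prandtl `Pr = cp mu / k`, the entry lengths
`L_h = 0.05 Re D` and `L_th = L_h Pr`, and the Womersley number
`alpha = r sqrt(2 pi f rho / mu)`.  Blood defaults are
`rho = 1060 kg/m³`, `mu = 2.78e-3 Pa s`, `cp = 3617 J/(kg K)`,
`k = 0.52 W/(m K)`; the viscosity is calibrated so that the laminar aortic
reference condition (`D = 2 cm`, `v = 0.11 m/s`) lands at `Re ≈ 838`.  With
these numbers the physiological window (`0.11–0.65 m/s`, `0–20 cm`) spans the
laminar developing region at the lowest velocities and the transitional
("low-Reynolds turbulent") band `2300 < Re < 8000` above about `0.3 m/s`.
Reynolds values exactly on a threshold are assigned to the lower regime; the
inequalities in the usual textbook statement are strict and do not decide the
boundary, so some convention is needed and this one is fixed and documented.

A note on the entry-length formula: for `Re = 838` the diameter-based formula
gives `L_h = 0.838 m`.  A value of `0.42 m` circulates for the same condition;
it corresponds to using the radius instead of the diameter.  The package
implements the diameter form and flags the discrepancy in the function
documentation rather than silently adopting either number.

## Oscillatory velocity: the Womersley stage

Pulsation is modelled as a travelling pressure wave with pulse-wave velocity
`c = 8.8 m/s`.  The oscillatory velocity component `u(r, t)` obeys the linear
momentum equation

    rho du/dt = mu (d²u/dr² + (1/r) du/dr) + s(t, z)

with no-slip at the wall and symmetry on the axis.  Three forcings are
supported: zero (steady flow), a sinusoid `A sin(2 pi f (t − z/c))`, and the
`(1/c) dP/dt` of a periodic pressure waveform evaluated at the retarded time.
On the amplitude convention: writing the sinusoidal source with an extra
`1/c` factor while quoting `A` in Pa/m is dimensionally inconsistent (the
forcing in this equation must carry Pa/m).  The package therefore treats `A`
as the amplitude of the *full* forcing by default and provides
`convention = "divided_by_c"` for sensitivity checks against the literal
transliteration.

The solver is Crank–Nicolson in time (unconditionally stable, second order)
on a radial node grid, with the removable axis singularity replaced by its
symmetry limit `2 d²u/dr²`.  Verification is two-fold: the step-forcing
steady state against the Poiseuille parabola, and the periodic state against
the closed-form Womersley solution built from the complex Bessel function
`J0` (evaluated by power series, accurate to `|z| ≤ 30`, i.e. `alpha ≤ 30`).
One practical subtlety: starting from rest, the homogeneous transient decays
on the viscous time scale `R²/nu`, which at `alpha = 15` is tens of forcing
periods.  Oracle comparisons therefore run either at moderate `alpha`
(fast decay) or over a long horizon; the tests use `alpha = 3` over six
periods and `alpha = 15` over sixty.

## Steady conjugate heat transfer and h(z)

The steady stage is a parabolic (boundary-layer) marching solver for
developing axisymmetric pipe flow: at each axial station an implicit radial
solve advances momentum, the pressure gradient is adjusted exactly (the
discrete problem is affine in `dp/dz`) to conserve mass flow, and the radial
velocity follows from discrete continuity.  The energy equation is then
marched with a flux-conservative finite-volume stencil, so the bulk enthalpy
rise equals the wall heat input to round-off; the prescribed wall flux is
`q_in = 200 W/m²` and the inlet is at body temperature, 310.15 K.

The heat-transfer coefficient is `h = q / (T_wall − T_bulk)` with the bulk
(mixing-cup) temperature `T_bulk = ∫ v T r dr / ∫ v r dr` over the full
cross-section.  The version of this integral sometimes printed with limits
`0..r/2` and no radial weight is not implementable as stated (it is neither
the area mean nor the flow-weighted mean); the package uses the standard
mass-flow-weighted mean and documents the choice.

Turbulence closure.  The reference workflow uses a proprietary low-Reynolds
k–ε model; that closure is out of scope here.  Instead the package uses an
algebraic mixing-length model — Nikuradse length-scale profile, Van Driest
damping (`A+ = 26`), turbulent Prandtl number 0.9 — multiplied by an
intermittency factor ramping linearly from 0 at `Re = 2300` to 1 at
`Re = 8000`, so the transitional band is not treated as fully turbulent.
Consequences, measured on the solved fields: velocity profiles in the
transitional regime flatten below the Poiseuille peak (centerline/mean
< 2); `h(z)` decreases monotonically over `z = 0.01–0.20 m`; the two-term
power law `h(z) = a z^(−1/2) + c z^(−3/2)` (exponents fixed) fits the
`v = 0.35 m/s` profile with R² ≥ 0.99, degrading toward ~0.84 at
`0.65 m/s` where the algebraic closure flattens `h(z)` more than k–ε would.
The absolute `h` envelope over the study window is of the same order as the
published 200–4800 W/(m² K) range but not equal to it; quantitative `h` in
the transitional regime is closure-dependent and the package makes no claim
of reproducing k–ε values exactly.

Verified anchors: the laminar constant-flux limit reaches the Graetz value
`Nu = 48/11` within 2% (run with a low-Prandtl fluid so the thermal field
develops inside the domain), mass flow is conserved to machine precision,
and a tapering radius raises `h` at every station.  Taper is carried in the
similarity coordinate `r/R(z)` with the mean velocity rescaled for mass
conservation — adequate for monotonicity statements, not for quantitative
tapered-duct work.

## Pulsatile h(z, t)

The transient temperature equation is advanced with the superposed velocity
`v_z = v_steady(r, z) + u(r, t − z/c)`; the coupling is one-way (the
oscillation does not feed back into the mean-flow momentum or the eddy
viscosity), mirroring the two-study structure of the reference workflow.
The scheme is Strang-split: explicit upwind axial advection (CFL
sub-stepped) around an implicit radial solve, initialized from the steady
solution so only the pulsatile perturbation must equilibrate.  `h(z, t)` is
recorded at 20 stations (0.01–0.20 m) and averaged over the trailing window
(the last 5 s of a 10 s horizon at full scale).

The split scheme's own fixed point deviates from the marching steady
solution near the inlet (first-order advection on a uniform grid, against a
graded-grid march).  Pulsatility changes are therefore always computed
against a zero-pulsation baseline run with the *same* transient scheme, so
the discretization bias cancels; the test suite checks the baseline is
time-stationary and agrees with the marching solution away from the inlet.
With the one-way coupling the time-averaged pulsatility effect is small
(well inside the reported −25% to +33% station spread); the larger mean
decreases reported for k–ε at 2–3 Hz arise from turbulence–pulsation
interaction that an algebraic closure cannot produce, and are treated as
qualitative only.

## Biofilm power arithmetic

A single E. coli cell releases 3.5 pW in a 1.49 µm³ volume, i.e.
2.35 MW/m³; a biofilm at 15% cell occupancy gives 352,350 W/m³, presented as
350,000 W/m³ (two significant figures).  Sweep sources are expressed as
percentages of that *presented* base — this choice, rather than the exact
352,350, reproduces the canonical table
{1000 → 0.29%, 2000 → 0.57%, 4000 → 1.14%, 10000 → 2.86%, 50000 → 14.29%}
at two-decimal rounding.  Both raw and presented values are returned.

## The 3D graft conduction model

Geometry: three nested cylinders — lumen wall at 10 mm radius, graft outer
wall at 11.05 mm, tissue out to 20 mm — over a 60 mm axial domain (end
effects on the sensor flux are below 0.1%; the domain is several diffusion
lengths longer than the largest infection).  A 4.4 × 4.4 × 0.5 mm heat-flux
sensor sits mid-wall (275 µm encapsulation each side, the nominal
quarter-millimetre PDMS case), and an infection is a 450 µm thick disc on
the graft outer surface with variable radius and arc-length offset `d` from
the sensor (angle `d / r_graft`).  Conductivities (W/m K): PDMS 0.15 <
PTFE 0.25 < ePTFE 0.28 < Dacron 0.33; tissue 0.48; sensor stack 1.0.  All
are assumptions standing in for unpublished supplementary values and all are
configurable.

Discretization: cell-centred finite volumes on a conforming `(r, θ, z)`
grid; radial faces coincide with every material interface and conductances
use serial (harmonic) averaging, so material jumps are exact.  Boundary
conditions: Robin at the lumen (`−k dT/dr = h (T − 310.15)`,
`h ∈ [200, 4800] W/(m² K)`) and Dirichlet 310.15 K on the outer and end
surfaces.  The symmetric system is solved by sparse Cholesky factorization
(CHOLMOD via the Matrix package) rather than a preconditioned iteration: the
factor at a given `h` is reused across every `(Q, radius, d)` right-hand
side of a sweep, which is both faster and exactly reproducible.  Discrete
conservation (generated power = boundary outflow) holds to solver precision
and is asserted in the tests.  The infection disc is antialiased: boundary
cells receive the sub-cell overlap fraction of the disc (4 × 4 subsampling),
which keeps the total source power grid-independent and gives sensor-flux
changes below 2% under 1.5× lateral refinement from the working grid
(64 × 40 cells in θ × z).

Sensor flux convention.  The reported quantity is the average of the
conductive through-fluxes on the two sensor faces (infection-facing and
lumen-facing), positive toward the lumen.  This equals the printed
half-difference formula when each face carries its own outward normal.  The
alternative literal reading — both faces oriented toward the lumen — yields
the net heat absorbed by the source-free sensor sheet, which is essentially
zero in steady state and cannot reproduce any of the study's flux numbers;
it is available as `convention = "signed_difference"` for completeness.

Heat-transfer efficiency.  A uniform inward flux is applied on the graft
outer wall over a patch congruent with the sensor footprint (an interface
heat sheet, deposited into the adjacent cells in proportion to their
half-cell conductances — the exact finite-volume representation), and the
efficiency is the percentage recovered as sensor-average flux.  Under the
package defaults this gives ≈ 27% at `h = 200` rising to ≈ 41% at
`h = 4800 W/(m² K)`.  The relative step across the `h` range (×1.48)
matches the published ×1.53, but the absolute level is below the published
43–66%.  A sensitivity study (sheet deposition side, sensor-stack
conductivity 1–10 W/m K, wall-thickness readings of the "250 µm PDMS"
phrase, and a wall-only variant in which the patch is a prescribed-flux
boundary window) moves the pair between roughly 26/38 and 69/83 without any
configuration reproducing 43/66; the published values evidently depend on
supplementary-table geometry that is not recoverable from the main text.
The package reports what its stated geometry computes and does not calibrate
to the published pair.  A `include_tissue = FALSE` wall-characterization
variant is exported for users who want the boundary-window reading.

Detection.  The detectability sweep reproduces the study's decision
structure quantitatively: at `h = 1200 W/(m² K)` a 4 mm, 2000 W/m³
infection directly above the sensor yields ≈ 0.5 W/m² (above the 0.41 W/m²
resolution); a 2 mm infection needs 4000 W/m³ on the canonical source grid;
at 10,000 W/m³ detection persists beyond `d = 5.24 mm`; and the
sensor-location temperature rise for the 2000 W/m³, 4 mm case stays within
0.0025–0.0030 K over the full `h` range — about thirty times below typical
temperature-sensor resolution, which is the argument for flux sensing.

## Sensor-array design

A detection radius `d` converts to a hexagonal lattice with constant
`a = √3 d` and per-site area `(√3/2) a²`; the sensor count is the ceiling of
lateral area over site area, which gives exactly 177 sensors for a 20 cm,
1 cm-radius graft at `d = 5.24 mm` and 100 at `d = 6.98 mm`.  Realized
positions wrap staggered rows onto the cylinder with the angular pitch
snapped to an integer divisor of the circumference; since a cylinder admits
no perfect hexagonal tiling, the packed count exceeds the area count by a
few percent (182 vs 177 at 5.24 mm) while guaranteeing full coverage —
verified numerically against a dense probe grid.  Both counts are reported;
the area count is the design number, the packing a layout diagnostic.

## Synthetic pressure waveform

The generator produces a band-limited periodic trace with a systolic
upstroke, dicrotic notch and diastolic decay: a fixed template pulse is
Fourier-truncated to `n_harmonics` (default 8), given a small seeded
perturbation of the harmonic amplitudes, and affinely rescaled to hit the
systolic/diastolic targets (defaults 120/80 mmHg at 60 bpm) exactly.  It
emulates the frequency content and amplitude of a real aortic recording, not
any particular patient's morphology; passing tests therefore demonstrate the
machinery, and transfer to a measured waveform goes through the CSV reader
(`time_s, pressure_pa`), which resamples arbitrary monotone grids.  The
pipeline seed governs only this synthesis; every solver is deterministic.

## Problem sizes

Full-scale runs use 64 radial nodes with wall clustering and 240 axial
stations for the steady march; 10 s transients at `dt = 5 ms` on a 100-cell
uniform axial grid; and the 64 × 40 (θ × z) graft grid (~33k cells, one
sparse factorization per `h`).  The test suite runs the same code on
shortened horizons and coarser grids (3 s transients, 48 × 30 graft cells)
chosen so each oracle comparison still has the headroom its tolerance
requires.

## Known limitations

- The algebraic closure makes transitional-regime `h` approximate; only
  regime structure, monotonicities, laminar limits and the power-law shape
  are quantitative claims.
- Pulsatility effects on time-averaged `h` are qualitative (one-way
  coupling; no turbulence–pulsation interaction).
- The 3D efficiency level depends on unpublished sensor-mounting geometry;
  see above.
- No aortic arch curvature, branching, wall distensibility or Windkessel
  dynamics — excluded by design; the vessel is a straight (optionally
  tapered) cylinder.
- Viscous dissipation in the 2D stage is neglected (negligible at these
  velocities); the 2D stage applies a prescribed wall flux rather than
  conjugate wall conduction.
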
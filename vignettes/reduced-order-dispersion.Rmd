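---
title: "Reduced-order solute dispersion in oscillatory flow: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-order solute dispersion in oscillatory flow: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(csfdrift)
```

## The model

Cerebrospinal fluid in the spinal subarachnoid space oscillates with the
cardiac cycle (period $T \approx 1$ s) while an injected drug disperses over
hours. The package separates these scales with a three-step reduced model:

1. **Flow.** One cycle of the incompressible velocity field
   $\nabla\cdot\boldsymbol v=0$,
   $\partial_t\boldsymbol v+\boldsymbol v\cdot\nabla\boldsymbol v
   =-\rho^{-1}\nabla p+\nu\nabla^2\boldsymbol v$, computed once and stored
   as 100 phase snapshots.
2. **Drift.** The mean Lagrangian velocity of fluid particles. In the
   small-stroke limit it is the streaming velocity plus the Stokes drift,
   $$\boldsymbol v_L=\langle\boldsymbol v\rangle+\Big\langle
   \int(\boldsymbol v-\langle\boldsymbol v\rangle)\,\mathrm dt\cdot
   \nabla(\boldsymbol v-\langle\boldsymbol v\rangle)\Big\rangle ,$$
   with $\langle\cdot\rangle$ the cycle average. At physiological stroke
   lengths this linearization fails, and the drift is instead measured from
   one-cycle trajectories, $\boldsymbol v_L^*(\boldsymbol x_o)=
   \delta\boldsymbol x/T$ attached at the cycle-mean particle position
   $\boldsymbol x_o$. The trajectory-based field is not solenoidal at finite
   stroke; writing its advection term in conservative form exposes a
   spurious sink/source density $-c\,\nabla\cdot\boldsymbol v_L^*$, so the
   gradient part is removed by a Helmholtz projection
   $\boldsymbol v_L=\boldsymbol v_L^*-\nabla\Phi$,
   $\nabla^2\Phi=\nabla\cdot\boldsymbol v_L^*$.
3. **Transport.** The reduced equation
   $\partial_t c+\boldsymbol v_L\cdot\nabla c=\kappa\nabla^2 c$ integrated
   on the dispersion time scale, benchmarked against the full oscillatory
   equation with $\boldsymbol v(\boldsymbol x,t)$. Dispersion is measured on
   the cross-sectionally integrated profile $C(x,t)=\int c\,\mathrm ds$
   through the center of mass $\bar x(t)$, the variance $\sigma^2(t)$, and
   the secant hydrodynamic diffusivity
   $\kappa_H(t)=[\sigma^2(t)-\sigma^2(0)]/(2t)$.

The key physical contrast: for a purely oscillatory, spatially non-uniform
flow the Eulerian mean can vanish identically while particles drift. The
Eulerian-mean comparison model (replacing $\boldsymbol v_L$ by
$\langle\boldsymbol v\rangle$) therefore underpredicts dispersion; the
package keeps it as a selectable variant (`comparison_eulerian`) precisely
to quantify that deficit.

## Study conditions: the desk-scale cervical channel

`channel_scenario()` builds a two-dimensional analog of a five-segment
cervical canal:

| quantity | value | why |
|---|---|---|
| segment length | 1.6 cm | C3–C4 intervertebral distance |
| channel height | 1.172 cm | mean open cross-section at unit depth, so the segment volume is 1.875 mL |
| transport domain | x = 1.6 … 9.6 cm | five stacked segments, open (outflow) ends |
| waveform | $Q_0\sin(2\pi t/T)$, $Q_0=\pi\cdot 0.823$ mL/s, $T=1$ s | stroke volume $V_s=\tfrac12\oint|Q|\,\mathrm dt=0.823$ mL, hence $\varepsilon=V_s/1.875=0.439$ |
| viscosity | $\nu=2\times10^{-6}$ m²/s | see below |
| Schmidt number | 1000 | drug-like molecular diffusivity $\kappa=\nu/1000$ |
| bolus | $c=\exp[-(x-5.6)^2/0.5]$, uniform across the section | canonical mid-canal injection |
| comparison time | $t=60\,T$ | long-time dispersion regime |

**Viscosity.** At the CSF value ($0.7\times10^{-6}$ m²/s) the oscillatory
Stokes layer is 0.047 cm thick — under three cells of the 64-cell
transverse grid. The scenario fluid uses $2\times10^{-6}$ m²/s, which
widens the layer to about five cells while keeping the Womersley number
near 10, still firmly in the physiological high-frequency regime; the
Schmidt number is held at 1000 so the solute remains drug-like.

**Obstacles.** The obstructed variant places two wall-mounted wedges per
segment (0.5 cm long, 0.66 cm tall, 0.8 cm apart; stair-step masked).
Their axial slant mirrors the oblique, caudally slanted exit of nerve
rootlets from the spinal cord, and their size and spacing are comparable to
the stroke length $V_s/A = 0.70$ cm. The design criterion was the *drift
topology*, not any transport outcome: an earlier, symmetric obstacle pair
(two circles related by a glide symmetry) produced a drift field of closed
recirculation cells in which no particle crossed a segment within 21
periods — qualitatively unlike an obstructed canal, where obstacles disrupt
recirculation and open intervertebral connecting pathways. The wedges break
that symmetry; with them roughly a quarter to a third of drift trajectories
traverse a full segment within 21 periods, the obstructed channel requires
about twice the forcing amplitude of the patent one, and the Eulerian-mean
model underpredicts dispersion by tens of percent.

**What the scenario does not emulate.** It is two-dimensional: no azimuthal
drift structure, no denticulate-ligament sheets, no spinal-cord
eccentricity; walls are rigid (no dura compliance); the waveform is a single
harmonic (no respiratory component); obstacles are stair-step rather than
body-fitted. Agreement of the reduced and benchmark solvers under these
conditions demonstrates the machinery and the drift-dominated mechanism, not
patient-specific accuracy.

## Numerical methods

### Flow solver (`solve_oscillatory_channel`)

Staggered (MAC) grid, fractional-step projection. Advection and diffusion
are explicit (conservative centered fluxes, second-order Adams–Bashforth);
sub-steps obey both the advective CFL (Courant 0.35) and the explicit
diffusion limit, which at the study conditions are of comparable size, so a
semi-implicit viscous treatment would buy little. The pressure Poisson
problem (periodic in $x$, Neumann at walls and stair-step solids) is
factorized once (sparse Cholesky; the constant nullspace is grounded at the
first fluid cell) and back-solved every sub-step, making each snapshot
machine-divergence-free — the reason velocity snapshots are stored on faces
rather than cell centers.

**Flow-rate controller.** The physiological boundary condition is a flow
rate, not a pressure gradient. A spatially uniform axial body force (the
surrogate of the section-to-section pressure difference) is updated each
sub-step by a PI(D) law acting on the flow-rate error. The plant gain is
identified exactly once from the projected unit-force response, so gains
are dimensionless fractions of the deadbeat gain; defaults
$k_p=0.9,\;k_i=0.05,\;k_d=0$ give per-phase tracking errors near $10^{-3}$
relative. (No gains are standard for this configuration; these were chosen
for tight deterministic tracking and are recorded in the controller state.)
Convergence to the permanent periodic regime is declared when the
cycle-to-cycle residual $\max_t\|v(\cdot,t)-v(\cdot,t-T)\|_\infty/
\max\|v\|_\infty$ falls below $10^{-4}$; initializing from the analytic
patent-channel profile reaches this within ten cycles at the study
conditions, versus many tens of cycles from rest.

### Analytic oracle (`womersley_channel_flow`)

The exact laminar pulsatile profile in a plane channel, assembled harmonic
by harmonic from the waveform's Fourier modes (a steady Poiseuille part
carries any nonzero mean). The constructor verifies that the discrete
cross-sectional integral reproduces $Q(t)$ to 0.5% and refuses otherwise.
Against this oracle the Navier–Stokes solver shows a per-phase relative
$L_2$ error of about $2\times10^{-3}$ at 64 transverse cells, improving by
a factor near 4 per mesh halving (second-order scheme contract).

### Particle tracking (`advect_particles`)

Classical four-stage Runge–Kutta with sub-step equal to the snapshot
interval ($T/100$); velocity at arbitrary points by staggered bilinear
interpolation with ghost layers that mirror across no-slip walls (so the
interpolant vanishes there) and wrap across the periodic seam; periodic
linear interpolation in time. The axial coordinate is unwrapped, so
$\delta\boldsymbol x$ is exact across the seam, and $\boldsymbol x_o$ is
accumulated as a running trapezoid of the unwrapped trajectory. A particle
whose position enters a solid cell is truncated (`entered_solid`) and
excluded from deposition; leaving an open boundary gives `left_domain`. At
the study conditions about 1% of seeds are lost, well under the 5% warning
threshold.

Seeding follows the cell centers of every fluid cell, with 20 initial
phases spaced $0.05\,T$; each (seed, phase) sample is deposited
independently and the averaging happens on the grid. (Whether the mean
position should be phase-averaged before deposition is ambiguous; depositing
independently uses strictly more information and is the package's choice.)

### Deposition (`scatter_to_grid`)

Moving least squares with a linear basis and inverse-squared-distance
weights floored at half a cell, gathered from growing bin neighbourhoods:
exact on linear data (any weights), exact when samples sit on the evaluated
center (dedicated branch), smoothing over the 20-phase sample cloud
otherwise, with a flagged nearest-sample fallback for cells with fewer than
three usable samples. A simplex (Delaunay) interpolant would also work;
MLS needs no triangulation and handles the near-duplicate positions the
phase ensemble produces.

### Helmholtz projection (`project_solenoidal`)

The discrete gradient $G$ over fluid cells is an explicit sparse operator —
centered where both neighbours are fluid, one-sided against walls and
obstacles, periodic across the seam — and the divergence is *defined* as its
negative adjoint, $D=-G^{\mathsf T}$. The projection solves the normal
equations $G^{\mathsf T}G\,\Phi=G^{\mathsf T}\boldsymbol v^*_L$ by
Jacobi-preconditioned conjugate gradients (relative tolerance $10^{-10}$),
with the known nullspace (constants, plus the parity modes the wide
centered stencil cannot see on fully periodic grids) deflated and a
stagnation guard for roundoff-level right-hand sides. Because the solve is
a least-squares projection, three contracts hold *by construction*:
$D\boldsymbol v_L$ equals the CG residual (divergence kill ratios of
$10^{-10}$ and better), projecting twice equals projecting once, and
$\|\boldsymbol v_L\|_2\le\|\boldsymbol v^*_L\|_2$ with exact discrete
orthogonality of the removed gradient. The Neumann condition
$\partial\Phi/\partial n=\boldsymbol v^*_L\cdot\boldsymbol n$ on solid
boundaries (restoring impermeability of $\boldsymbol v_L$) is implied by
the one-sided rows of $G$; no boundary condition is standard for this
problem, and this choice is the package's. The pure-Neumann gauge is a zero
fluid-cell mean.

### Transport solvers

One conservative finite-volume kernel (compiled) serves both solvers.
Advection uses flux-limited upwind reconstruction — the Koren limiter
(third-order $\kappa=1/3$ scheme where smooth) by default; an unlimited
third-order scheme oscillates on these grids, and the limiter's bounded
undershoot ($|c_{\min}|\le10^{-10}$) is asserted. Diffusion is explicit
centered. Time stepping is SSP-RK2 with sub-steps from the CFL (0.35) and
diffusive limits; the requested step (0.01 s for the oscillatory benchmark,
1 s for the reduced solver) is an upper bound that the kernel reduces
automatically — at the study conditions the drift CFL brings the reduced
step to about 0.016 s — and both values are recorded. Open ends extrapolate
first-order upwind with exiting mass accumulated in a ledger; the ledger
closes to $10^{-12}$ relative (asserted at $10^{-6}$). The reduced solver
accepts only `lagrangian_solenoidal` or `eulerian_mean` drift roles: raw
trajectory drift is rejected with a conservation error. Steady center
fields are averaged to faces and cleaned by one projection so the kernel
always sees a machine-divergence-free face field; the single-segment field
is tiled five times for the transport domain.

### Degenerate inputs and tie-breaks

Zero waveforms produce zero fields and zero forcing; zero-amplitude
manufactured waves are identically zero; a zero Poisson source returns the
gauge-fixed zero potential; upwind ties at exactly zero face velocity take
the west/south cell (sign convention `u >= 0`); limiter ratios with zero
local difference fall back to first order; cells whose gradient stencil
would cross a solid use one-sided differences and are flagged in metadata.

## Problem sizes

Unit tests run on 16–96-cell grids in seconds. The acceptance study uses
the scenario defaults: a 64 × 64 single-segment flow grid (320 × 64 tiled
transport domain), 100 phase snapshots, 20 seeding phases (about 76 000
trajectories), and 60-cycle transport runs; the whole acceptance script
completes in a few minutes on one CPU.

## Known limitations

* The asymptotic drift formula is used only as a small-stroke oracle; its
  2% agreement band with trajectory drift is verified at
  $\varepsilon\approx0.003$ and tightens linearly (observed: quadratically)
  as the stroke is halved.
* At $\varepsilon=0.44$ over stair-step obstacles the *non-solenoidal*
  fraction of the raw trajectory drift is not small near obstacle corners
  (median over fluid cells ≈ 5%, but max-norm ≈ 60% in the acceptance run):
  the compressive part of $\boldsymbol v^*_L$ concentrates at the stair
  steps. A smooth body-fitted boundary would reduce it; the projection
  removes it regardless, which is the step's purpose.
* The secant diffusivity $\kappa_H(t)$ of the 2-D benchmark does not
  plateau to within 2% between 50 and 60 cycles: the bolus initially
  straddles the fast drift pathway, and the resulting early shear burst
  leaves a $1/t$ memory in the secant. The corresponding three-dimensional
  canal approaches its plateau from below; this property did not transfer
  to the desk-scale analog for any obstacle arrangement tried.
* The benchmark's center of mass drifts rostrally as mass leaves the caudal
  end preferentially; the reduced model reproduces the variance growth
  (1.5% at 60 cycles in the acceptance run) more faithfully than the
  center-of-mass shift.
* Excluded physics: buoyancy, dura compliance, drug uptake, the injection
  phase, respiratory forcing, non-Newtonian rheology, and
  three-dimensionality.
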
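---
title: "Vorticity measures for airway aeration: models, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vorticity measures for airway aeration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sinusflow)
```

## The problem

The maxillary sinuses exchange air with the nasal passage only through a
narrow ostium, and how vigorously (and how chaotically) that exchange
happens is believed to matter for sinus physiology. Patient-specific CFD
studies characterise this with *vorticity measures*: scalar summaries of a
velocity field that quantify local spinning, vortex organisation and
dissipation, averaged over the whole airway lumen and over the breathing
cycle. Healthy anatomies show the smallest values; obstructions such as a
deviated septum raise them.

This package implements that measurement pipeline in a reusable,
verifiable form: the measures themselves, the breathing model, readers and
writers for voxel velocity fields, and — because no patient data ship with
it — analytic verification fields, airway-like phantoms and a small
laminar solver that generates physically consistent unsteady fields on
them.

## Measures and averaging

With gradient tensor $G = \nabla u$, strain/spin split
$D = (G + G^\top)/2$, $A = (G - G^\top)/2$ and vorticity
$\Omega = \nabla \times u$, the pointwise densities are the vorticity
magnitude $\lVert\Omega\rVert$ (1/s), helicity $u \cdot \Omega$ and its
absolute value (m/s²), enstrophy $\tfrac12\lVert\Omega\rVert^2$ (1/s²),
$Q = \tfrac12(\lVert A\rVert_F^2 - \lVert D\rVert_F^2)$ (1/s²), and
$\lambda_2$, the middle eigenvalue (sorted descending, the Jeong–Hussain
convention — the source convention is not always stated, so we fix it
explicitly) of $D^2 + A^2$. Each density is volume-averaged as
$\frac{1}{|V|}\int_V f\,\mathrm dV$, evaluated as the voxel-volume-weighted
sum over all inside voxels divided by $|V|$; boundary voxels are retained
so $|V|$ is the whole lumen volume. The double-bar measure is the time
average of the volume averages — the arithmetic mean of the per-snapshot
values whose time falls in the phase window (rectangle rule at the fixed
step). With the two phases of equal length, the full-cycle value is
exactly the mean of the expiration and inspiration values, which is the
arithmetic the published per-patient tables follow.

Useful exact identities, all enforced in the tests: $\lVert A\rVert_F^2 =
\tfrac12\lVert\Omega\rVert^2$, $\lVert\Omega\rVert^2 = 2E$,
$\lambda_1+\lambda_2+\lambda_3 = \operatorname{tr}(D^2+A^2) = -2Q$, and
$\bar{\bar Q} + \tfrac12\langle\lVert D\rVert^2\rangle =
\tfrac12\bar{\bar E}$ (the global balance between strain power and
enstrophy).

## Breathing model

The inlet flow rate is $\dot V(t) = A\sin(2\pi t/T)$ in ml/s with defaults
$A = 267$ ml/s and $T = 4$ s — a tidal volume of $AT/\pi \approx 340$ ml
and minute ventilation of 5.1 L/min at 15 breaths/min. (The source
literature states A "in seconds", an apparent unit slip; treating A as a
flow-rate amplitude in ml/s reproduces the printed 5.1 L/min, so that is
the convention used.) Flow is signed positive *into* the domain at the
larynx-side inlet, making the first half-cycle expiration; this makes the
e-then-i ordering of reported tables coincide with time order. Nasal
resistance is defined as
$\mathrm{NR} = \int_w |\Delta p|\,\mathrm dt \,/\, \int_w |\dot V|\,
\mathrm dt$ over a phase window $w$: the source never writes its formula,
and this definition is phase-symmetric, exact for proportional signals and
robust to the zero-flow endpoints of the sine.

## Discrete calculus

Fields live at voxel centres of a uniform Cartesian grid with a boolean
fluid mask. Derivatives use second-order central differences where both
axis neighbours are inside, first-order one-sided differences where only
one is, and a flagged zero where neither is (such voxels also zero their
whole tensor). Planar grids (`nz = 1`) define z-derivatives as zero and
assume a unit depth so volumes and fluxes keep 3-D units. One-sided
stencils rather than ghost extrapolation at the mask boundary is the
simplest defensible choice; its first-order boundary error affects an
$O(h)$ fraction of voxels, so volume averages stay second-order accurate
(verified: the ABC-flow helicity average converges at $\approx 4\times$
per halving of $h$).

$\lambda_2$ uses the trigonometric closed form for symmetric $3\times3$
eigenvalues, vectorised over voxels, with the acos argument snapped to
$\pm1$ when within $10^{-12}$ — exactly repeated eigenvalues land there up
to rounding, and the snap restores exactness for them while staying below
the method's noise floor for genuinely near-degenerate tensors. The test
suite checks all six densities against a brute-force oracle (explicit
loops, explicit characteristic-polynomial eigensolve) to $10^{-10}$
relative on a random masked field.

## Synthetic fields and phantoms

Analytic fields provide closed-form oracles: rigid rotation (all densities
known exactly; central differences are exact on linear fields), the ABC
Beltrami flow ($\Omega = u$, helicity density $\lVert u\rVert^2$, volume
mean $a^2+b^2+c^2$), the planar Taylor–Green vortex (divergence-free, zero
helicity) and plane Poiseuille (pure shear, $Q \equiv 0$). Periodic fields
are sampled endpoint-exclusively at voxel centres so discrete means match
continuous means.

The airway phantom is a straight channel (nasal-passage analog), a
two-voxel wall pierced by a narrow ostium gap at 70 % of the channel
length, and a rectangular cavity (sinus analog) communicating with the
channel only through the gap. Default proportions: 10:1 channel, cavity
$\approx\sqrt{Lw}$ on a side, ostium 10 % of the channel width — chosen so
ostium flow is far slower than channel flow, echoing the anatomy. A
mid-channel floor bump occluding a fraction of the width is the
septal-deviation analog.

**Why the demo phantom is thinly extruded.** For any planar flow the
velocity is in-plane and the vorticity out-of-plane, so helicity is
*identically zero* — a strictly 2-D phantom can never show the
helicity-ordering property (constricted > healthy would read 0 > 0). The
demo therefore extrudes the phantom four voxels in z between no-slip walls
and lets the bump span only half the depth: the healthy duct flow stays
essentially planar (absolute helicity at rounding-to-entrance level,
$\sim10^{-4}$ m/s²) while the constricted flow is genuinely
three-dimensional and helicity-generating ($\sim2\times10^{-3}$ m/s², a
13-fold separation). Planar phantoms remain available and are used for the
Poiseuille verification.

## The toy solver

A projection (fractional-step) scheme on a staggered (MAC) grid over the
mask: explicit predictor — first-order upwind advection and central
diffusion, with no-slip imposed at stair-step walls by linear-reflection
ghosts — followed by a pressure-Poisson solve (sparse Cholesky, factorised
once per mask) with Neumann conditions at walls and inlet and a zero-
pressure Dirichlet condition at the outlet face, then a face-velocity
correction. The staggering makes the discrete divergence exact, so the
inlet/outlet flux imbalance sits at rounding level ($\sim10^{-12}$
relative) rather than merely below the $10^{-6}$ bound asserted in the
tests. The inlet imposes a plug profile matching $\dot V(t)$ (uniform
inflow is the airway boundary contract); a parabolic option exists for
verification runs. The advective CFL number is recorded every step and the
run aborts if it reaches 1; dt must also respect the explicit diffusive
limit $h^2/(2d\nu)$, checked at setup. Runs are deterministic — no random
initialisation — so a saved configuration reproduces its outputs bit for
bit.

Verification: steady planar channel flow reproduces the sampled parabolic
profile (centreline/mean within 0.8 % of 3/2 at 16 voxels across) and the
analytic resistance $12\mu L/w^3$ within 0.9 %, improving under grid
refinement. The resistance check uses the developed (parabolic) inflow: a
plug inflow adds a genuine, length-independent Stokes entrance-development
pressure excess (about 8 % of the viscous drop at aspect ratio 5) that is
physics rather than discretization error.

## Demo study conditions and what they show

The end-to-end comparison (`runPhantomDemo()`) rasterises a
0.06 × 0.006 m channel with a 0.019 m cavity at 0.4 mm spacing
(150 × 64 × 4 voxels, ostium 0.8 mm — the two-voxel minimum at this
spacing), drives it with the 4 s sine in 4000 steps of 1 ms, and uses a
peak inlet flow of 0.3 ml/s, giving a channel Reynolds number of about 12.
These are desk-scale conditions chosen once: patient-scale Reynolds
numbers (nasal speeds of 1–2.5 m/s) would demand far finer grids and time
steps, and the qualitative orderings under study do not require them.
Snapshots are stored every 50 steps for the measure pipeline; the scalar
series (flow, pressure drop, CFL, divergence) keep full 1 ms resolution.

Findings the package reproduces as properties: the net ostium flux is zero
to rounding (an exact consequence of incompressibility for a rigid sealed
cavity — air leaves one part of the opening exactly as fast as it enters
another, so exchange is measured on the half-gap flux); the constricted
phantom yields strictly larger enstrophy, vorticity-magnitude and
absolute-helicity measures and larger nasal resistance than the healthy
one. At this Reynolds number the exchange flow is quasi-steady: it
reverses once per cycle with the driving flow, and within-phase reversal
counts are equal (zero) for both phantoms — the within-phase pulsatility
reported for patients arises at Reynolds numbers that are not
desk-reproducible, so the property holds as an inequality, not strictly.

## What passing tests do and do not show

The synthetic fields exercise every code path with known answers, and the
phantom runs demonstrate the qualitative healthy-versus-pathological
orderings under laminar, desk-scale conditions. They do not emulate
turbulence, patient geometry, compliant walls or heat/humidity transport,
and no attempt is made to match patient-specific measure magnitudes —
units are SI and scales follow from the phantom conditions. Measures are
computed on the fields as given; whether a source's fields were resolved
or turbulence-model-averaged is outside this package's scope.

## Known limitations

- Stair-step wall representation: geometric boundaries are voxelised, so
  wall placement carries a half-voxel ambiguity (the ghost-reflection
  no-slip puts the effective wall at the face, which the Poiseuille test
  confirms to second order).
- First-order upwind advection is diffusive; acceptable at the demo's
  Re ≈ 12, not for inertial regimes.
- The explicit predictor's diffusive stability limit makes the solver
  impractical below ~0.2 mm spacing at air viscosity.
- `lambda2` on 2-D fields reduces to eigenvalues of a rank-2 tensor; its
  sign convention still follows the 3-D definition.
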
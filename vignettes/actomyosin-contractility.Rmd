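---
title: "Methods: cooperative and telescopic contraction of disordered actomyosin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cooperative and telescopic contraction of disordered actomyosin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(actoflow)
```

## The system and the measurement chain

`actoflow` analyses light-activated contraction of quasi-two-dimensional
disordered actomyosin networks: F-actin crowded onto a supported lipid
bilayer, decorated with myosin II thick filaments held inactive by
blebbistatin, and locally re-activated by 405 nm illumination of a circular
region of radius $\xi$. The primary observable is a PIV-derived velocity
field $\mathbf v(x, y, t)$ sampled on a regular grid every 10 s.

The analysis chain turns that field into the quantities that characterise
contraction:

1. **Divergence** $\nabla\cdot\mathbf v$ (second-order central differences,
   one-sided at grid edges) is the local areal strain rate.
2. **Radial decomposition** about the activation centre gives $v_r$
   (*inward-positive*, so contraction means $v_r > 0$ — note that most
   vector-calculus conventions are outward-positive) and the signed
   azimuthal component $v_t$. Within half a grid spacing of the centre the
   direction is singular and both are set to zero.
3. **Strain timecourse.** The displacement field is the cumulative
   trapezoidal time-integral of velocity; the contraction-positive strain is
   $\varepsilon(t) = -\langle \nabla\cdot\mathbf u \rangle_{r\le\xi}$.
   Because strain counts material flowing into the disc as well as radial
   and orthoradial compression, $\varepsilon$ can exceed 1. Whether one
   spatially averages before or after time integration is immaterial on a
   uniform grid with linear stencils (the operations commute); the package
   computes both and stores their maximum discrepancy as `commute_gap`, a
   numerical self-check that is ~machine precision on clean fields.
4. **Phases.** $\varepsilon(t)$ splits into a lag phase P1 ($t < t_1$,
   default 100 s), a linear phase P2 ($t_1 \le t \le t_2$, default 300 s)
   and a plateau P3. The strain rate is the OLS slope on P2; the maximum
   strain $\varepsilon_{\max}$ is the P3 mean. P1 is excluded from rates
   because early flow has a large tangential component; the per-frame
   tangential fraction $|v_t|/(|v_r|+|v_t|)$ is reported so the exclusion is
   auditable.
5. **Boundary velocity** is the mean inward $v_r$ over a 2.65 µm-wide
   annulus centred on the activation circumference.

### Stress inference without material properties

With two assumptions — overdamped dynamics with substrate friction
$\zeta$, and radially symmetric deformation — the in-plane force balance
reduces to $\partial_r \sigma = -\zeta\, v_r$ (inward-positive $v_r$),
under the closure $\sigma_{rr} \approx \sigma_{\theta\theta}$. That
isotropy closure is the minimal assumption that makes the inversion
well-posed from $v_r$ alone: the fully anisotropic problem is
under-determined, and any anisotropic correction would add geometric terms
that cannot be constrained without a constitutive law, which is precisely
what this estimate avoids. Hence

$$\sigma(r) = \zeta \int_r^{R_\mathrm{out}} v_r(r')\,dr',$$

integrated trapezoidally over the binned radial profile; $\sigma$ vanishes
at $R_\mathrm{out}$ by construction (default: the largest sampled radius,
because stress extends into the passive surroundings, not just the disc)
and, for inward flow, peaks at the centre and decays outward. `zeta = 1`
reports stress per unit friction. `applicability_check()` flags frames
whose tangential fraction exceeds 0.25, where the symmetry assumption is
not tenable (early frames, non-circular activation).

### Cooperativity

Maximum strain versus myosin thick-filament density $\rho$ is fitted with
the Hill equation
$\varepsilon_{\max}(\rho) = \varepsilon_\mathrm{sat}/(1 + (\rho_{1/2}/\rho)^{n})$
by bounded nonlinear least squares. Steep Hill fits are multi-modal in
$(\rho_{1/2}, n)$, so the optimiser starts from $n \in \{1, 2, 5, 10, 20\}$
and keeps the best residual; bounds are $n \in [0.5, 30]$,
$\varepsilon_\mathrm{sat} \in (0, 10]$, $\rho_{1/2}$ within the data range
±50%. Standard errors come from the Jacobian at the optimum; degenerate
data produce a flagged non-fit rather than a silent one. The critical
density $\rho_c$ is identified with $\rho_{1/2}$: at $n \approx 11$ the
transition is steep enough that the half-saturation point and any
reasonable "critical density" estimate coincide within the data
resolution. This is an interpretation, recorded here and revisitable.

## The active gel model

The continuum model treats the film as a homogeneous, isotropic
Kelvin–Voigt solid (elastic and viscous stresses in parallel — chosen
because measured strain rises and then *plateaus*, the signature of a
viscoelastic solid, not a fluid) with substrate friction and an isotropic
active stress confined to the activation disc and ramping in time:

$$\zeta\,\partial_t u = \partial_r \sigma_{rr} +
  \frac{\sigma_{rr}-\sigma_{\theta\theta}}{r},\qquad
  \sigma_{rr} = C\left(u' + \nu\frac{u}{r}\right)
  + \eta\,\partial_t\!\left(u' + \nu\frac{u}{r}\right) + \sigma_a(r,t),$$

with the analogous hoop stress, $C = E/(1-\nu^2)$ in plane stress (the
default for a thin film on a bilayer; plane strain is switchable and only
changes the modulus prefactor), and
$\sigma_a = \sigma_0\,(1 - e^{-t/\tau_a})$ for $r \le \xi$. The active
stress enters with positive sign as network tension; because it is
isotropic it cancels from the hoop-difference term, and its whole
mechanical effect is the gradient $\partial_r\sigma_a$ — an inward pull
concentrated at the activation boundary, which is why the flow localises
there.

**Numerics.** Crank–Nicolson in time (the viscous term makes every step
implicit), sparse banded direct solves, central differences in $r$ with
$u(0) = 0$ and a clamped ($u(R) = 0$) or stress-free outer edge. The active
forcing is discretised in conservative (flux) form with the activation step
sampled at half-nodes, which centres the interface exactly on $\xi$; the
residual interface error is first order and halves with each grid
refinement. The disc-averaged strain follows from the divergence theorem
as $\varepsilon(t) = -2u(\xi,t)/\xi$. A strain increment above 10% in one
step aborts with a diagnostic.

**Oracle.** The $t\to\infty$ equilibrium has the classical disc-inclusion
closed form $u = Ar$ inside, $u = Br + C_c/r$ outside, with constants
fixed by continuity of $u$ and $\sigma_{rr}$ at $\xi$ plus the outer
boundary condition (for the clamped edge
$B = \sigma_0\xi^2/2CR^2$, $C_c = -BR^2$, $A = B(1 - R^2/\xi^2)$). The
in-disc areal strain $2A$ is spatially uniform and the hoop stress jumps
by $(1-\nu)\sigma_0$ at the interface (equal to $\sigma_0$ only at
$\nu = 0$). `gel_steady_state()` is implemented directly from this
derivation and serves as the solver's analytic oracle in the tests.

**Defaults** (dimensionless; the stress scale is $\sigma_0 = 1$):
$E/\sigma_0 = 1$ — the regime where active and elastic stresses are
comparable, which is where model and experiment agree; $\nu = 0.3$;
$\eta = 10$ Pa·s so the short-time viscous scale $\eta/C \approx 9$ s;
$\zeta = 0.03$ Pa·s·µm⁻², putting the stress-diffusion time
$\zeta R^2/C$ at a few hundred seconds so strain plateaus within the P3
window, as observed; $\tau_a = 60$ s, the time by which flow becomes
pronounced and radial; $\xi = 10$ µm with $R = 10\xi$; $N = 800$ grid
intervals, $T = 600$ s at $\Delta t = 0.5$ s. These were fixed from the
above physical reasoning, once, before any sweep was run.

**Telescopic behaviour.** Holding $R/\xi$ and all times fixed, the steady
displacement scales as $u(\xi) \propto \xi$ while the governing timescales
($\tau_a$, $\eta/C$) stay fixed, so the peak boundary velocity grows
nearly linearly with $\xi$; stiffening the gel (larger $E/\sigma_0$)
shrinks $u$ and hence the slope. The disc-averaged $\varepsilon_{\max}$
depends on $\xi$ only through $\zeta\xi^2/C$-type relaxation corrections
and decreases nominally. Two strain-rate summaries are reported: the
P2-window OLS slope (the experimental convention) and the maximum
instantaneous rate; the latter is the one that stays essentially constant
with a nominal decrease across activation sizes, while the P2-window slope
is sensitive to where the fixed window falls relative to each size's
relaxation, and can trend upward for small discs that finish contracting
before the window opens.

## The agent-based model

A reduced-scale Brownian-dynamics simulator probes the molecular origin of
the same behaviours. F-actin is a bead–spring chain (280 nm segments, 7 nm
binding-site lattice, fixed polarity) with worm-like-chain bending of
stiffness $\kappa = l_p k_BT$; myosin thick filaments are 4-node backbones
(three 42 nm segments, stiff springs, hinge bending) with two motor arms
per node. Arms bind sites within a 20 nm capture radius at
$k_\mathrm{on} = 40\,\mathrm{s^{-1}}$, take stochastic 7 nm steps toward
the barbed end with a linear force–velocity relation
($v_0 = 140$ nm/s, $F_\mathrm{stall} = 4$ pN), and unbind with
load-dependent catch-like kinetics
$k_\mathrm{off} = k_0 e^{-F/F_0}$ ($k_0 = 0.35\,\mathrm{s^{-1}}$,
$F_0 = 4$ pN) when the motor centre lies inside the activation disc, or at
a constant $20\,\mathrm{s^{-1}}$ outside it — the non-processive,
blebbistatin-inhibited state. These kinetic constants are standard
non-muscle myosin II modelling values, stated as such wherever they
appear. There are no passive crosslinkers: all connectivity is via motors.

Design choices that matter:

* **Motors start on the network.** Myosin dimers polymerise into thick
  filaments on F-actin, so motor centres are placed uniformly along the
  actin contour. With thermal noise off (the default — motor forces
  dominate at this friction), an off-network motor could never diffuse to
  a binding site.
* **Density.** The default 800 filaments in the 20 µm box give a contour
  density of ~14 µm/µm² (mesh ≈ 0.25 µm), a realistic crowded-cortex
  density. This matters mechanistically: contraction requires motors to
  *bridge* filament pairs and percolate force across the disc, and at
  several-fold sparser networks the activation disc contains too few
  bridges and strain is negligible — the simulation analogue of the
  sub-critical regime.
* **Reduced scale.** 20 µm box, 3–9 µm activation radii, 100 s simulated
  at $\Delta t = 1$ ms with extensional stiffness softened to
  1.5 pN/nm (stability requires $k\,\Delta t/\gamma < 1/2$ at the bead
  drag $\gamma = 0.01$ pN·s/nm). Beads within a 1 µm rim of the box edge
  are anchored, mimicking the quiescent surrounding network. Consequently
  radius sweeps that approach the rim are run in a 30 µm box at matched
  density.
* **Binding cadence.** Binding searches run at the neighbour-list rebuild
  interval (10 steps) with the on-rate integrated over that interval;
  displacements per interval are far below the capture radius, so the
  binding statistics are unchanged.
* **Omissions.** Excluded volume between filaments (dominant couplings are
  the motor crosslinks in a quasi-2D film), actin turnover, hydrodynamics,
  and 3D effects are all out of scope.

ABM output re-enters the experimental pipeline through `measure_strain()`:
bead displacements since $t=0$ are binned onto a 1 µm grid (cell means,
median-infilled gaps) and processed with exactly the divergence/region-mean
conventions used for PIV data. For runs shorter than the experimental
300 s the phase boundaries scale to the same fractions (25% / 75%) of the
simulated span.

## Synthetic data

`gen_piv_series()` emulates what PIV hands the pipeline: a scenario field
(analytic sink, rigid rotation, their sum, or a rasterised gel solution)
sampled at 10 s intervals, plus i.i.d. Gaussian component noise (default
sd 0.002 µm/s, the scale of ~0.02 µm sub-pixel displacement error over a
10 s interval) and a 5% vector drop rate so the gap-infilling path is
exercised by default. `gen_hill_dataset()` draws densities uniformly on
[0.2, 1.2] µm⁻² — bracketing the critical density 0.56 µm⁻² and the
experimental low/medium/high conditions — and applies *multiplicative*
lognormal noise, because strain spans an order of magnitude across the
transition and additive noise would distort the sub-critical branch. The
generating curve uses the experimentally fitted $\rho_{1/2} = 0.56$ µm⁻²
and $n = 11$ with $\varepsilon_\mathrm{sat} = 1.4$, a generator choice
consistent with $\varepsilon_{\max} > 1$ above the transition (the
saturation strain itself is not an experimentally printed value).
Filament lengths are truncated-exponential on [0.56, 25] µm with the rate
solved so the *truncated* mean is 7.1 µm; orientations are uniform, and
`nematic_order()` of such a set sits at the $1/\sqrt n$ null.

What passing these tests does **not** show about real data: the generators
contain no spatially correlated PIV error, no optical-flow bias near
aggregates, no photobleaching drift, and no post-contraction coalescence
(the pipeline deliberately stops at the plateau). Conclusions about those
regimes need real fields.

## Problem sizes and tolerances used by the test-suite

Unit and property tests run in seconds on analytic fields (machine
precision where stencils are exact for the polynomial degree, stated
statistical bounds otherwise). The heavier scientific checks use: the gel
oracle at $N = 800$ (relative $L_2$ error < 1% against the closed form,
halving under refinement) with the convergence invariant probed at
$N = 3200 \to 6400$; telescopic sweeps over $\xi \in \{5,10,20,40\}$ µm at
$E/\sigma_0 \in \{1, 2\}$; and reduced-scale ABM comparisons (100 s,
seed-pinned) for the density, stiffness and activation-size orderings.
These sizes are the package's standard verification set; all are
reproducible from `tests/testthat/` as-is.

## Known limitations

* The stress inversion reports a friction-normalised, isotropically closed
  estimate; shear components and anisotropy are invisible to it.
* The gel model is linear: it cannot capture density-dependent moduli
  (left as an extension hook) or the post-plateau aggregation regime.
* The ABM is reduced-scale: orderings and mechanisms are meaningful,
  absolute strain magnitudes at 100 s are smaller than experimental
  plateau values reached over 400+ s.
* `fit_hill()` bounds $n \le 30$; data steeper than that pin the bound and
  are flagged through the standard-error check rather than extrapolated.
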
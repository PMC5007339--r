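# actoflow

Contraction analysis and forward modelling of disordered actomyosin
networks.

In reconstituted cell-cortex mimics, F-actin crowded onto a lipid bilayer
and decorated with blebbistatin-inhibited myosin II can be switched on
locally with 405 nm light: myosin activity inside a circular region of
radius ξ drives the disordered network to contract. `actoflow` implements
the full computational chain for quantifying that contraction from
PIV-style velocity fields, together with the two forward models used to
explain it:

* **Field analysis** — divergence, inward-positive radial / tangential
  decomposition about the activation centre, radial profiles, boundary
  velocity (2.65 µm annulus).
* **Contraction metrics** — contraction-positive strain
  ε(t) = −⟨∇·u⟩ from the time-integrated velocity field, P1/P2/P3 phase
  segmentation (lag 0–100 s, linear 100–300 s, plateau >300 s), P2 strain
  rate dε/dt, plateau strain ε_max.
* **Stress inference** — friction-based force balance
  σ(r) = ζ ∫ᵣ^R v_r dr′, the stress pattern of a contracting disc without
  assuming any material properties.
* **Cooperativity** — bounded multi-start Hill fits of ε_max vs myosin
  thick-filament density ρ:
  ε_max(ρ) = ε_sat / (1 + (ρ_half/ρ)^n), with the critical density ρ_c
  identified with ρ_half and the Hill coefficient n quantifying how
  switch-like the contraction transition is.
* **Active gel model** — radially symmetric overdamped Kelvin–Voigt solid
  with substrate friction ζ and a ramped isotropic active stress
  σ_a = σ₀(1 − e^(−t/τ_a)) inside the disc; Crank–Nicolson solver with a
  closed-form disc-inclusion steady state as its analytic oracle.
* **Agent-based model** — reduced-scale Brownian dynamics of semiflexible
  bead-spring filaments connected only by bipolar motor thick filaments
  with load-dependent (catch-like) kinetics gated by the activation disc
  (Rcpp core).
* **Synthetic data** — seeded generators for PIV-like field series (with
  Gaussian noise and dropped-vector gaps), Hill datasets, and disordered
  filament sets, so every stage is testable without microscopy data.

All user-facing functions take data frames / tibbles and return tibbles;
fitted objects support `tidy()` / `glance()`; every result type has an
`autoplot()` method.

## Worked example

Simulate the gel model at its default operating point (E/σ₀ = 1,
ξ = 10 µm), rasterise it into a noisy PIV-like field series, and push that
through the measurement chain:

```r
library(actoflow)

sol   <- solve_gel(gel_params())
field <- gen_piv_series("gel", sol = sol, seed = 1)
reg   <- attr(field, "region")

tc <- strain_timecourse(field, reg)
glance(tc)
#> # A tibble: 1 × 6
#>   strain_rate eps_max n_frames    t1    t2 commute_gap
#>         <dbl>   <dbl>    <int> <dbl> <dbl>       <dbl>
#> 1    0.000857   0.850       61   100   300    1.11e-16
```

The strain curve rises through the linear phase at
dε/dt ≈ 8.6 × 10⁻⁴ s⁻¹ and plateaus at ε_max ≈ 0.85: the noisy pipeline
recovers the solver's own plateau strain (0.905) to ~6%. The inferred
stress profile peaks at the centre of the activation region and decays
outward to zero at the edge of the sampled field:

```r
vr   <- decompose_radial(field, reg)$v_r
prof <- radial_profile(vr[vr$time == 150, ] |> scalar_field_series(), reg, 1)
radial_stress(prof)        # sigma(r), zeta-normalised units
```

Fit the cooperativity of maximum strain against myosin density on a
synthetic dataset generated from the experimentally fitted curve
(ρ_half = 0.56 µm⁻², n = 11) with 5% noise:

```r
fit <- fit_hill(gen_hill_dataset(50, seed = 1))
glance(fit)[, c("eps_sat", "rho_half", "n_hill", "converged")]
#> # A tibble: 1 × 4
#>   eps_sat rho_half n_hill converged
#>     <dbl>    <dbl>  <dbl> <lgl>
#> 1    1.41    0.559   11.0 TRUE
```

A 50-point, 5%-noise dataset pins the Hill coefficient to ≈ 11 — the
extremely steep, switch-like dependence of contraction on myosin density —
and the half-saturation (critical) density to ≈ 0.56 µm⁻².

Telescopic behaviour of the gel model (`sweep_activation()`): the peak
boundary velocity grows near-linearly with the activation radius while
ε_max stays essentially constant, and stiffening the network (E/σ₀ = 2)
halves the slope:

```r
sweep_activation(gel_params(), xi = c(5, 10, 20, 40), stiffness = c(1, 2))
```

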
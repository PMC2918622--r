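# aneumt — convection-scheme choice in aneurysm mass transport

`aneumt` is a desk-scale finite-volume toolkit for blood-side mass
transport in an idealised axisymmetric aneurysm.  It exists to make one
methodological point reproducible: **the convection-diffusion
discretisation scheme controls the computed species concentration field in
convection-dominated vascular transport.**  At the study conditions
(Re = 800, Sc = 3200, Pe = Re·Sc = 2,560,000) first-order upwinding and
the power-law scheme — which collapses onto upwinding at high face Peclet
number — smear concentration gradients by numerical (false) diffusion and
grossly over-predict how fast the aneurysmal sac fills with tracer, while
the second-order upwind and QUICK schemes preserve the sharp gradients
perpendicular to the flow.

The package is aimed at people building or validating mass-transport CFD
pipelines who want a small, fully scripted, dependency-light testbed for
scheme behaviour rather than a production solver.

## What is inside

For the finite-volume transport equation

    d(ρφ)/dt·V + Σ_f (ρ v·A)_f φ_f = Σ_f Γ (∇φ·A)_f + S·V

the package implements the four classical face interpolations of the
convective `φ_f`:

| scheme | face value |
|---|---|
| first-order upwind | `φ_P` (upstream cell) |
| power law | exact 1-D profile `(e^{Pe·s}−1)/(e^{Pe}−1)` between cell centres |
| second-order upwind | `φ_P + ∇φ·Δs` (Green–Gauss upwind gradient) |
| QUICK (blend ψ, default 3/4) | `ψ[S_d φ_P + S_c φ_E]/(S_c+S_d) + (1−ψ)[(S_u+2S_c)φ_P − S_c φ_W]/(S_u+S_c)` |

around them: a body-fitted structured axisymmetric mesh generator with
quality metrics (equiangle skew, aspect ratio), a SIMPLE-type collocated
steady flow solver (QUICK momentum, Rhie–Chow face fluxes, conservative to
machine precision after a final projection), an implicit-Euler transient
species solver with deferred-correction high-order schemes, a hemispherical
probe (0.8 ml, 5 equal-height slabs, volume-weighted centroid sampling)
emulating the fluid-extraction measurement, synthetic reference generators
(exact 1-D benchmark, 45° oblique-step false-diffusion fixture, seeded
pseudo-experimental sac-fill series), and comparison metrics.

## Worked example

```r
library(aneumt)

dimensionless_numbers(aneurysm_geometry(), fluid_properties(),
                      flow_bcs(reynolds = 800), diffusivity = 3.125e-10)
#> $Re 800      $Sc 3200      $Pe 2560000
#> $mean_velocity 0.0319 m/s  $flow_rate 1.58e-05 m^3/s

mesh_quality(generate_mesh(aneurysm_geometry(), 240, 60))
#> Mesh quality: 14400 cells, max equiangle skew 0.3070, max aspect ratio 4.500

scheme_order_study()$orders          # 1-D convergence vs the exact profile
#>       fou power_law       sou     quick
#>      0.92      2.08      2.10      2.09

# false diffusion: 0.1-0.9 transition width of the 45-degree oblique step
fx <- generate_oblique_step(45, 64)
sapply(c(fou = "fou", sou = "sou", quick = "quick"),
       function(s) transition_width(solve_oblique_step(fx, s)))
#>    fou    sou  quick
#> 0.3190 0.0830 0.0727
```

The full pipeline (one flow solve, four transient species runs at matched
settings, probe extraction, comparison) on a scaled-down grid:

```r
cfg <- default_config()
cfg$mesh <- list(ni = 72, nj = 20, wall_stretch = 1)
run_pipeline(cfg)
#> Scheme comparison report
#>   grid: 1440 cells, Re = 800, Sc = 100
#>   probe series (normalised concentration):
#>             t=0s t=120s t=240s t=360s
#> fou       0.5052 0.9896 0.9997 1.0000
#> power_law 0.5031 0.9893 0.9997 1.0000
#> sou       0.1717 0.6524 0.8186 0.9042
#> quick     0.1636 0.6242 0.7746 0.8603
#>   reference series (pseudo_experiment): 0, 0.3971, 0.6154, 0.8088
#>   pairwise percentage differences:
#>             fou power_law   sou quick
#> fou        0.00      0.11 42.39 46.96
#> power_law  0.11      0.00 42.31 46.87
#> sou       42.39     42.31  0.00  4.94
#> quick     46.96     46.87  4.94  0.00
#>   average percentage difference vs reference:
#>       fou power_law       sou     quick
#>     78.42     78.40     36.37     29.80
```

Reading the numbers: the two first-order-family schemes agree with each
other to 0.11% and the two higher-order schemes to 4.9%, while the two
families differ by 40–47% — and against the monotone fill-in reference the
first-order schemes over-predict the sac concentration at every sampled
time.  That is the paper-scale phenomenon reproduced at desk scale:
**use second-order upwind or QUICK for convection-dominated mass
transport.**

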
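# chemokin

Keller–Segel dynamics of bacterial populations that combine **chemotaxis**
(tumble-rate bias up attractant gradients) with **chemokinesis**
(concentration-dependent swimming speed).

Many soil and marine bacteria swim faster at higher attractant
concentration. For a run-and-tumble swimmer this has three coupled
consequences: the population diffusivity scales as the squared speed
(D ∝ v²), the chemotactic sensitivity scales the same way (χ ∝ v²), and a
*spatially varying* speed drives a drift −(v/α)∂v/∂x towards regions of
**low** speed — i.e. down the attractant gradient, against the chemotactic
drift. `chemokin` implements the dimensionless continuum model coupling a
bacterial density B(X, T) to an attractant field C(X, T):

    ∂C/∂T = N ∇²C − H B C/(C + K_S)
    ∂B/∂T = −∇·J + B C/(C + K_S) (1 − B)
        J = −V(C)² ∇B + (V_k + V_χ) B
      V_k = −V(C) · (dV/dC) · ∇C
      V_χ = V(C)² δ₀ K_χ/(C + K_χ)² · (∇C + ζ/V(C) · ∂C/∂T)

with the Hill-type speed response `V(C) = 1 + η Cⁿ/(Cⁿ + ωⁿ)`. The ζ-term
corrects the chemotactic drift for the concentration change a swimming
cell perceives when the field itself varies in time; its impact shrinks at
higher swimming speed.

The package is aimed at quantitative microbiologists and biophysicists who
want to explore when chemokinesis helps or hinders a chemotactic
population. It provides:

* the pointwise model terms (`hill_speed()`, `chemokinetic_drift()`,
  `chemotactic_drift()`, `monod()`, `assemble_flux()`) and the
  dimensional ↔ dimensionless mapping (`nondimensionalize()`);
* closed-form analysis: the threshold Hill exponent above which the
  chemokinetic drift dominates at C = ω
  (`hill_threshold()`, `dominance_condition()`), and the zero-flux steady
  state `B/B* = (V*/V) exp{δ₀[C/(C+K_χ) − C*/(C*+K_χ)]}`
  (`steady_state_ratio()`);
* a conservative finite-volume solver (cell-centered, minmod-limited
  upwind advection, Heun time stepping under a CFL bound, compiled core)
  for 1D Cartesian and 2D axisymmetric geometry (`advance()`);
* three benchmark scenarios — fixed linear gradient
  (`make_linear_gradient()`), self-generated gradient on an agar plate
  (`make_agar_plate()`), transient attractant pulse
  (`make_transient_source()`) — plus observables (`peak_density()`,
  `total_population()`, `front_position()`), a plain-text config format
  and a command-line entry point (`run_cli()`, `inst/cli/chemokin`).

## Worked example

When does the speed response become steep enough that the chemokinetic
drift beats chemotaxis at the half-saturation concentration?

```r
library(chemokin)
p <- model_params(eta = 2, omega = 0.2, n_hill = 5, delta0 = 50, K_chi = 0.53)
hill_threshold(p)
#> [1] 39.78232
hill_speed(c(0, 0.2, 1), p)
#> [1] 1.00000 2.00000 2.99936
```

With these parameters the swimming speed triples across the attractant
range (half-maximal exactly at C = ω = 0.2), but the drift competition
only tips in favour of chemokinesis for Hill exponents above ≈ 39.8 — the
default n = 5 population still accumulates at high attractant.

Around a transient nutrient pulse, chemokinesis buys a faster and stronger
peak accumulation while the attractant is plentiful:

```r
sc  <- make_transient_source(n_cells = 200, T_snapshots = c(0.02, 0.05, 0.1))
run <- run_scenario(sc, variants = c("base", "pure_chemotaxis"))
subset(run$series, time > 0.01, select = c(variant, time, B_S, total_population))
#>           variant time      B_S total_population
#> 2            base 0.02 6.741168         62.83185
#> 3            base 0.05 8.771056         62.83185
#> 4            base 0.10 5.718438         62.83185
#> 6 pure_chemotaxis 0.02 5.817433         62.83185
#> 7 pure_chemotaxis 0.05 8.537458         62.83185
#> 8 pure_chemotaxis 0.10 5.946265         62.83185
```

`B_S` is the peak of the radial density profile (the accumulation at the
source): the chemokinetic population (`base`, η = 2) peaks higher than the
purely chemotactic one early on (6.74 vs 5.82 at T = 0.02, i.e. ~16% at
this reduced resolution), and disperses faster once the pulse has decayed
(T = 0.1). `total_population` stays at 0.2·π·10² = 62.83: with growth off
the solver conserves cells to round-off.

The same scenarios can be driven from a shell through the thin Rscript
wrapper shipped in `inst/cli/chemokin` (after installation, at
`system.file("cli", "chemokin", package = "chemokin")`; symlink it onto
your PATH to taste):

```sh
chemokin run transient.cfg --out results/
chemokin analyze threshold transient.cfg
```

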
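---
title: "Modelling chemotaxis with chemokinesis: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling chemotaxis with chemokinesis: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemokin)
```

## The model

`chemokin` simulates the spatio-temporal dynamics of a run-and-tumble
bacterial population whose swimming is modulated by a chemoeffector field
in two distinct ways. In *chemotaxis* the cell biases its tumbling rate,
lengthening runs up the gradient while the speed stays constant. In
*chemokinesis* the cell modulates its swimming speed with the local
concentration, typically swimming faster where attractant is abundant.
Coarse-graining the run-and-tumble walk gives a drift–diffusion (extended
Keller–Segel) description in which a concentration-dependent speed enters
three times:

* the population diffusivity is $D = \mathcal{V}(C)^2$ (in units of the
  base diffusivity $D_b^0 = v_0^2/\alpha$);
* the chemotactic sensitivity also scales as $\mathcal{V}^2$, because
  longer, faster runs sample the gradient more effectively;
* a spatially varying speed by itself produces a drift
  $\mathsf{V}_k = -\mathcal{V}\,\mathcal{V}'(C)\,\nabla C$ towards
  regions of *low* speed — for a positive speed response this opposes
  the chemotactic drift.

In dimensionless form (time in units of the inverse maximal growth rate,
length in units of the run-diffusion length, densities relative to their
initial scales) the coupled equations are

$$\partial_T C = N \nabla^2 C - H B \frac{C}{C+K_S}, \qquad
  \partial_T B = -\nabla \cdot J + B \frac{C}{C+K_S}(1-B),$$

$$J = -\mathcal{V}^2 \nabla B + (\mathsf{V}_k + \mathsf{V}_\chi) B,
\qquad
  \mathsf{V}_\chi = \mathcal{V}^2
  \frac{\delta_0 K_\chi}{(C+K_\chi)^2}
  \left(\nabla C + \frac{\zeta}{\mathcal{V}} \,\partial_T C\right),$$

with the Hill-type speed response
$\mathcal{V}(C) = 1 + \eta\, C^n/(C^n + \omega^n)$. The model is solved
in 1D Cartesian or 2D axisymmetric (radial) geometry with zero-flux
boundaries.

### Assumptions

* **Instantaneous speed adaptation.** The speed is a pure function of the
  local concentration; no relaxation timescale is modelled. Measured
  adaptation times for real species range from seconds to minutes, so
  this is an idealization appropriate for dynamics slow compared to the
  adaptation kinetics.
* **Hill-shaped response.** The functional form of speed versus
  concentration has not been measured systematically for any species; a
  Hill curve is the simplest family that interpolates between a
  Michaelis–Menten response ($n = 1$) and a step response
  ($n \to \infty$), with half-maximal increase exactly at $C = \omega$
  for every $n$. (In dimensional terms: $v = v_0 + v_c/2$ at $c = k_c$ —
  the half-saturation is in *speed*, not concentration units.)
* **Temporal-gradient correction.** In a time-varying field, a swimming
  cell perceives $\mathrm{d}C/\mathrm{d}t$ along its run, not the static
  spatial gradient; the $\zeta$-term accounts for this. Its weight is
  inversely proportional to the swimming speed, which is precisely the
  channel through which chemokinesis mitigates the bias.
* **Negative chemokinesis** ($-1 < \eta < 0$, slower at high attractant)
  is allowed; the speed then stays positive and the chemokinetic drift
  reinforces chemotaxis.
* **Growth vs consumption.** The logistic growth term in the B-equation
  is switched by `growth_on`; attractant consumption is governed by $H$
  alone. This decoupling lets a population consume a pulse without
  growing on it — the transient-source benchmark explicitly combines
  $H = 3.5$ with growth off, consistent with a chemoeffector that is
  taken up on timescales short compared to division.

### Parameters

| Parameter | Meaning | Typical benchmark values |
|---|---|---|
| `N` | attractant/bacterial diffusivity ratio | 0–0.5 |
| `H` | consumption strength $b_0/(Y c_0)$ | 0 or 3.5 |
| `K_S` | Monod half-saturation of growth/consumption | 1 |
| `eta` | maximal relative speed increase | 0.5–2 |
| `omega` | speed half-saturation concentration | 0.2–0.5 |
| `n_hill` | steepness of the speed response | 1–40 |
| `delta0` | chemotactic sensitivity $\chi_0/D_b^0$ | 50–105 |
| `K_chi` | receptor half-saturation | 0.53 |
| `zeta` | temporal-correction weight $v_0/(\alpha x_0)$ | 0 or $8.164\times10^{-3}$ |

All are dimensionless; `nondimensionalize()` maps a dimensional swimming
and kinetic parameter set (speeds, tumble rate, growth rate, yields,
diffusivities) onto them and reports the characteristic scales.

## Closed-form results

Two analytic results are implemented independently of the solver and
double as solver oracles.

**Drift competition.** For a stationary linear attractant profile the two
drifts share the factor $\mathcal{V}^2 \nabla C$, so their relative size
reduces to a pointwise comparison (`dominance_condition()`), and
evaluating it where the speed gradient is steepest ($C = \omega$) gives a
closed-form threshold on the Hill exponent (`hill_threshold()`):

$$n^* \;=\; \frac{4\,\delta_0\,\omega K_\chi}{(\omega+K_\chi)^2}
  \left(\frac{1}{\eta} + \frac{1}{2}\right).$$

```{r}
hill_threshold(model_params(eta = 2, omega = 0.2, n_hill = 5,
                            delta0 = 50, K_chi = 0.53))
```

For $\eta \le 0$ the drifts never compete and `hill_threshold()` returns
the sentinel string `"never"` — a deliberate design choice over `Inf` so
that parameter scans can distinguish "no finite threshold exists" from a
merely large value; the closed form is only derived for $\eta > 0$.

**Zero-flux steady state.** With a static attractant and zero-flux
boundaries, $J = 0$ integrates to
$B/B^* = (\mathcal{V}^*/\mathcal{V})
\exp\{\delta_0[C/(C+K_\chi) - C^*/(C^*+K_\chi)]\}$
(`steady_state_ratio()`): the chemotactic exponential is speed-independent
(the $\mathcal{V}^2$ enhancements of sensitivity and diffusivity cancel at
steady state), and chemokinesis survives only through the
$\mathcal{V}^*/\mathcal{V}$ prefactor — accumulation at low speed. The
test suite verifies this expression against direct numerical integration
of the first-order flux-balance ODE (written with the
$\tfrac{1}{2D}\,\partial_X D$ factor exactly as it appears in the balance,
integrated with `deSolve` at tolerance $10^{-10}$) and against the PDE
solver's long-time limit.

## Numerical scheme

The published text of the source model does not fix a discretization, so
the engine's scheme was chosen for discrete conservation and positivity:

* **Finite volumes** on a uniform cell-centered grid; all transport is
  assembled as face fluxes, and both boundary faces carry exactly zero
  *total* flux $J$ (not merely zero gradient). The axisymmetric operator
  is implemented in flux form $(1/R)\,\partial_R(R\,\cdot)$ with the
  $R = 0$ face carrying zero area, so the coordinate singularity never
  appears. Total content $\sum_i B_i w_i$ is conserved to round-off
  whenever growth is off.
* **Face coefficients.** The diffusivity at a face is the arithmetic mean
  of the adjacent cell values of $\mathcal{V}^2$; drift speeds are
  evaluated at the face from the mean concentration.
* **Limited upwinding.** The advected density at a face is reconstructed
  from the upwind cell with a minmod-limited slope. Plain first-order
  upwinding was tried first but its numerical diffusion left a ~1%
  L1 error against the steady-state oracle at 400 cells; the limited
  second-order reconstruction brings this to ~0.03% while remaining
  monotone (face values never leave the range of the adjacent cells), so
  positivity is preserved under the step-size bound.
* **Time stepping.** Explicit Heun (two-stage Runge–Kutta) with an
  adaptive step obeying
  $\Delta t \le s\,\min\{\Delta^2/(2\max\mathcal{V}^2),\;
  \Delta^2/(2N),\; \Delta/\max|\mathsf{V}_k + \mathsf{V}_\chi|\}$,
  safety factor $s = 0.4$, recomputed every step; the step is shortened
  to land exactly on output times, and a collapse below `dt_min` aborts
  with a diagnostic. Any negative values produced by round-off are
  clipped to zero with the clipped mass accounted; a run whose cumulative
  clipped mass exceeds $10^{-6}$ of the total fails validation (in
  practice the benchmark runs clip nothing).
* **Temporal derivative for the $\zeta$-term.** The $\partial_T C$ fed
  into $\mathsf{V}_\chi$ is the just-computed right-hand side of the
  attractant equation, not a finite difference of stored time levels:
  this is exact for a frozen field (zero) and avoids order-coupling
  between the two equations.
* **Frozen-field caching.** When the attractant is static the face
  diffusivities and drifts are computed once and reused, which makes the
  long steady-state runs roughly 25 times faster without changing a
  single arithmetic operation in the update.
* **Verification.** The compiled core is mirrored by a plain-R reference
  implementation (`pde_rhs()`, `divergence_of_flux()`, `fv_laplacian()`);
  an equivalence test keeps the two within $10^{-12}$ on random fields.
  Grid-refinement against the steady-state oracle shows error ratios of
  ≈ 4.4–4.6 per halving of $\Delta$, i.e. second-order convergence.

## Benchmark scenarios

Three scenario constructors reproduce the benchmark set-ups; their
parameter defaults are stored as data, and the geometric choices below
are the package's own (the source text does not specify them).

**Fixed linear gradient** (`make_linear_gradient()`): 1D Cartesian domain
$[0, 10]$, static linear attractant from 0 to 1 (so the profile spans the
whole speed response and the $C = \omega$ point lies strictly inside),
400 cells, no consumption or growth. The initial population is a Gaussian
bump (σ = 0.2, centred at $X = 1$ on the low-attractant side) normalized
to a domain mean of 0.2; the bump shape is config-exposed because the
conclusions are qualitative in it. Variants: pure chemotaxis
($\eta = 0$) and the Hill sweep $n \in \{1, 10, 40\}$.

**Self-generated gradient** (`make_agar_plate()`): axisymmetric domain,
uniform attractant $C = 1$, narrow inoculum at the origin (peak 1,
σ = 0.6), growth and consumption on, $\zeta = 0$ (the self-generated
profile is stationary in the wave frame). The default radius is 60 with
900 cells: the travelling wave reaches $R \approx 54$ by the last
snapshot ($T = 16.4$), and doubling the domain changes the late-time
front position by far less than 0.5%, so boundary effects are
negligible. Variants: purely chemotactic populations at constant speed 1
and $1 + \eta$. In `constant_speed` mode the speed field is uniformly
$s$, the diffusivity $s^2$, the chemotactic prefactor $\delta_0 s^2$, and
the chemokinetic drift identically zero.

**Transient source** (`make_transient_source()`): axisymmetric domain
$[0, 10]$, 400 cells, bacteria uniform at 0.2, attractant initialized at
$T_0 = 0.01$ from the spreading 2D kernel
$C(R,T) = S(4\pi N T)^{-1} e^{-R^2/4NT}$ with $S = 0.5$. By default the
field is then *evolved* with diffusion and consumption ($H = 3.5$, growth
off); a `prescribed` mode imposes the analytic kernel at all times
instead, for studies without consumption feedback. Whether the original
benchmark evolved or prescribed the field is not documented; both give
the same qualitative conclusions here (the maximal chemokinetic
enhancement of peak accumulation is 11.9% evolved vs 13.0% prescribed),
and evolved is the default because it closes the mass budget.

### Observables and reported properties

`peak_density()` returns the maximum of the density profile ($B_S$, the
accumulation at a source) with inward tie-breaking; `total_population()`
integrates the density with exact piecewise-constant weights;
`front_position()` finds the outermost crossing of a fraction of the
maximum (default 0.1) with linear interpolation, and reports the distance
to the innermost crossing as a wave width. The 10% level is a
convention — no quantitative front definition exists for these systems —
and it is config-exposed. For the agar travelling waves the density
behind the front settles on a plateau above 10% of the peak, so band
*widths* are compared at 75% of the peak, a level that lies inside the
band for all three populations.

The acceptance suite checks, at the benchmark parameters: the steady
linear-gradient profile against the closed form (L1 < 1% at 400 cells,
and the $1/\mathcal{V}$ profile for $\delta_0 = 0$); conservation to
$10^{-8}$ and positivity; the diffusion-only solution against the heat
kernel ($L_\infty < 10^{-3}$); the front-speed ordering (constant
$1+\eta$ > chemokinetic > constant 1), the chemokinetic band broadening
and the population-size ordering in the agar scenario; and the transient
enhancement and mitigation properties below.

### The temporal-gradient correction: sign and mitigation

Around a decaying pulse the $\zeta$-correction has two opposing local
effects: ahead of the spreading pulse $\partial_T C > 0$ and the inward
drift is *reduced*, while near the centre $\nabla C \to 0$ and
$\partial_T C < 0$, so the correction adds a small *inward* drift right
at the source. In the benchmark runs the net effect on the peak
accumulation $B_S$ is positive — the $\zeta > 0$ runs accumulate slightly
more at the source than their $\zeta = 0$ twins, for both the
chemokinetic and the purely chemotactic pair. (Published descriptions of
this set-up state both directions in different places; the package
reports what the model equations produce.) What is unambiguous, and what
the tests assert, is the *mitigation* property: because the correction is
weighted by $1/\mathcal{V}$, the gap $|B_S^{\zeta>0} - B_S^{\zeta=0}|$ is
smaller for the chemokinetic population than for the purely chemotactic
one at every output time (less than half its maximum), i.e. faster
swimmers are less biased by the transience of the field. The maximal
relative excess of chemokinetic over purely chemotactic accumulation is
11.9%, reached early in the high-attractant phase; past $T \approx 0.05$
the faster-diffusing chemokinetic population disperses sooner and the
ordering reverses.

## Problem sizes and costs

The defaults used throughout the tests are 400 cells (linear gradient and
transient source) and 900 cells (agar plate), chosen so that halving the
resolution changes no reported digit of the qualitative observables and
the steady-state L1 criterion holds with a factor-30 margin. A full
steady-state relaxation (to $T = 30$) takes a few seconds with the
frozen-field cache; the four transient-source variants and the three agar
variants take a few seconds each on one core.

## Limitations

* Speed adaptation is instantaneous; finite adaptation kinetics (measured
  at 10–200 s in different species) are not modelled.
* The chemotactic response constant is treated through $\delta_0$ only;
  effects of speed on the *precision* of chemosensing are out of scope.
* Geometry is 1D Cartesian or axisymmetric; no full 2D/3D, multiple
  sources, or stochastic nutrient landscapes.
* The synthetic scenarios emulate idealized assays (perfectly linear
  static gradients, a single clean pulse, uniform agar); real assays add
  boundary geometry, flow, and finite observation noise, so passing these
  benchmarks shows the model and solver are implemented faithfully — not
  that any particular species follows the Hill response.
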
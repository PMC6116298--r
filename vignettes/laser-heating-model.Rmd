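---
title: "Modelling laser heating of a carbon nanotube in tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling laser heating of a carbon nanotube in tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cntheat)
```

## The physical problem

A carbon nanotube (CNT) injected into tissue and irradiated by a
continuous (or time-averaged) laser acts as a localized heat source: it
absorbs light far more strongly than the surrounding tissue and conducts
the deposited power outward. For photothermal therapy the design question
is whether the temperature at the CNT–tissue interface — the value in
contact with the cells — reaches the 41–47 °C hyperthermia window; for
photoacoustic imaging the same heating drives the signal.

`cntheat` models one CNT as an infinitely long solid cylinder of radius
$a$ embedded in a tissue shell out to radius $b$ held at body temperature
$T_b$. Three geometric assumptions make the problem one-dimensional in
the radius $r$:

* the tube length greatly exceeds its diameter (aspect ratios of
  $10^3$ or more are typical), so axial conduction is negligible;
* the laser spot greatly exceeds the tube, so there is no angular
  dependence;
* the solid-cylinder idealization, common when the tube walls are dense
  (double- and multi-walled tubes especially).

The governing equations are classical conduction in cylindrical
coordinates: inside the tube,
$\rho_c c_c \,\partial T/\partial t = (k_c/r)\,\partial_r(r\,\partial_r T) + q(r)$,
and outside the same without the source, with conductivities $k_c$
(CNT) and $k_t$ (tissue). Four conditions close the problem: zero
gradient at the axis, continuity of temperature and of conductive flux
$k\,\partial_r T$ at $r=a$, and $T=T_b$ at $r=b$.

## The heating function and its simplification

Beer–Lambert absorption deposits
$$q(r) = (1-R)\, I_0\, \alpha\, e^{-\alpha z}, \qquad z = a - r,$$
with intensity $I_0$, absorption coefficient $\alpha$ and reflectivity
$R$, the depth $z$ measured radially inward from the surface. For a
nanometre-scale absorber $\alpha a \ll 1$ (0.12 at the defaults), so the
exponential factor stays within $[e^{-0.12}, 1] \approx [0.887, 1]$ and
the source is well approximated by its surface value
$q = (1-R) I_0 \alpha$. That constant-source simplification is what makes
a closed form possible; because it replaces the true deposition by a
pointwise upper bound, every temperature it predicts inside the absorber
is an overestimate. The package treats both sources as first-class
(`source_field()`) and quantifies the gap (`approximation_report()`).

## Closed-form steady state

Dropping the time derivative (the long-time limit; the transient solver
below justifies this) and integrating twice, the four conditions
determine all integration constants and give the piecewise profile

$$T(r) = \begin{cases}
\dfrac{q}{4k_c}(a^2 - r^2) + \dfrac{q a^2}{2 k_t}\ln(b/a) + T_b, & 0 \le r \le a,\\[6pt]
\dfrac{q a^2}{2 k_t}\ln(b/r) + T_b, & a < r \le b.
\end{cases}$$

The maximum sits on the axis; the interface value
$T(a) = q a^2 \ln(b/a) / (2k_t) + T_b$ carries the clinically relevant
rise. Two exact scaling laws follow and are enforced in the test suite:
at fixed $b/a$ the rise scales as $a^2$ (doubling the radius quadruples
it — the reason larger-diameter tubes are preferred as heating agents),
and the rise scales as $1/k_t$. Note the $a^2\ln(b/a)$ dependence: the
rise grows faster than linearly in the radius, and informal statements
that it is "proportional to the radius" should be read against the
closed form above.

Outside the absorber the radial heat flow per unit length,
$-k_t\, 2\pi r\, T'(r) = \pi a^2 q$, is conserved and equals the total
generated power per unit length — the energy-balance invariant used to
cross-check every solver in the package.

## Parameters

| Quantity | Symbol | Default | Units | Why |
|---|---|---|---|---|
| Tissue conductivity | $k_t$ | 0.567 | W m⁻¹ K⁻¹ | standard soft-tissue value |
| CNT conductivity | $k_c$ | 3000 | W m⁻¹ K⁻¹ | low end of the 3000–3500 range quoted for CNTs; a deterministic scalar was preferred over a range, and any value in the range changes only the ~10⁻⁴ K interior excess |
| Reflectivity | $R$ | 0.1 | — | a few percent of light is reflected |
| Absorption coefficient | $\alpha$ | 2.4×10⁷ | m⁻¹ | CNT optical absorption |
| Intensity | $I_0$ | 10¹⁰ (= 10⁶ W cm⁻²) | W m⁻² | reference irradiation level |
| CNT radius | $a$ | 5 | nm | single-walled tube scale |
| Far radius | $b$ | 100 $a$ | m | far-field convention; $T(b)=T_b$ |
| Body temperature | $T_b$ | 310.15 K (37 °C) | K | normal body temperature |

Densities and specific heats never enter the steady state. The transient
solver needs them; the defaults (CNT 1400 kg m⁻³ / 700 J kg⁻¹ K⁻¹,
tissue 1000 / 4000) are order-of-magnitude literature-style placeholders,
configurable like everything else. They set the *time scale* of the
approach to steady state, not its limit, and any time-to-steady-state the
package reports should be read with that caveat.

All computation is in SI with temperatures in kelvin; configuration keys
carry explicit unit suffixes (`cnt_radius_nm`, `intensity_W_per_cm2`,
`far_temperature_C`, ...) and are converted on load, so downstream code
never sees mixed units. Results are presented in °C to match clinical
convention, via `K_to_C()`.

## The quadrature solver (arbitrary sources)

`general_steady_solve()` handles any nonnegative radial source confined
to the absorber, in particular the exponential one the closed form drops.
One integration of the steady equation gives
$T'(r) = -Q(r)/(k_c r)$ inside, with $Q(r)=\int_0^r q(s)\,s\,ds$; the
removable singularity at the axis is evaluated by its limit 0 (the
integral is $O(r^2)$), which is exactly the zero-slope axis condition.
Exchanging the order of the second integration collapses the nested
double integral into single smooth ones,
$$T(r) - T(a) = \frac{\ln(a/r)}{k_c}\,Q(r) + \frac{1}{k_c}\int_r^a q(u)\,u\ln(a/u)\,du,$$
each evaluated by adaptive quadrature at relative tolerance $10^{-12}$
(the integrands are smooth; cost is trivial). Flux continuity and the
far-field pin fix the outer branch as $T_b + Q(a)\ln(b/r)/k_t$. With a
constant source this must coincide with the closed form — the central
cross-validation between the two solution paths, asserted at $10^{-10}$
relative error in the acceptance suite. Accumulated quadrature error
estimates are checked and a numerical-accuracy error is raised if they
exceed tolerance.

For the exponential source, $q_{\exp}(r) \le q$ pointwise implies
$T_{\exp}(r) \le T_{\mathrm{const}}(r)$ everywhere — the ordering the
test suite verifies over randomized parameter sets. The limit
$\alpha \to \infty$ at fixed $(1-R)I_0\alpha$ (a surface-localized
source) is deliberately not modelled; the volumetric description breaks
down there.

## The transient finite-volume solver

`solve_to_steady()` integrates the full two-region time-dependent
problem to quantify what the steady-state simplification discards.
Numerical choices:

* **Interface-conforming grid.** A cell edge sits exactly (bit-equal) at
  $r=a$, so the conductivity jump coincides with a face. Face
  conductivities are harmonic means weighted by the half-widths on each
  side, which reproduces flux continuity exactly for piecewise-linear
  profiles.
* **Geometric outer spacing** (default). The tissue-side log profile has
  curvature $\propto 1/r^2$, concentrated at the interface; the default
  grid matches the first tissue cell width to the CNT cell width and
  grows widths by a constant ratio (solved for so the cells exactly span
  $[a, b]$). Uniform spacing is available and is what the convergence
  study uses after midpoint splitting (`refine_grid()` halves every cell
  so Richardson-style order estimates are clean).
* **Nondimensionalization.** The system is assembled in scaled variables
  ($r/a$, $(T-T_b)/(q a^2/2k_t)$, $t\,k_t/(a^2\rho_t c_t)$): raw SI
  coefficients at nanometre scale produce badly scaled matrices. When
  the laser is off the temperature scale falls back to 1 K.
* **Backward Euler + tridiagonal solve.** The conductivity contrast
  $k_c/k_t \approx 5000$ and nanometre cells make explicit stepping
  hopeless; the implicit scheme is unconditionally stable for any `dt`.
  The default step is 1/100 of the tissue-shell diffusion time
  $b^2 \rho_t c_t / k_t$. `step()` performs one Thomas-algorithm solve;
  `solve_to_steady()` factors the (constant) system once.
* **Steady-state detection** by the max-norm per-step change normalized
  by the current rise, tolerance $10^{-10}$ — simple and monotone for
  this diffusive problem; exceeding `max_steps` raises a
  non-convergence error carrying the final residual. The initial
  condition is uniform $T_b$, the physically natural pre-laser state.

On the default 400-cell grid the converged interface temperature agrees
with the closed form to well within 1%, the discrete outer-face heat
flows all equal $\pi a^2 q$ to the stopping residual, and halving the
spacing reduces the $L_\infty$ error against the closed form at observed
order $\approx 2$, as the acceptance suite checks (grids of 200–800
cells; each march takes a fraction of a second).

## Experiments and dosing

`radius_sweep()` tabulates interface and centre temperatures over CNT
radii (default 0.5–10 nm, bracketing the 5 nm reference). By default
$b/a$ is held at the spec's ratio per point, matching the $b=100a$
convention, which makes the quadratic scaling exact; holding $b$ fixed
instead is available, with a domain error for rows where $b \le a$.
`hyperthermia_check()` classifies the interface temperature against the
41–47 °C window (inclusive bounds), and `intensity_for_interface()`
inverts the interface relation for $I_0$ to dose the laser onto a
target.

## What the randomized tests do and do not show

Property tests draw parameters from broad log-uniform ranges around the
defaults (radii 0.5–20 nm, $b/a \in [20, 200]$, conductivity ratios up
to $\sim 10^4$, reflectivities up to 0.9) — the regime of the intended
application. They verify *mathematical* guarantees: boundary conditions,
solver cross-agreement, orderings, scalings, conservation. They do not
validate the physics against measurement: real CNTs are hollow,
interfacial (Kapitza) resistance is neglected (perfect thermal contact
is assumed), tissue perfusion and bioheat sink terms are absent, pulsed
lasers are represented only by their average intensity, and the optical
parameters are single-wavelength constants. Passing tests therefore
certify the implementation of the model, not the model's fidelity to
tissue.

## Known limitations

* Pure conduction: no perfusion, phase change, or metabolic terms.
* Perfect thermal contact at the interface; no Kapitza resistance.
* Constant material properties (no temperature dependence).
* Continuous illumination only; pulse repetition structure is out of
  scope.
* The far field is a hard Dirichlet boundary at $b$; physically $b$
  stands in for "far enough that the body thermostats the temperature",
  and the $\ln(b/a)$ factor means the predicted rise depends (weakly)
  on that choice.
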
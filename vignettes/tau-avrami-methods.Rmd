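---
title: "Modelling post-traumatic tau aggregation with strain-coupled Avrami kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling post-traumatic tau aggregation with strain-coupled Avrami kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tauavrami)
```

## The model

After a traumatic brain injury, hyperphosphorylated tau accumulates slowly
for weeks and then rises sharply — a sigmoidal, saturation-type trajectory
that classical phase-transformation kinetics describe naturally. This
package models tau aggregation as a deterministic
Kolmogorov–Johnson–Mehl–Avrami (KJMA) nucleation–growth process:

* new misfolded-tau "seeds" appear at a volumetric nucleation rate
  $J(t') = J_0\,e^{k_J t'}$ (nuclei mm⁻³ day⁻¹),
* each seed grows as a sphere whose radius expands at
  $v(t) = v_0\,e^{k_v t}$ (mm/day), so a seed born at $t'$ has radius
  $R(t,t') = \frac{v_0}{k_v}\bigl(e^{k_v t} - e^{k_v t'}\bigr)$,
* the *extended volume* $Y_e(t)=\int_0^t J(t')\,\tfrac{4\pi}{3}R^3(t,t')\,dt'$
  sums what all seeds would occupy if they never overlapped, and the
  impingement-corrected burden is
  $X(t) = \alpha\,\bigl(1 - e^{-Y_e(t)}\bigr)$.

All times are in days; tau values are AT%-unit numbers (the percentage of
histological area labelled by the AT8 antibody) used as plain numbers inside
the exponentials — `0.0032` means 0.0032, never 0.0032/100. The saturation
bound $\alpha$ (default 0.35) caps the tissue-scale burden: even at six
months, AT8-positive area in the murine calibration data is only ≈0.25
AT%, so unbounded transformation toward 100% would be biologically
meaningless. $\alpha$ is an ordinary argument everywhere and can be raised
for late-stage tauopathy datasets.

The four kinetic constants are held in `kinetic_params()`. Positive,
negative and zero modulation coefficients are all meaningful (accelerating,
decelerating, constant rates), and $k_v, k_J$ may take either sign.

## Numerical evaluation of the extended volume

`extended_volume()` evaluates the closed form of the integral; the bracket
is an alternating combination of four exponential terms with denominators
$k_J,\,k_J+k_v,\,k_J+2k_v,\,k_J+3k_v$. Written naively, each term divides a
difference of exponentials by a possibly tiny denominator. We instead
evaluate each term as
$h_m = e^{(3-m)k_v t}\,t\,\varphi\!\bigl((k_J+mk_v)\,t\bigr)$ with
$\varphi(x) = \mathrm{expm1}(x)/x$ (and $\varphi(0)=1$), which is stable for
*any* magnitude of the individual denominators. The one remaining hazard is
that the alternating sum $h_0-3h_1+3h_2-h_3$ is a third finite difference of
order $(k_v t)^3$: when $|k_v|\,t$ is small the sum cancels almost
completely and the relative error grows like
$\varepsilon_{\text{mach}}/(k_v t)^3$. Below $|k_v|\,t = 10^{-2}$ —
where that error would exceed roughly $10^{-9}$ — the function switches to
adaptive quadrature of the integral form
(`extended_volume_quadrature()`, `stats::integrate` at relative tolerance
$10^{-11}$), which also covers $k_v = 0$ exactly. The integrand uses the
cancellation-free radius
$v_0 e^{k_v t'}(t-t')\varphi\!\bigl(k_v(t-t')\bigr)$, so the quadrature path
is well conditioned everywhere. Tests hold the two routes together to
better than $10^{-6}$ relative (measured: ~$3\times10^{-9}$ worst case over
200 random draws spanning the near-degenerate lines) and check continuity
across the switchover. Exponent arguments above 700 raise a typed overflow
error rather than returning `Inf`; the calibration objective converts that
error into a large finite penalty ($10^{12}$) so derivative-free optimizers
can keep moving.

## Calibration

The reference dataset, `murine_tbi_observations()`, is the global
AT8-positive burden in tau-transgenic mice after a single controlled
cortical impact: 0.0032, 0.0048, 0.0085 and 0.2533 AT% at days 1, 7, 60 and
180. `calibrate()` follows a two-stage procedure: a broad seeded random
exploration of parameter space (`global_search()`) followed by Nelder–Mead
refinement (`refine()`, via `stats::optim`) of the mean-squared error from
the best candidates.

Two design points deserve emphasis:

* **Identifiability.** $J_0$ and $v_0$ enter $Y_e$ only through
  $C = J_0 v_0^3$ (alongside the $k$-dependent exponentials), so a burden
  time series determines only $(C, k_v, k_J)$. The optimizer therefore works
  in the reduced coordinates $(\log C, k_v, k_J)$ — the log transform also
  enforces positivity — and the four-parameter report fixes $v_0$ at a
  configurable reference (default 0.0472197 mm/day) with
  $J_0 = C/v_0^3$. `tidy()` flags which terms are identifiable.
* **Search ranges** (the data do not pin them): $C$ log-uniform in
  $[10^{-14}, 10^{-2}]$ and $k_v, k_J$ uniform in $[-0.1, 0.1]$ day⁻¹,
  which brackets both the magnitudes of published constants for this system
  and the regimes the data shape demands. Defaults: $5\times10^4$ samples,
  5 refinements, simplex tolerance $10^{-12}$, iteration cap $10^4$. The
  refinement stage is deliberately unconstrained: the exploration bounds
  are a sampling prior, not a hard feasible set. The seed is mandatory —
  there is no silent clock seeding — and a fixed seed reproduces the fit
  bit for bit.

A caution for users comparing against published constants for this system:
evaluating the published optimized quadruple
($v_0=0.0472197$, $J_0=1.12609\times10^{-5}$,
$k_v=2.89573\times10^{-6}$, $k_J=3.14002\times10^{-6}$, $t$ in days) puts
$|k|\,t \le 6\times10^{-4}$ over the whole observation window, i.e. the
constant-rate regime, and yields $X(1)\approx 4\times10^{-10}$ — orders of
magnitude below the tabulated day-1 prediction of 0.00388. The published
predictions are therefore not reachable from the published constants under
these equations and units, and re-fitting the four points bottoms out near
RMSE $2.8\times10^{-3}$ (seed-independent), well above the published
$5.230\times10^{-4}$. The package exposes both: the printed constants can
be evaluated directly, and `calibrate()` reports its own honest fit. The
calibration machinery itself is validated where ground truth exists —
noise-free synthetic trajectories from known parameters are recovered
across seeds comfortably inside the test tolerances of 5% relative in
$C = J_0 v_0^3$ and 0.05 day⁻¹ absolute in $k_v, k_J$, typically by
several orders of magnitude.
`goodness_of_fit()` applied to the published observed/predicted pairs does
reproduce the published statistics (RMSE to 0.2%, $R^2 = 0.99998$ at five
decimals), confirming the table is internally consistent even though the
constants are not.

## Sensitivity analysis

`ofat_scan()` perturbs one parameter at a time about the baseline
$v_0=J_0=k_v=k_J=10^{-3}$ by factors $\{0.5, 0.8, 1.0, 1.2, 1.5\}$ and
returns a long tibble of trajectories. Because $Y_e$ is increasing in each
parameter (at a positive baseline), the transformed percentage responds
monotonically to every factor — a structural property the tests assert
pointwise — and every curve stays below $\alpha$.

```{r ofat, fig.width = 6, fig.height = 4, eval = FALSE}
plot_ofat(ofat_scan())
```

## Coupling to a mechanical strain field

A finite-element head impact simulation supplies one scalar per mesh node —
typically the logarithmic maximum principal strain (MPS) at the end of the
impact. `normalize_field()` min–max rescales the raw scalar to
$w_i \in [0,1]$; a constant field (the formula's 0/0 case) maps to
$w \equiv 1$ so the spatial model degrades to the homogeneous curve rather
than failing. The local extended variable is
$Y_i(t) = A^4 w_i^4\,Y_e(t)$: the fourth power is an exploratory modelling
choice that sharpens spatial contrast (the exponent is an argument,
default 4), and $A = (Q/Q_{\text{ref}})(N/N_{\text{ref}})$ is an optional
global impact-amplitude factor, 1 by default since the calibration is
single-impact and the field is normalized.

The naive local law $\tau_i = 1-e^{-Y_i}$ does not average back to the
calibrated curve, so a time-dependent correction $S(t)$ is solved from

$$\frac{1}{N}\sum_i \left(1 - e^{-S(t)\,A^4 w_i^4\,Y_e(t)}\right)
  = \alpha\left(1 - e^{-Y_e(t)}\right) = X(t),$$

an unweighted node mean, exactly as the coupling defines it. The left side
is continuous and strictly increasing in $S$, so the root is unique; it is
bracketed by doubling and bisected to an absolute tolerance of $10^{-12}$
on the mean. Before solving, feasibility is checked: as $S\to\infty$ the
mean approaches the fraction of nodes with positive weight, so a field
dominated by zero-strain nodes cannot reach the target and raises a typed
infeasibility error naming the time, rather than diverging silently.
$S(0)$ is set to 1 by convention when $Y_e=0$ (any value solves the vacuous
equation).

`tau_map()` performs the solve per output time in the composite variable
$\lambda(t) = S(t)\,Y_e(t)$, flooring each solution at the previous time's
$\lambda$. Analytically $\lambda$ is non-decreasing (the target mean is,
and the mean is strictly increasing in $\lambda$), but two independent
bisections can land on either side of their targets; the floor turns the
analytic monotonicity into an exact floating-point guarantee for every
node, at a cost to the enforced mean no larger than the solver tolerance.
Default output grid: 1, 50, 100, 150, 200, 250, 300, 350 days.

## Atrophy surrogate

Nodal burdens are reduced to elements (`element_tau()`: mean by default;
max and min exposed — the choice of reduction is not dictated by the
science, and the mean is the least biased default), thresholded at
$\tau \ge 0.7$ AT%-units (`apply_threshold()`), and the volume of surviving
elements tracked (`remaining_volume()`). Removal is automatically monotone
in time because $\tau$ is. Note the scale separation: the homogeneous
burden can never exceed $\alpha = 0.35$, so a uniform field never atrophies
at the 0.7 threshold; only the $w^4$-concentrated local burdens — which may
approach 1 — cross it, which is precisely the behaviour the surrogate is
meant to visualize. No feedback from removed volume into the kinetics is
modelled; that coupling is speculative and would change the global
trajectory itself.

## Synthetic strain fields

`generate_synthetic_field()` emulates the qualitative structure of an
FE-derived MPS field so the spatial machinery can be exercised and tested
without a head model: a smooth non-negative background
(default 0.05, diffuse strain) plus a focal Gaussian blob
(default amplitude 0.35, $\sigma = 3$ mm, centred at a frontal superficial
location of the mesh — a frontal-impact-like strain focus of peak ≈0.4,
the order of MPS reported for injurious impacts) and optional seeded
Gaussian noise, clipped at zero. Meshes are structured hexahedral grids
(default $20^3$ nodes at 1 mm) or triangulated spherical shells. What the
generator does *not* emulate: anatomical geometry, sulcal strain
concentration, gray–white interfaces, strain-rate effects and measurement
correlation structure — so passing tests demonstrate the correctness of the
kinetics, the mean-enforcing projection and the thresholding machinery, not
fidelity of any particular anatomical prediction.

## Problem sizes and tolerances used in the checks

The test-suite and acceptance-script runs use desk-scale problem sizes
chosen to exercise every property with comfortable margin: 200 random
parameter draws × 3 times for the closed-form/quadrature comparison; random
fields of $10^3$ and $10^5$ nodes plus a $20^3$ focal grid for mean
enforcement (defect ≤ $10^{-10}$ required, ~$10^{-12}$ measured); recovery
experiments over 5 seeds with $4\times10^3$-sample searches (the default
$5\times10^4$ is for production fits); the murine re-fit at
$2\times10^4$ samples. Randomness always flows from explicit seeds.

## Known limitations

* Calibration is global: one burden curve for the whole organ. Regional
  heterogeneity of tau spreading enters only through the mechanical
  weighting, not through region-specific kinetics.
* The model is deterministic by construction; it captures mean kinetics,
  not realization-to-realization variability of nucleation.
* The spatial mean is unweighted by element volume, exactly as the coupling
  defines it; on strongly graded meshes a volume-weighted mean would differ.
* The $w^4$ weighting and the single end-of-impact scalar per node are
  modelling conventions inherited from the framework, not validated
  mechanobiological laws.
* Single-impact calibration: repetitive-impact protocols (the clinically
  dominant scenario for chronic traumatic encephalopathy) are only crudely
  representable through the amplitude factor $A$.
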
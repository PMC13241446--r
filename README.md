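# tauavrami

Deterministic Avrami (KJMA) nucleation–growth kinetics of post-traumatic
tau aggregation, coupled to finite-element-derived mechanical strain
fields.

## The problem

After traumatic brain injury, hyperphosphorylated tau (measured
histologically as AT%, the AT8-antibody-positive area fraction) stays near
zero for weeks and then rises steeply — a sigmoidal trajectory that
nucleation-and-growth kinetics describe naturally. This package is for
modellers who want to (i) fit that trajectory with a mechanistic kinetic
law, (ii) project the fitted curve onto a spatial field of mechanical
vulnerability from a head-impact simulation, and (iii) explore a simple
atrophy surrogate on the resulting tau maps.

The core model: misfolded-tau seeds nucleate at
$J(t') = J_0 e^{k_J t'}$ and grow as spheres with radial velocity
$v(t) = v_0 e^{k_v t}$. The extended volume
$Y_e(t) = \int_0^t J(t')\, \tfrac{4\pi}{3} R^3(t, t')\, dt'$ has a closed
form, and the observable burden saturates at a bound $\alpha$ (default
0.35 AT%):

$$X(t) = \alpha \left(1 - e^{-Y_e(t)}\right).$$

Spatially, each mesh node carries a min–max-normalized strain
$w_i \in [0,1]$; the local burden is
$\tau_i(t) = 1 - e^{-S(t)\, A^4 w_i^4\, Y_e(t)}$, where the correction
factor $S(t)$ is solved at every time so that the unweighted node mean of
$\tau_i$ equals $X(t)$ exactly. Elements whose tau exceeds 0.7 AT%-units
are removed as an atrophy surrogate.

## Worked example

```r
library(tauavrami)

# 1. Calibrate the kinetics to the murine post-TBI AT% series
#    (0.0032, 0.0048, 0.0085, 0.2533 at days 1, 7, 60, 180).
obs <- murine_tbi_observations()
fit <- calibrate(obs, search_config(seed = 42, n_samples = 20000))
fit
#> <tau_calibration>
#>   v0 = 0.0472197 mm/day (reference)  J0 = 0.7537 nuclei mm^-3 day^-1
#>   kv = -1.30396 day^-1  kJ = 3.94324 day^-1
#>   rmse = 0.002752 AT%  R^2 = 0.999342  (seed 42, converged)
augment(fit)
#> # A tibble: 4 x 5
#>   time_days tau_at_percent  predicted    residual  abs_error
#>       <dbl>          <dbl>      <dbl>       <dbl>      <dbl>
#> 1         1         0.0032 0.00000735  0.00319    0.00319
#> 2         7         0.0048 0.000321    0.00448    0.00448
#> 3        60         0.0085 0.00872    -0.000224   0.000224
#> 4       180         0.253  0.253       0.00000375 0.00000375

# 2. Project the fitted curve onto a synthetic focal strain field
#    (a stand-in for an FE-derived MPS field).
mesh <- generate_synthetic_field(seed = 42, noise_sd = 0.01)
tf <- tau_map(normalize_field(mesh$field), fit$params)
tf
#> <tau_field>
#>   8000 nodes x 8 times (1..350 days), exponent 4, A = 1, alpha = 0.35
#>   final mean tau = 0.35 (homogeneous X = 0.35)

# 3. Atrophy surrogate: remove elements whose mean nodal tau reaches 0.7.
mask <- apply_threshold(element_tau(tf, mesh$elements), 0.7)
tail(remaining_volume(mask, mesh$elements), 3)
#> # A tibble: 3 x 2
#>   time_days volume_mm3
#>       <dbl>      <dbl>
#> 1       250       6046
#> 2       300       6046
#> 3       350       6046
```

Reading the numbers: the fitted curve matches the late observations almost
exactly but cannot reproduce the near-flat day-1/day-7 burden within this
model family — rmse ≈ 2.8×10⁻³ is the honest floor for these four points
(seed-independent), and the residual column shows where it sits. The
spatial step pins the node mean to the homogeneous curve at every output
time (hence "final mean tau = 0.35" at saturation), while high-strain nodes
run far ahead of the mean: of the 6859 mm³ mesh, 813 mm³ of focal
high-strain tissue has crossed the removal threshold by day 250.

Every result is a tibble or has `tidy()`/`glance()`/`augment()` methods,
and `plot_trajectory()`, `plot_ofat()`, `autoplot()` and
`plot_remaining_volume()` give quick ggplot2 views. A command-line driver
(`tauavrami_cli()`, or the installed `inst/cli/tauavrami` script) exposes
the same workflow as `simulate`, `calibrate`, `sensitivity`, `project`,
`atrophy` and `synth-field` subcommands with YAML config support.

See the vignette (`vignettes/tau-avrami-methods.Rmd`) for the model's
assumptions, the numerical design (degeneracy handling in the closed form,
the mean-enforcement solver) and known limitations — including why the
published optimized constants for this system do not reproduce the
published predictions under these equations.

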
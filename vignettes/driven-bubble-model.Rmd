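---
title: "The driven-bubble model behind bubbleacoustics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The driven-bubble model behind bubbleacoustics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bubbleacoustics)
```

## The model

A fish swim bladder driven by sonic muscles is modelled as a spherical gas
bubble of equilibrium radius $R_0$ pulsating in seawater. The linearised
equation of motion is that of a driven, damped oscillator whose stiffness
$K$ and damping factor $\beta$ are themselves functions of the driving
angular frequency $\omega$ — this frequency dependence is what separates
the model from the textbook mass–spring system and from the classical
Minnaert estimate
$$\omega_M = \frac{1}{R_0}\sqrt{\frac{3\gamma P_\mathrm{liq}}{\rho_\mathrm{liq}}}.$$

The chain of quantities evaluated by the package is:

* **Complex polytropic index.** Heat conduction between the compressed gas
  and the surrounding water is captured by
  $$\Gamma(\omega) = \frac{\gamma}{1 - \left[\frac{z}{\tanh z} - 1\right]
  \frac{6i(\gamma - 1)}{X^2}}, \qquad z = (1+i)\frac{X}{2},$$
  where $X = R_0/l_\mathrm{th}$ is the thermal diffusion ratio and
  $l_\mathrm{th} = \sqrt{D_p/2\omega}$ the thermal diffusion length. For
  small $X$ the gas behaves isothermally ($\Gamma \to 1$); for large $X$
  adiabatically ($\Gamma \to \gamma$). $\operatorname{Im}\Gamma \ge 0$
  produces thermal damping.
* **Stiffness.** With the dimensionless frequency
  $\epsilon = \omega R_0 / c$ and
  $$\omega_0^2 = \frac{3\operatorname{Re}\Gamma\, P_\mathrm{gas}}
  {\rho_\mathrm{liq} R_0^2} - \frac{2\tau}{\rho_\mathrm{liq} R_0^3},$$
  the stiffness is
  $$K(\omega) = \omega_0^2(\omega) + \frac{\epsilon^2}{1+\epsilon^2}\,
  \omega^2 .$$
  The additive radiation term matters: it is what lifts the undamped
  frequency above $\omega_0$ (and above $\omega_M$) at depth, where
  $\epsilon$ at resonance reaches $\approx 0.29$ at 3500 m. An alternative
  algebraic reading that divides the whole numerator by $1+\epsilon^2$
  collapses $\omega_\mathrm{und}$ onto $\omega_0$ and is inconsistent with
  the resonance-ratio table this package reproduces to seven digits, which
  is how the form above was pinned down.
* **Damping.** Three mechanisms:
  $\beta_\mathrm{th} = 3 P_\mathrm{gas}\operatorname{Im}\Gamma /
  (2\rho_\mathrm{liq} R_0^2 \omega)$ (thermal),
  $\beta_\mathrm{vis} = 2\eta_s/(\rho_\mathrm{liq} R_0^2)$ (viscous,
  negligible at bladder scale), and
  $\beta_\mathrm{ac} = \tfrac{\omega}{2}\,\epsilon/(1+\epsilon^2)$
  (radiation), with $\beta_0 = \beta_\mathrm{th} + \beta_\mathrm{vis}$ and
  $\beta = \beta_0 + \beta_\mathrm{ac}$. Thermal damping dominates at low
  frequency, radiation at high frequency.
* **Scattering cross-section.**
  $$\sigma_s = \frac{4\pi R_0^2}{\left(\frac{\omega_0^2}{\omega^2} - 1 -
  \frac{2\beta_0\epsilon}{\omega}\right)^2 + \left(\frac{2\beta_0}{\omega} +
  \frac{\omega_0^2}{\omega^2}\epsilon\right)^2},$$
  normalised as $\sigma_s' = \sigma_s/(4\pi R_0^2)$. Only the non-acoustic
  $\beta_0$ enters explicitly; radiation loss is carried by the $\epsilon$
  terms. Substituting the total $\beta$ here would double-count radiation
  damping and measurably shift the peak.

Three resonances are solved for: the undamped frequency
$\omega_\mathrm{und}$ from $\omega^2 = K(\omega)$, the natural frequency
from $\omega^2 = K - \beta^2$, and the far-field resonance
$\omega_\sigma = \arg\max_\omega \sigma_s$, the frequency at which a driven
bladder radiates most efficiently to distant receivers. The quality factor
is $Q_f = \omega_\sigma / (2\beta(\omega_\sigma))$.

## Study conditions

The shipped fixture table provides five environments — warm (20 °C) and
cold (1.5 °C) surface water, and cold water at 1000, 2000 and 3500 m — for
nitrogen and oxygen, the dominant swim-bladder gases. Pressure is the
dominant depth effect (0.101 MPa at the surface to 35.62 MPa at 3500 m);
the deep gas properties differ strongly from the surface ones (e.g. the
N$_2$ thermal diffusivity falls from $1.86\times10^{-5}$ to
$9.5\times10^{-8}$ m$^2$/s), which raises thermal damping at depth.
Radii of interest span 0.01–0.20 m.

Equilibrium gas pressure uses the Laplace relation
$P_\mathrm{gas} = P_\mathrm{liq} + 2\tau/R_0$, switchable off via
`laplace = FALSE`. At $R_0 \ge 0.01$ m and surface pressure the correction
is below 0.02%, so no downstream result depends visibly on the convention.

## Numerical choices

* **Units.** Strict SI internally (Pa, kg/m³, Pa·s, N/m, m/s, m²/s,
  rad/s); the tabulated MPa / mPa·s / mN/m / $10^{-9}$ m²/s conventions are
  converted exactly once, on fixture load.
* **Stable evaluation of $\Gamma$.** For $X > 80$, $\tanh z$ is 1 to
  double precision and $z/\tanh z - 1$ is replaced by $z - 1$ (complex
  `tanh` overflows near $\operatorname{Re} z \approx 350$); for
  $X < 10^{-3}$ the subtraction cancels catastrophically and the series
  $z^2/3 - z^4/45$ is used. Both branches were validated against a 50-digit
  arbitrary-precision evaluation (frozen into the test suite at
  $10^{-12}$ relative), and the isothermal/adiabatic limits hold to
  $10^{-6}$ for $\gamma \in [1.3, 2.0]$. With that, double precision
  reproduces the seven-significant-digit resonance-ratio targets; no
  extended precision is needed at run time.
* **Root finding and maximisation.** Roots (`uniroot`, relative tolerance
  $10^{-12}$) are bracketed in $[0.5, 2]\,\omega_M$, widened geometrically
  to at most $[10^{-2}, 10^{2}]\,\omega_M$ — every resonance studied lies
  within a few percent of $\omega_M$ — and the bracket is checked for a
  single sign change. The cross-section maximum uses Brent's method
  (`optimize`) on $\log \sigma_s'$ at relative tolerance $10^{-10}$;
  convergence onto a bracket edge widens the bracket once and then fails
  loudly. Solutions agree with independent dense-grid/bisection scans to
  better than six significant digits on all fixtures.
* **Overdamped inputs.** `solve_natural()` reports a non-oscillatory
  outcome instead of throwing; `damping_regime()` classifies
  $\beta/\omega_\mathrm{und}$ against 1 with a $10^{-9}$ critical band.
* **Profiles.** Depth-resolved analyses consume property-vs-depth tables
  (CSV, SI columns) interpolated with cubic splines (`splinefun`, method
  `"fmm"`, which reproduces polynomials up to cubic exactly). Thermal
  diffusivity alone is interpolated on the log scale: it drops two orders
  of magnitude over the first kilometre and a linear-scale cubic spline
  through so coarse a grid overshoots below zero. Log-scale interpolation
  is exact at the nodes and keeps the interpolant positive. Property
  correlations (equation-of-state recomputation of the table) are
  deliberately out of scope; profiles are data.
* **Power-reduction reference.** The depth-loss curve compares each
  depth's peak $\sigma_s$ (at that depth's own far-field resonance)
  against the cold-surface peak for the same radius and gas — peak to
  peak, not at a common frequency, matching how the factor-of-~300 deep
  loss is defined. The canonical comparison radius is $R_0 = 0.10$ m, the
  same single radius used for the damping-breakdown analyses; the deep
  peaks are radius-invariant, but the sharp surface reference peak is not
  (its height grows with $R_0$ exactly as the surface $Q_f$ does), so the
  quoted fold-reductions are tied to that choice.

## The synthetic generators

`perturbed_specs()` draws seeded bubble specifications: log-uniform radii
in [0.005, 0.25] m and ±20% multiplicative perturbations of every physical
property of a randomly chosen fixture pair. It exists to exercise
invariants (damping non-negativity, normalisation identities, solver
convergence) on a neighbourhood of the study conditions, not to emulate
ocean variability: real covariance between properties (temperature–
viscosity, pressure–sound-speed) is deliberately ignored, so passing
property tests says nothing about oceanographic realism. `limit_cases()`
constructs corner specs (zero surface tension + adiabatic + vanishing
$\epsilon$; isothermal; radiation-free) whose closed-form answers are
known exactly.

## Worked example

```{r example}
fx <- load_fixture_environments()
pair <- fx[["depth_3500m.N2"]]
spec <- bubble_spec(0.05, pair$environment, pair$gas)
summary(spec)
```

At 3500 m a 5 cm nitrogen bubble resonates near 1379 Hz — above its
Minnaert estimate by 2% — with $Q_f \approx 3.8$, against $Q_f \approx 57$
for the same bubble at the cold surface. The radiated-power loss versus the
surface:

```{r power}
power_reduction_db(fixture_profile(), "N2", 0.10, c(0, 1000, 2000, 3500))
```

## Known limitations

* The bubble is linear and spherical: no large-amplitude dynamics, no
  prolate-spheroid frequency correction, no bladder-wall viscoelasticity —
  a real swim bladder damps faster and radiates less than this model.
* Depth profiles are only as good as the supplied table; the shipped
  4-node constant-temperature profile is adequate for the fixture depths
  and smooth interpolation between them, not a substitute for a measured
  CTD-derived profile.
* Band integration of spectral source levels assumes a flat spectrum
  across the band.
* The published fold-reduction figures for 1000/2000/3500 m appear to be
  generous roundings (the 2000 m value especially); the package reports
  the computed factors and makes the comparison radius explicit rather
  than matching rounded prose.
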
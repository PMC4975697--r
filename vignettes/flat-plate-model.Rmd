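---
title: "Modelling flat-plate cultivation and biohydrogen production of Cyanothece"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling flat-plate cultivation and biohydrogen production of Cyanothece}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyanoH2)
```

## Scope and assumptions

`cyanoH2` simulates batch cultivation of the nitrogen-fixing cyanobacterium
*Cyanothece* sp. ATCC 51142 in flat-plate photobioreactors, in two regimes:
photo-autotrophic growth (light + CO~2~, the cheap route to biomass) and
photo-heterotrophic growth on glycerol with nitrogenase-catalysed hydrogen
production. The governing assumptions:

* **Light is the master variable.** Temperature is treated as fixed (35 °C
  cultivation); CO~2~ supply, gas–liquid mass transfer and pH are not
  modelled. Light enters every rate through a depth-averaged photoresponse.
* **One spatial dimension.** The plate is described only by its width `L`
  (the light path); the culture is otherwise well mixed. Mixing faster than
  the photosynthetic/enzymatic response would let cells integrate light over
  depth and is not represented — predictions for thick, vigorously mixed
  plates are therefore conservative.
* **Monochromatic optics.** A single extinction coefficient lumps cell
  absorption and bubble scattering; no wavelength resolution, no radiative
  transfer, no photoacclimation.
* **Hydrogen is a pure sink.** `H2` feeds back into no other balance; its
  glycerol/electron cost is neglected.

## The light field

Local intensity decays as `I(z) = I0 exp(-a z)` with extinction

    a = tau_c * X[g m^-3] + 3 * alpha_g / d_b      (m^-1)

Biomass is handled in g L^-1 everywhere else; the conversion factor 1000
lives only inside the light field. With the default optics
(`tau_c = 0.126` m² g⁻¹, `alpha_g = 0.0067`, `d_b = 0.002` m) cell
absorption overtakes bubble scattering (10.05 m⁻¹) already below
0.1 g L⁻¹. Two illuminated surfaces superpose two opposed exponentials with
`I0` on each face; interfacial reflection is neglected.

The Aiba response `k(I) = I/(I + ks + I^2/ki)` peaks at `sqrt(ks*ki)`
(≈ 275 µmol m⁻² s⁻¹ for growth, `ks = 165`, `ki = 457`; the hydrogen
response uses `ks = 140`, `ki = 457`). Its depth average

    kbar(X) = (1/L) * integral of k(I(z)) dz

is evaluated by composite trapezoid quadrature. The base interval count is
20, the count validated for the 0.025 m laboratory plate (at 12 g L⁻¹ it
stays within 4% of a 10⁴-interval reference, comfortably inside the 10%
design bound). Because the integrand varies on the attenuation length
`1/a`, a *fixed* count under-resolves thick reactors: at `L = 0.2` m and
3 g L⁻¹ the boundary layer is ≈ 2.6 mm while 20 intervals give 10 mm
steps, and the resulting quadrature error (≈ 6% here) is large enough to
scramble fine comparisons between designs — it even makes the predicted
biomass ceiling spuriously non-monotone in the incident intensity. The
depth average therefore refines adaptively, `n = max(n_steps,
ceiling(2 a L))`, so a step never exceeds half the attenuation length; this
leaves laboratory-scale calculations on the classic 20-interval rule and
keeps scale-up calculations within ~1% of the converged integral.
`adaptive = FALSE` restores the fixed count exactly.

One invariant worth spelling out: two-sided illumination at the same
per-surface intensity is guaranteed to outperform one-sided illumination
only while local intensities stay below the Aiba optimum. Above it (e.g.
`I0 = 457` in a nearly transparent culture) the extra photons inhibit, and
the two-sided average can dip below the one-sided one. The package treats
this as model behaviour, not a bug; the corresponding regression test
asserts the ordering in the sub-inhibitory regime only.

## Autotrophic growth and the biomass ceiling

    dX/dt = kbar(I; X) * mu_max_a * X - mu_d_a * X^2

with `mu_max_a = 0.255` h⁻¹ and `mu_d_a = 0.00227` L h⁻¹ g⁻¹. Because
`kbar` falls monotonically with `X`, the growth–decay balance
`kbar(I; X) mu_max_a = mu_d_a X` has a unique positive root: the maximum
sustainable ("plateau") concentration `Cmax`. `steady_state_cmax()` finds
it by bracketed root-finding on [10⁻³, 10³] g L⁻¹ (relative tolerance
10⁻⁶), a bracket spanning all physically plausible densities; a missing
sign change (e.g. a dark reactor) is reported explicitly rather than
guessed. Long-horizon integration agrees with the root to better than 0.1%
and is kept as a cross-check, not the definition.

## Heterotrophic growth and hydrogen

The six-state Droop model tracks biomass `X`, nitrate `N` (mg L⁻¹),
normalized internal nitrogen quota `q`, glycerol `C` (mmol L⁻¹),
accumulated oxygen `O2` (L L⁻¹) and cumulative hydrogen `H2` (mL L⁻¹).
Growth runs at `kbar * mu_max_h * (1 - kq/q)` — arrested as the quota falls
to its minimum `kq = 0.165` — and nitrate uptake both refills the quota and
releases oxygen (ATP for uptake comes from photosynthesis). Hydrogen
evolves as `Y_HX * hbar(I) * X * f(N) * f(O2)` with smooth switches:
`f(N)` is *exactly* zero at or above 100 mg L⁻¹ nitrate (the numerator
vanishes algebraically) and `f(O2)` equals one only in anaerobiosis. The
smoothing constants (0.1) are kept verbatim in model units.

Numerical choices:

* `K_C = 0` (glycerol never limiting in the fitted data) makes the Monod
  factor `C/(C + K_C)` formally 0/0 at `C = 0`; it is defined as 1 for
  `C > 0` and 0 at `C <= 0` (the limit behaviour).
* Glycerol consumption (growth *and* maintenance) stops once the pool is
  exhausted. The printed balance has no such guard because glycerol was
  always in excess in the fitted experiment; without it, maintenance would
  drive `C` indefinitely negative at aggressive trial parameters during
  estimation.
* States are never clamped. Small negative excursions of the order of the
  absolute tolerance are tolerated and recorded (`"min_state"` attribute);
  anything beyond 10⁻⁶ warns, because it indicates solver misconfiguration
  rather than model behaviour.
* The system is stiff — the oxygen balance relaxes orders of magnitude
  faster than growth once decay sets in, and an explicit Euler scheme is
  unstable at any practical step. The default integrator is `lsoda`
  (`rtol = 1e-8`, `atol = 1e-10`); `radau` is available. A fixed-step
  classical RK4 at `dt = 10^-3` h is shipped purely as a cross-checking
  oracle (the test suite holds it to 10⁻⁵ of the stiff solution over
  240 h), and a 3-stage Radau IIA collocation stepper backs the estimation
  module.

For reactor comparisons, `average_h2_productivity()` integrates a 240 h
batch from the *stationary-phase preset*: `X0 = 3.5` g L⁻¹, `N = 0`,
`q = kq`, `O2 = 0`, `C = 50` mmol L⁻¹. Hydrogen is produced mainly in the
stationary and decay phases, so the preset opens both switches from the
start and excludes residual growth; the published sweep conditions do not
pin down the initial quota or glycerol level, and the preset (exposed as an
argument) is this package's single fixed reading of them. With it, the
package reproduces the qualitative design conclusions: productivity falls
steeply with width (thin plates for hydrogen) and rises with two-sided
intensity.

## Parameter estimation

`generate_synthetic()` is first-class: it simulates the heterotrophic model
under stated conditions and applies independent multiplicative Gaussian
noise per observed variable, deterministically under a seed. Its defaults
emulate the laboratory batch the kinetics were fitted on — nutrient-replete
start (0.2 g L⁻¹ biomass, 500 mg L⁻¹ nitrate, full quota, 50 mmol L⁻¹
glycerol), one-sided 92 µmol m⁻² s⁻¹ in the 0.025 m plate, sampling every
5 h over 150 h, 5% relative noise on `X, N, C, O2, H2` (the quota is not
measurable). What recovery tests on such data do *not* exercise: real
measurement error is not multiplicative-Gaussian-independent (gas
chromatography drift, autocorrelated biomass proxies), and model error is
absent by construction — success here demonstrates identifiability and
correctness of the estimation machinery, not field accuracy.

The loss is a weighted sum of squared residuals with per-variable weights
`1/mean(|observed|)` (the data give no replicate variances, and this
equalizes the wildly different units). Optimization is bounded L-BFGS-B
with seeded multistart (default 5 starts: the objective is non-convex), a
derivative-free simplex polish if the line search aborts on a flat valley,
and explicit reporting of non-convergence. Two trajectory backends:

* **shooting** — each candidate is integrated with the stiff solver;
* **collocation** — the trajectory solves the 3-stage Radau IIA
  orthogonal-collocation equations on fixed elements (8 per observation
  interval by default, set by a convergence study on the default design:
  4 subdivisions leave visible transient error at the nitrate crash, 8
  bring the whole trajectory within ~2×10⁻⁴ absolute of the reference).
  The stage equations — the equality constraints of a simultaneous
  discretization — are solved exactly per element by damped exact Newton,
  i.e. a feasible-path treatment; a full simultaneous NLP would need a
  constrained solver of the Ipopt class, which the estimation module does
  not assume.

On noiseless data the two backends agree to ~10⁻⁷ on the per-observation
RMS loss scale and to ~10⁻⁴ relative in the estimates; the suite asserts
both. Recovery on the default design: every free parameter within 1% from
noiseless data; `mu_max_h` and `kq` within 10% at 5% noise; and with
glycerol in excess a free `K_C` pins to its lower bound 0 — the degenerate
value the laboratory fit also produced.

## Sensitivity analysis

`normalized_sensitivity()` computes `S(t) = (dy/dx)(x/y)` by 1% central
finite differences on the parameter. Defaults chosen here: integration at
`rtol = 1e-10`, `atol = 1e-12` (differencing amplifies solver noise), and a
floor `eps = 10^-6` in each output's units below which `S` is reported
`NA` — normalized sensitivity is undefined where the output vanishes, and
windows where hydrogen or oxygen are identically absent are flagged rather
than NaN-propagated. Two analytic anchors double as tests: `S(H2; Y_HX)`
is exactly 1 wherever hydrogen is present (linearity), and during growth
`S(X; mu_max_h) > 0` while `S(X; kq) < 0` — to grow more biomass, raise
the growth rate or breed for tolerance of nitrogen deprivation.

## Mutant transform

A low-chlorophyll mutant with photosystem cross-section reduced by fraction
`r` rescales exactly the light-coupled constants: `ks`, `ki` (and the
hydrogen pair) by `1/(1-r)` — both are inversely proportional to the
cross-section — and `tau_c` by `(1-r)`, since cellular extinction tracks
the chlorophyll mass fraction. The turnover and damage/recovery constants
of the underlying mechanistic decomposition cancel in these ratios and are
deliberately not independent configuration values. The default `r = 0.30`
mirrors reported low-chlorophyll isolates of *Dunaliella tertiolecta*. The
payoff is scale-dependent: in a wide reactor reduced self-shading dominates
and the mutant's depth-averaged response — hence its biomass ceiling —
matches or beats the wild type at any density (asserted over a grid), while
in a thin, well-lit plate the transform mostly trades away saturation
headroom. Published gain figures for such a mutant lack the reactor width
and initial conditions needed to reproduce them numerically, so the package
treats mutant benefits as ordering statements only.

## Problem sizes and determinism

The shipped tests and the acceptance script run the model at the study's
native sizes: 150–240 h batches on hourly-to-5-hourly grids, 20 to a few
hundred quadrature intervals, 30-point observation designs, 2–5 optimizer
starts. Every stochastic path (synthetic noise, multistart draws) is
driven by an explicit integer seed, and the command-line interface logs the
resolved configuration and seed with every run.

## Known limitations

* The two-sided light field ignores reflection and any cross-talk with the
  sparging pattern; at high intensities the photoinhibited regime makes
  two-sided/one-sided comparisons intensity-dependent (see above).
* Scale-up hydrogen predictions inherit the stationary-phase preset; a
  culture entering the batch with residual quota (`q > kq`) would grow
  first and shade itself more.
* Dark hydrogen production under fast mixing is not represented, so thick
  well-mixed reactors may do better than predicted.
* The estimation module quantifies identifiability only through local
  sensitivity proxies; it is not a Bayesian posterior, and confidence
  statements beyond "the observed outputs respond to this parameter" need
  profile or resampling methods outside this package's scope.
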
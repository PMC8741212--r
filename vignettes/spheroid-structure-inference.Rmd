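---
title: "Quantifying tumour-spheroid structure: model, likelihood, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumour-spheroid structure: model, likelihood, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroidstruct)
library(dplyr)
```

## The scientific problem

Tumour spheroids grown in non-adherent culture develop a layered structure:
an actively cycling rim, an inner region of viable but cell-cycle-arrested
cells (the *inhibited region*), and a central *necrotic core*. As spheroids
grow, loss of necrotic material eventually balances proliferation at the rim
and overall growth stalls at a *limiting size*. Each fixed-and-imaged
spheroid is summarised by three numbers: the outer radius $R$ (µm), the
relative inhibited radius $\phi = R_i/R$, and the relative necrotic radius
$\eta = R_n/R$, with $R > 0$ and $0 \le \eta \le \phi < 1$.

This package implements Greenspan's classical mechanistic description of
that process together with a likelihood-based statistical workflow for
estimating its parameters, comparing experimental conditions (typically
seeding densities), and quantifying uncertainty.

## The mechanistic model

Nutrient and inhibitor transport is fast relative to proliferation, so both
are taken at diffusive equilibrium. Two dimensionless groups then govern
the structure:

* $Q \in (0,1)$ — the balance between nutrient supply/consumption and
  inhibitor production/clearance (`compose_Q()`). The regime $Q < 1$
  corresponds to the inhibited region appearing before the necrotic core.
* $\gamma = \lambda/s > 0$ — the ratio of the necrotic mass-loss rate
  $\lambda$ to the per-volume proliferation rate $s$ (`compose_gamma()`).

together with $R_c$, the radius at which necrosis first appears.

**Structural model.** The inner structure is a function of outer radius
alone, through three phases: $\phi = \eta = 0$ for $R \le Q R_c$;
$\phi = \sqrt{1 - Q^2R_c^2/R^2}$, $\eta = 0$ for $QR_c < R \le R_c$; and for
$R > R_c$ the pair $(\phi, \eta)$ solves the cubic system

$$
0 = 2R^2\eta^3 - 3R^2\eta^2 + R^2 - R_c^2, \qquad
0 = R^2\phi^3 + \left(Q^2R_c^2 - R^2(1 + 2\eta^3)\right)\phi + 2\eta^3R^2 .
$$

The first cubic factors as $(1-\eta)^2(1+2\eta) = R_c^2/R^2$, whose left
side is strictly decreasing on $(0,1)$, so $\eta$ is unique; the second has
a proven sign change on $(\eta, 1)$. Both are depressed cubics with three
real roots, so `spheroid_structure()` uses the exact trigonometric closed
form plus one Newton polish step; bracketed `uniroot()` solvers and dense
grid scans serve as independent oracles in the test suite. Phase
boundaries are assigned by convention to the lower phase ($R = QR_c$ is
phase 1, $R = R_c$ is phase 2); the map is continuous there, so the choice
is observationally irrelevant.

**Growth.** `simulate_growth()` integrates
$\mathrm{d}R/\mathrm{d}t = (s/3)\left[(1-\phi^3) - \gamma\eta^3\right]R$
with `deSolve::lsoda` at relative tolerance $10^{-8}$, re-solving the
structural model at every right-hand-side evaluation (the closed form makes
this cheap; no caching across steps).

**Steady state.** Setting $\mathrm{d}R/\mathrm{d}t = 0$ couples the mass
balance $1 - \bar\phi^3 = \gamma\bar\eta^3$ to the structural system.
Parameterising by $\rho = \bar\eta/\bar\phi \in (0,1)$ reduces this to one
scalar equation (`steady_state()`): with
$\bar\phi = (1+\gamma\rho^3)^{-1/3}$ and $\bar\eta = \rho\bar\phi$,

$$
Q^2(1-\bar\eta)^2(1+2\bar\eta)
  = 1 - \bar\phi^2 - \frac{2\bar\eta^3(1-\bar\phi)}{\bar\phi},
\qquad
\bar R = \frac{R_c}{(1-\bar\eta)\sqrt{1+2\bar\eta}} .
$$

The residual has opposite signs at the two ends of $(0,1)$ for every valid
parameter set, so a bracketed root always exists; a 1000-point vectorised
pre-scan brackets it (and would flag multiple roots, never observed) before
`uniroot` refines to $10^{-12}$ in the argument. Both defining equations
hold to $10^{-10}$ at the returned state. Uniqueness of the $\rho$ root is
not proven; if several sign changes ever appeared the solver would warn and
take the smallest.

**Identifiability and inversion.** The steady-state map
$m: (Q, R_c, \gamma) \mapsto (\bar R, \bar\phi, \bar\eta)$ has a
closed-form inverse (`invert_steady_state()`):
$R_c = \bar R\sqrt{(1-\bar\eta)^2(1+2\bar\eta)}$,
$\gamma = (1-\bar\phi^3)/\bar\eta^3$, and
$Q^2 = \bar R^2[(1+2\bar\eta^3)\bar\phi - \bar\phi^3 - 2\bar\eta^3]/(R_c^2\bar\phi)$.
All three structure measurements are therefore needed: dropping $\phi$
(no cell-cycle label) or observing $\bar\eta = 0$ leaves parameters
unidentifiable. `invert_structure()` applies the same algebra to any
phase-3 observation, recovering $(Q, R_c)$ without a steady-state
assumption. Sensitivities $\partial m/\partial\theta$ come from implicit
differentiation of the steady-state system with analytic partials
(`steady_state_jacobian()`), cross-checked against central finite
differences; finite differences are a check, never the default.

A caveat the analysis itself surfaces: real late-time spheroids can shrink
below the limiting size ("decay"), which this growth law cannot produce;
no decay mechanism is modelled.

## The statistical layer

Observations $x_i = (R_i, \phi_i, \eta_i)$ are modelled as multivariate
normal about the model mean, $x_i \sim N(\mu, \Sigma)$, with $\Sigma$ the
*plug-in* sample covariance (unbiased, $n-1$ denominator) of the relevant
group — per (density, day) group by default, or pooled across densities
(`pooled_covariance()`) for steady-state analyses. $\Sigma$ is held fixed
during optimisation and never co-estimated with $\theta$. Records from
phases 1–2 carry structural zeros in $\phi$ or $\eta$; zero-variance
coordinates are dropped from the likelihood with a warning rather than
making it degenerate.

All three fit-able models are saturated three-parameter descriptions of a
three-dimensional mean, so whenever the sample mean lies in the model's
image the MLE is available in closed form (the inversion of the mean);
`fit_spheroid_model()` uses that and falls back to a multi-start
Nelder–Mead search (10 Latin-hypercube starts) with a BFGS polish using the
analytic chain-rule gradient
$\nabla_\theta \ell = J_m^\top\, n\Sigma^{-1}(\bar x - \mu)$.

**Profile likelihoods.** `profile_likelihood()` normalises the profile to 0
at the MLE, sweeps a grid of 41 points spanning ±4 plug-in standard errors
(extended adaptively until the profile crosses the threshold), warm-starts
each nuisance optimisation from the adjacent grid point, and locates the
95% interval endpoints by bisection at the drop
$\Delta_{1,0.95}/2 \approx 1.92$ (`wilks_threshold()`). Endpoints that hit
a parameter bound first are flagged unbounded.

**Equivalence tests.** `lrt_equivalence()` compares a joint fit (one
$\theta$ for all groups, group-specific or pooled $\Sigma$) against
group-wise fits via $T = 2(\sum_g \ell_g - \ell_{joint}) \sim \chi^2(\nu)$
with $\nu = (G-1)\dim\theta$. `lrt_single_parameter()` shares only one
indexed parameter across groups (all others free per group; $\nu = G-1$) —
the constraint structure behind per-parameter comparisons was genuinely
open, and this is the choice implemented. Small negative statistics from
optimiser noise ($T > -10^{-6}$) are clipped to zero; anything more
negative warns.

**Confidence regions.** `trace_confidence_region()` finds a boundary point
by bisection along a ray from the MLE (first coordinate axis by default —
the ray choice was open and only affects where the trace starts), then
integrates the rotated-gradient field, re-projecting onto the contour by a
Newton step along the gradient at every step so the log-likelihood drift
stays below $10^{-6}$ over the whole boundary. Because parameter scales
differ by orders of magnitude (e.g. $Q$ vs $R_c$), tracing happens in
curvature-scaled coordinates internally. Three-parameter regions are
rendered as two-dimensional slices at the 3-degree-of-freedom threshold
(`slice_region_3d()`); slices whose conditional maximum falls below the
threshold are empty by construction.

## The phase-3 linear trajectory model

Empirically, phase-3 structure develops nearly linearly in
$(R, \phi, \eta)$ space, while the cubic structural model is curved — a
useful misspecification diagnostic. `fit_phase3_line()` fits

$$ x(\tau) = (R_c^{emp}, \phi_c, 0) + \tau\,\hat q, $$

with a latent progression value $\tau_i$ per observation, by maximising the
normal likelihood jointly over the line and the $\tau_i$. Profiling out
$\tau_i$ makes the ML line the principal axis of the $\Sigma$-whitened
centred data, de-whitened back — an exact errors-in-variables (total least
squares) solution for this model. The anchor is reported where the fitted
line crosses $\eta = 0$ and $\tau$ is signed to increase with $\eta$;
negative fitted $\tau$ values are reported, not clipped, since clipping
would bias the line. Phase-3 records are selected by a configurable
threshold on measured $\eta$ (default 0.01; the field's selection rule is
not standardised, so the threshold is explicit).

When $\Sigma$ is not supplied it is estimated from the data about the
fitted line, iterated twice. Two numerical points matter: the *initial*
whitening uses only the per-coordinate variances, because whitening by the
full sample covariance (signal plus noise) renders the data exactly
isotropic and erases the line; and the residual covariance is
rank-deficient along the fitted direction, so its null eigenvalue is
floored at $10^{-3}$ of the largest. `lrt_phase3_shared()` tests a shared
line across groups with $\nu = 4$ per extra group (two free anchor
components in the $\eta = 0$ plane, two free direction components on the
unit sphere; the $\tau_i$ are free under both hypotheses and cancel). The
pooled $\Sigma$ is estimated once on the pooled selection and held fixed
for null and alternative fits, so the test compares line parameters only —
whether the original analysis pooled or stratified $\Sigma$ here is
unknown; pooling keeps the null and alternative on a common observation
model.

## The synthetic cohort generator

`generate_cohort()` emulates the cross-sectional design of multi-density
spheroid experiments: spheroids seeded at 2500/5000/10000 cells, grown
under the model, and harvested destructively on days 3–24 (so each
spheroid contributes one row and noise is independent across days),
10 spheroids per condition and day by default. Defaults, chosen once:

* **Mechanistic truth** $\theta = (Q, R_c, \gamma) = (0.75, 149, 0.737)$ —
  the scale of melanoma spheroids with a ~340 µm limiting radius, ~90%
  inhibited and ~72% necrotic relative radii.
* **Noise** $\Sigma = \mathrm{diag}(20\ \mu m, 0.02, 0.1)^2$ —
  standard deviations of the order implied by late-time confidence-interval
  widths at 20 spheroids per condition; illustrative values, not measured
  ones.
* **Proliferation rate** $s = 1.5$/d and initial-radius medians scaling as
  density$^{1/3}$ from 100 µm at 10000 cells (lognormal, CV 0.1): these
  make the mean trajectory reach its limiting size by about day 18 and put
  day-3 radii near 200–250 µm, ordered by density, matching the
  qualitative dynamics of late-time growth curves. Only the generator uses
  $s$; the inference workflow never fits the time course. True
  initial-size distributions are unreported, so these medians are
  placeholders and flagged as such.
* **Invariant repair.** A trivariate normal draw can violate
  $0 \le \eta \le \phi < 1$. Components that are structurally zero in the
  model (both inner radii in phase 1, $\eta$ in phase 2) are emitted as
  exact zeros — the imaging pipeline reports no detectable region — and the
  noise vector on the remaining components is redrawn (up to 100 times)
  until the invariant holds, rather than clipped, to avoid boundary point
  masses. Redraws are counted and reported. With the default noise this
  repair truncates roughly 4% of deep-phase-3 draws at the $\eta \le \phi$
  boundary, biasing $\bar\eta$ down by a fraction of its standard error —
  visible as mild undercoverage for $\gamma$ in coverage simulations (see
  below).
* **Reproducibility.** One seed in the config; per-spheroid substreams are
  derived by hashing (seed, density, day, replicate), so a condition's rows
  do not depend on which other conditions are generated.

What the generator deliberately does **not** emulate: late-time decay below
the limiting size, day-dependent covariance growth (supported via a
`Sigma(day)` function but not default), within-spheroid longitudinal
correlation (none exists in a destructive design), aggregation dynamics in
the first days, and image-processing artefacts. Passing tests therefore
validate the inference machinery under the stated observation model, not
the biology of any particular cell line.

## Validation design and problem sizes

The test suite validates every stage against independent oracles: dense
grid scans and bracketed solvers for the cubics, an independent
three-dimensional simultaneous solve for the steady state, finite
differences for the Jacobian and gradients, analytic normal-theory
ellipses and marching-squares contours for region tracing, angular grid
scans for the TLS direction, and simulation studies for the statistical
properties. Simulation sizes were fixed at values a laptop handles in
minutes: 200 replicate day-21 cohorts of 20 spheroids for profile-interval
coverage (the per-density design of the steady-state analysis), 500 null
replicates each for the type-I error of the steady-state and TLS
equivalence tests, and $10^4$ observations for point-estimate consistency.

Two honest limitations surface in those studies, both properties of the
plug-in likelihood procedure and the stated generator conditions rather
than implementation artefacts.

First, treating an estimated covariance as known makes Wilks calibrations
anticonservative at small $n$. For the two-group equivalence test with
$\Sigma$ re-estimated from 10 spheroids per group, the statistic is
Hotelling-$T^2$-like rather than $\chi^2_3$: the nominal 5% cut-off
rejects $\approx 11\text{–}13\%$ of null replicates
($T^2 \sim 3.375\,F_{3,16}$ at these sizes, so
$P(T^2 > \chi^2_{3,0.95}) \approx 0.115$). The type-I simulations
therefore supply the generating covariance, under which the $\chi^2$
reference applies and the empirical rate sits at the nominal level; users
comparing small groups with re-estimated covariances should expect the
anticonservatism quantified above.

Second, the generator's invariant repair truncates the normal draws at the
$\eta \le \phi$ boundary (about 4% of deep-phase-3 draws at the default
noise), biasing $\bar\eta$ down by $\approx 0.09$ standard deviations and
shrinking its spread $\approx 8\%$. Propagated through
$\gamma = (1-\bar\phi^3)/\bar\eta^3$, profile intervals for $\gamma$ cover
the generating value in roughly 89–91% of replicates instead of 95%,
while $Q$ and $R_c$ are unaffected. This is the price of forcing a
physically valid table out of an unconstrained normal observation model —
the real measurement process (concentric annuli) satisfies the ordering by
construction and is therefore not exactly multivariate normal either. The
coverage assertions in the acceptance tests record where the empirical
rates land rather than hiding the effect.

## Worked example

```{r example, eval = FALSE}
cohort <- generate_cohort(cohort_config(observation_days = c(14, 18, 21),
                                        n_per_condition = 10, seed = 1))
report <- run_pipeline(cohort,
                       analysis_config(model = "steady_state", days = 21))
report$fits          # per-density estimates with profile CIs
report$lrt_pairwise  # equivalence tests between densities
```

## Numerical conventions

All lengths are µm, all times days; no unit-conversion layer exists.
Cubic roots: closed form + Newton polish (exact bracket proofs above);
$\rho$ root: pre-scan + `uniroot` at $10^{-12}$; ODE: `lsoda` at
$10^{-8}$; nuisance optimisation: Nelder–Mead, relative tolerance
$10^{-10}$, warm-started; CI bisection: $10^{-4}$ of a standard error;
region tracing: adaptive arc-length with Newton re-projection each step,
drift $< 10^{-6}$ over the boundary. Degenerate inputs (no phase-3 steady
state, $\eta = 0$ inversions, isotropic whitened TLS data, singular
covariances) raise informative errors rather than returning silently
wrong numbers.
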
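---
title: "Morphoelastic models of tumour spheroid growth: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphoelastic models of tumour spheroid growth: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphospheroid)
```

## The model family

`morphospheroid` simulates an avascular tumour spheroid as a spherically
symmetric morphoelastic solid. The deformation gradient decomposes
multiplicatively into growth and elastic parts, $F = A G$, with isotropic
growth stretch $\gamma(R, t)$ ($\gamma_r = \gamma_\theta = \gamma$) and
incompressible elasticity ($\det A = 1$). Under these assumptions the
current radius of the material point with Lagrangian label $R \in [0, B]$
follows from the growth field alone,
$$ r(R, t)^3 = 3 \int_0^R \gamma^3 \tilde{R}^2 \, d\tilde{R}, $$
and the circumferential elastic stretch is $\alpha = r / (R\gamma)$.

The tissue is neo-Hookean with shear modulus $\mu$. Momentum balance
reduces to a single quasistatic ODE for the radial Cauchy stress,
$$ \frac{\partial \sigma_r}{\partial R}
   = 2\mu\gamma\,\frac{r^6 - \gamma^6 R^6}{r^7}, $$
integrated inwards from the boundary condition
$\sigma_r(B, t) = -\kappa\,(b - B)/B$, where $b = r(B,t)$ is the outer
radius and $\kappa \ge 0$ is the stiffness of the surrounding medium
($\kappa = 0$ is free suspension). The hoop stress follows algebraically,
$\sigma_\theta = \sigma_r + \mu(\alpha^2 - \alpha^{-4})$. Residual
stresses use the same ODE with a traction-free boundary,
$\sigma_r^R(B) = 0$.

A single diffusing nutrient (interpreted as oxygen) with surface
concentration $c_\infty$, constant consumption $\lambda$ and diffusivity
$D$ is quasistatic relative to growth, giving the parabolic profile
$c(r) = \lambda (r^2 - b^2)/(6D) + c_\infty$. This sets the natural
scales $L = \sqrt{D c_\infty / \lambda}$ and $T = 1/(k c_\infty)$; all
internal computation is dimensionless (lengths $/L$, times $/T$, stresses
$/\mu$, concentrations $/c_\infty$), matching how the parameter fixtures
are stated, and dimensional quantities are converted only at the
interface.

Five growth laws close the system through
$\gamma^{-1}\,\partial\gamma/\partial t = k f(\sigma, c)$:

| law | $f$ | character |
|-----|-----|-----------|
| M1 | $c - \hat{c}$ | nutrient-limited (Greenspan-like), necrotic decay |
| M2 | $n(\sigma_r)(c - \hat{c})$ above threshold; decay unmodified below | local stress arrest |
| M3 | as M2 outside the necrotic front $R_N$; zero inside; never negative | permanent necrosis |
| M4 | $n$ of the global measure $\min_R\{\sigma_r, \sigma_\theta\}$ | non-local arrest, guaranteed steady state for $\kappa > 0$ |
| M5 | M4 times a local factor $\tilde{n} = n(\beta\sigma_r)$ | adds tensile boundary residual hoop stress |

where $n$ is the piecewise-linear arrest ramp: $0$ below $\hat\sigma \le 0$,
$1 - s/\hat\sigma$ on $[\hat\sigma, 0)$, $1$ for $s \ge 0$. The necrotic
front $R_N(t)$ is the running maximum of the Lagrangian preimage of the
radius where $c = \hat{c}$ — necrosis is permanent in M3–M5.

## Parameters

All parameters carry documented units but no unit inference. The
dimensionless set that fully determines the dynamics is
$\hat{c}/c_\infty \in (0,1)$, $\kappa/\mu \ge 0$, $\hat\sigma/\mu \le 0$,
$\beta > 0$ (M5 only), and $B/L > 0$. Six named fixtures
(`figure_params()`) span the hierarchy's behaviours: nutrient-limited
saturation (`fig3`), local stress limitation with runaway interior stress
(`fig5_text` / `fig5_caption`), stress-driven arrest with persistent
necrosis (`fig6`), unbounded evolution under a local law (`fig7`), and
combined local/non-local response with tensile boundary residual stress
(`fig9`). Two values of $\kappa/\mu$ (100 and 316.2) circulate for the
stress-limited illustration; both fixtures are kept and neither is
asserted against a published curve.

## Numerical scheme

**Time stepping.** Classical four-stage Runge–Kutta on $\ln\gamma$
(positivity by construction), fixed step $\Delta t = T/200$ by default,
with the quasistatic fields ($r$, $c$, $\sigma$) recomputed at every
stage. The necrotic front is frozen during a step and updated afterwards.
Stiffness is mild — rates are bounded by $k c_\infty$ — and the
closed-form nutrient-only solution pins the accuracy.

**The graded Lagrangian grid.** This is the one place where the design
departed from the obvious choice, and it matters. Under sustained growth
the proliferating rim is a fixed Eulerian shell but an exponentially
thinning Lagrangian layer: material points continually leave the rim and
drift toward the core, while $\gamma(B,t) \sim e^{k(c_\infty-\hat{c})t}$
concentrates all new volume near $R = B$. On a uniform 400-node grid the
nutrient-only benchmark (fig3 parameters, $t/T = 30$) fails
catastrophically ($b \to 62L$ instead of $\sqrt{3}L$) once the layer
drops below one grid spacing. The default grid is therefore geometrically
refined toward $R = B$, with spacing proportional to the distance from
the boundary down to a floor of $10^{-10}B$. A geometric mesh is
scale-invariant, so it resolves the self-similar layer at *every* time
for which the layer is wider than the floor; with the default 400
intervals about half sit in the graded region and the benchmark is met at
$3 \times 10^{-4}$ relative error. A warning fires if $\gamma$ ever jumps
by more than a factor 3 across the outermost interval (the layer
outrunning the floor). Uniform grids remain available
(`spheroid_grid(..., grading = "uniform")`).

**Quadrature.** The radius map integrates $\gamma^3 R^2$ by *product
quadrature*: $\gamma^3$ is taken piecewise linear and the $R^2$ weight is
integrated exactly, in a cancellation-safe local form. Plain trapezoid on
the product has an $O(1)$ relative error on the first interval off the
origin ($h^3/2$ versus the exact $h^3/3$), which leaks a spurious radial
stress of order $0.3\mu$ into the core — harmless when
$|\hat\sigma|/\mu = 100$, but enough to falsely arrest the entire
spheroid in the `fig9` regime ($\hat\sigma/\mu = -1$, $\beta = 6.25$).
Product integration is exact for spatially constant $\gamma$, origin
included. The inward stress integration keeps the trapezoid rule: its
integrand has a removable zero at the centre
(numerator $O(R^8)$ against denominator $O(R^7)$ when $\gamma'(0) = 0$)
and is set to its limit there. The hoop stress is always evaluated
through the algebraic identity, never by differentiating the quadrature
result; the derivative form is retained as a cross-check in the tests.

**Termination.** Steady state is declared on the outer radius only
(relative change below $10^{-8}$ per $T$ over 10 consecutive steps),
since the nutrient-only law has a steady $b$ with vigorous interior
turnover; a separate `quiescent` flag requires all nodal rates to be
below tolerance. The unbounded-growth regime of M1/M2 is a model finding,
not a failure: the run halts cleanly with status
`unbounded_growth_stretch` when $\gamma$ exceeds $10^{12}$.

**Degenerate inputs.** $\hat\sigma = 0$ uses the pointwise limit of the
arrest ramp (indicator of non-negative stress). Concentrations are *not*
clipped when the spheroid exceeds the depletion radius $\sqrt{6}L$ — the
parabolic profile is returned unmodified with a warning, faithful to the
model's stated simplification, and `strict = TRUE` upgrades the warning
to an error. Sub-threshold nutrient at the node straddling the necrotic
front can be marginally negative by discretisation; M3–M5 rates are
clamped at zero there to preserve the non-negativity theorem at finite
resolution.

## Closed-form results used as oracles

For the nutrient-only law the outer radius obeys
$db/dt = k b\,[-\lambda b^2/(15D) + c_\infty - \hat{c}]$, with explicit
logistic-like solution (`closed_form_radius()`), unstable zero state and
stable nonzero state $b_N^* = \sqrt{15(c_\infty - \hat{c})/c_\infty}\,L$.
The steady necrotic radius is $3\sqrt{(c_\infty - \hat{c})/c_\infty}\,L$,
so the necrotic-to-outer ratio is $3/\sqrt{15}$ and the necrotic volume
fraction $(3/\sqrt{15})^3 \approx 46\%$ *independently of all
parameters*. At the steady radius the boundary material keeps growing
exponentially and its elastic stretch collapses, so the boundary hoop
stress magnitude grows like $e^{4k(c_\infty - \hat{c})t}$ — the
$\alpha^{-4}$ term of the neo-Hookean response dominates. The prefactor
constants of that asymptotic are not exposed, only the rate
(`boundary_stress_rate()`); the derivation is recorded in that
function's documentation so it can be audited. For M4/M5 with
$\kappa > 0$ the radius is bounded by $B(1 - \hat\sigma/\kappa)$, the
radius at which the boundary condition delivers the arrest threshold.

Whether loaded or residual stresses enter the non-local measure is a
genuine ambiguity; the package uses the *loaded* stresses, since they are
the stress state the growth law responds to, and computes residual
profiles as a separate diagnostic.

## Fitting and synthetic data

The fitting layer emulates multi-condition spheroid-compression
experiments: all biological and mechanical parameters are shared across
growth curves, and only the initial radius $B$ and stiffness $\kappa$
vary between conditions, with free-suspension curves pinning
$\kappa = 0$. The objective is an unweighted least-squares residual on
the radius (volume-based and relative variants are available), model
time zero aligned to each dataset's first observation. The optimiser is
Nelder–Mead on a logistic transform of each parameter to its bounds,
restarted from a Latin-hypercube design; when all free parameters are
per-dataset the objective separates and each dataset is fitted
independently. Fits are deterministic given the seed, and every start is
logged.

The synthetic generator produces the stated world the recovery tests
live in: one free-suspension condition plus embedded conditions of
increasing stiffness ($\kappa/\mu \in \{0, 0.1, 0.3, 1\}$ by default),
sharing the combined-law biology ($\hat{c}/c_\infty = 1/4$,
$\hat\sigma/\mu = -1$, $\beta = 6.25$ — the parameter regime that
produces realistic residual-stress profiles), initial radius $B = L/2$,
observations at unit intervals of $T$ over $[0, 20]$, and additive
Gaussian radius noise with standard deviation $0.02\,L$ (about 2% of a
typical radius, comparable to digitisation error of published growth
curves). The generator samples the simulator itself, so recovery tests
establish identifiability of the inference machinery under the model's
own dynamics — they say nothing about model misspecification, biological
variability, or measurement error structure in real data. The classical
gel-compression radii that motivate this layer are not redistributed
here (they were never printed as numbers); the CSV loader accepts any
two-column (time, radius-or-diameter) file with unit scaling.

Discretisation bias cancels in recovery studies only if the generator
and the objective use the same simulator controls; `fit_spec()` and
`synthesize_growth_data()` therefore expose `dt` and `n` and default to
a coarser, affordable pair (`dt = 0.05`, `n = 80`).

## What the tests establish, and limits

The test suite verifies: exactness on homogeneous growth; agreement of
the radius map and stress integration with independent high-resolution
quadrature; the algebraic-versus-derivative hoop consistency; the
monotone-growth theorems (non-decreasing $\gamma$ implies $\alpha \le 1$,
decreasing residual radial stress, non-tensile boundary residual hoop);
the vanishing volume integral of the residual stress trace; the
closed-form nutrient-only trajectory across a parameter grid; the
exponential boundary-stress rate; monotonicity and boundedness of the
robust laws; the tensile-boundary residual profile of the combined law;
and parameter recovery on synthetic data.

Known limitations: strictly spherical symmetry (no shedding or
symmetry-breaking instabilities, which the unbounded-stress regime hints
at); single-phase incompressible solid (no poroelasticity or material
clearance); quasistatic nutrient with constant consumption and no
quiescence threshold; the piecewise-linear arrest ramp is one convenient
choice among many; and the fitting layer offers multistart spread, not
uncertainty quantification.
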
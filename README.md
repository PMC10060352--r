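# morphospheroid

Simulation and analysis of avascular tumour spheroid growth as a
morphoelastic solid, for mathematical oncologists and continuum
biomechanicists who want a small, rigorously tested sandbox for
stress-regulated growth laws.

A spheroid is modelled in strict spherical symmetry with the
multiplicative decomposition `F = A G` of the deformation gradient into
elastic and growth parts. With isotropic growth stretch γ(R, t) and
incompressible neo-Hookean elasticity (shear modulus μ), the governing
system is

    r² ∂r/∂R           = γ³ R²                            (kinematics)
    ∂σ_r/∂R            = 2 μ γ (r⁶ − γ⁶R⁶) / r⁷           (radial stress)
    σ_θ                = σ_r + μ (α² − α⁻⁴),  α = r/(Rγ)  (hoop stress)
    c(r)               = λ (r² − b²) / (6D) + c∞          (nutrient)
    (1/γ) ∂γ/∂t        = k f(σ, c)                        (growth law)

with the compressive boundary condition `σ_r(B, t) = −κ (b − B)/B`
modelling an embedding medium of stiffness κ (κ = 0 is free suspension).
Five growth laws `f` of increasing sophistication are provided:

- **M1** — nutrient-limited growth and necrotic decay, `f = c − ĉ`
  (Greenspan-like; admits a full closed-form outer-radius solution but
  accumulates unbounded solid stress);
- **M2** — local radial-stress arrest through a piecewise-linear ramp
  `n(σ_r)` with threshold σ̂ ≤ 0;
- **M3** — as M2 with *permanent* necrosis (non-decreasing Lagrangian
  front R_N, non-negative growth everywhere);
- **M4** — arrest by the non-local measure `min over R of {σ_r, σ_θ}`,
  which guarantees a steady state whenever κ > 0, with radius bound
  `b ≤ B (1 − σ̂/κ)`;
- **M5** — M4 times a local factor `n(β σ_r)`, which can produce the
  experimentally observed residual-stress signature: tensile hoop stress
  at the surface, compressive inside.

Also included: residual-stress profiles (traction-free unloading),
closed-form steady-state geometry and boundary-stress asymptotics for
M1, a multi-condition growth-curve fitting layer (shared biology, only
initial radius B and stiffness κ vary between conditions), a synthetic
multi-condition data generator for parameter-recovery studies, and a
small CLI (`inst/cli/morphospheroid`).

## Worked example

Nutrient-limited growth (law M1) at the classic benchmark parameters
ĉ/c∞ = 4/5 with initial radius B = L (the diffusive lengthscale
`L = sqrt(D c∞ / λ)`):

```r
library(morphospheroid)
params <- figure_params("fig3")
traj <- simulate_spheroid(params, "M1", t_end = 30)
traj
#> <spheroid_trajectory> law M1, 6000 steps, t in [0, 30] T
#>   b/L: 1 -> 1.73282; status: completed
steady_state_radius(params)
#> <steady_state_summary>
#>   b* = 1.73205 (stable); b = 0 unstable
#>   necrotic radius = 1.34164 (ratio 0.774597, volume fraction 0.4648)
```

The simulated outer radius lands on the analytic steady state
`b* = sqrt(3) L ≈ 1.73205` to three decimal places. The steady spheroid
carries a necrotic core out to `r = 1.34164 L`; the necrotic-to-outer
ratio `3/sqrt(15) ≈ 0.7746` — and hence the roughly 46% necrotic volume
fraction — is independent of every model parameter. Despite the steady
radius, interior material turns over continuously
(`material_paths(traj, 0.5)` shows interior points drifting into the
core) and the boundary hoop stress grows exponentially at rate
`4 k (c∞ − ĉ)` (`boundary_stress_history(traj)`,
`boundary_stress_rate(params)`) — the pathology that motivates the
stress-regulated laws M2–M5.

Units: simulations run dimensionless; trajectory times are in units of
`T = 1/(k c∞)`, radii in units of `L`, stresses in units of `μ`.
Dimensional parameter sets (`spheroid_params()`) are converted at the
interface and carry their scales.

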
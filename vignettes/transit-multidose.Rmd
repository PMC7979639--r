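---
title: "Exact multi-dose transit-compartment kinetics and dosing regimen regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact multi-dose transit-compartment kinetics and dosing regimen regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transitpk)
```

## The models

All models in this package are linear compartment cascades ending in a
central (systemic circulation) compartment whose drug *amount* `a_c(t)` (mg)
is the output of interest; for a known central volume `V` the concentration
is `a_c / V`, and we leave that division to the caller throughout.

* **M1** (one-compartment IV): the dose appears directly in the central
  compartment; elimination is first-order with rate `k_e` (1/h).
* **M2** (two-compartment oral): the dose enters an absorption compartment
  (amount `a_b`, e.g. the GI tract) and transfers to the central compartment
  at rate `k_a`.
* **Mt** (transit-compartment): a cascade of `n` identical compartments
  with transfer rate `k` precedes the absorption compartment, producing a
  gamma-shaped "smoothed delay" with mean transit time `MTT = n/k`. This is
  the linear chain trick: as `n` grows at fixed `MTT` the cascade
  approaches a pure time lag of length `MTT`.

Bioavailability `F` is applied at the entry point: the first compartment
receives the effective dose `F × dose`. Dosing regimens are equi-dosing
patterns: a single bolus (`B1`), `M` boluses `D0` every `T` hours (`Beq`),
the same with a loading first dose `D_L ≥ D0` (`BeqL`), a single constant
infusion (`Iinf`), and repeated infusions at rate `k_in`, on for `t_f` and
off for `T − t_f` (`Ieq`).

## Exact solutions

For M1 and M2 the package implements the classical superposition solutions,
their collapsed per-interval geometric forms (O(1) in the dose count `M`),
and their T-periodic steady states. Both code paths are retained and
cross-checked against each other; the collapsed forms are the ones used for
large-`M` work because they avoid O(M) summation and the associated
rounding accumulation.

For Mt, every compartment has an exact multi-dose solution. The building
block is the scaled lower-incomplete-gamma kernel

$$P(m, a, \tau) \;=\; \frac{1}{(m-1)!}\int_0^{\tau} s^{m-1} e^{-a s}\,ds
\;=\; \frac{\gamma(m, a\tau)}{a^{m}\,(m-1)!},$$

where `a` is a difference of rate constants (`k − k_a` or `k − k_e`) of
either sign. Written this way the kernel is positive everywhere, while its
conventional factors `γ(m, aτ)` and `a^{-m}/(m-1)!` are separately
astronomical for large `m`. The package therefore never forms those factors:
`incgamma_log_scaled()` returns `log P` directly, using

* the regularised gamma CDF (`pgamma` in log space) for `a > 0`;
* for `a < 0` (which arises whenever the transit rate is smaller than the
  absorption or elimination rate — a regime the closed forms cover but for
  which no evaluation recipe is standard), an everywhere-positive ascending
  series when `|a|τ` is moderate, switching to the exact `n`-term
  integration-by-parts sum when `|a|τ > 2n + 20`, where its alternating
  terms decay by at least a factor 2 and cancellation is bounded.

The branch point matters: the naive truncated-exponential-sum form of
`γ(n, t)` for negative `t` cancels catastrophically (about `e^{|t|}`
amplification), and compensated summation does not rescue it.

### Steady state

Under equi-bolus dosing the system approaches a T-periodic steady state.
Its per-compartment interval-initial values are computed from
`φ = kT` and `β = e^{-φ}/(1-e^{-φ})` by a forward recurrence (the default:
all terms positive, numerically benign) or by a closed form in Stirling
numbers of the second kind `S(i, p)`. The closed form mixes
combinatorially large `S` with powers of `β` and loses floating-point
accuracy for large `n`, so it serves as a cross-validation path rather than
the default. `S(n, q)` itself is computed exactly in a small
arbitrary-precision integer routine (base-1e7 limbs, recurrence
`S(n,q) = q·S(n-1,q) + S(n-1,q-1)`, additions and small scalar products
only), converting to double only on return; the double-precision
alternating-sum formula is used as an independent oracle in the tests where
it is itself exact.

Two structural checks pin the steady state down: propagating the profile to
the end of the interval and applying one dose must reproduce the initial
values (only the first transit compartment jumps — the absorption and
central levels are continuous at dose times), and first-order elimination
must balance the input over one period, `k_e \int_0^T a_c^\infty = F D_0`.
Both are asserted in the test suite, alongside agreement of the steady
profile with the 300-dose transient to a relative sup-norm of 1e-6.

### Conventions and numerical choices

* **Heaviside at zero**: `H(0) = 1`, so a value sampled exactly at a dose
  time is the post-dose value (this makes `a_c(0) = F D_0` for an IV bolus).
  To record a jump, duplicate the abscissa: the first of the pair is the
  pre-dose left limit.
* **Rate coincidence**: the closed forms have `(k−k_a)`, `(k−k_e)`,
  `(k_a−k_e)` denominators. Rather than substituting algebraic limit forms,
  parameter sets with any pair of rates closer than a relative `1e-6` are
  rejected with a dedicated error; the tolerance is configurable. The
  ordering `k_a < k_e` is unusual but the formulas remain valid, so it is
  accepted with a flip-flop warning rather than refused.
* **Units** are fixed: mg, h, mg/h. No unit-conversion layer.
* `expm1` is used for every `1 − e^{-x}` to keep small-`x` accuracy.
* An infinite dose count `M` is a marker meaning "ask the steady-state
  evaluator"; it is rejected by the finite-sum transient solvers.

## The approximate baseline

The historical single-dose treatment of the transit model couples the exact
`n`-th transit compartment outflow to the absorption/central pair after
replacing `(n−1)!` with its Stirling approximation
`√(2π)(n−1)^{n−1/2}e^{−(n−1)}`. The package integrates that system
numerically (`lsoda`, `rtol = atol = 1e-10`, so the approximation error
dominates solver error by several orders of magnitude); there is no closed
form. `n = 1` is degenerate — the Stirling factor vanishes — and raises an
error; comparison tables flag it and report its columns as `NA`.

`compare_exact_approx()` reports, per `n` at fixed `MTT`: RMSE of the
central level over a dense shared grid, the percent relative error of the
peak (peaks located by a dense grid with `dt = MTT/2000` plus local
parabolic refinement, the same procedure for both curves so the comparison
is procedure-consistent), and the raw Stirling relative error of `n!`. For
the glibenclamide-like setting (`k_a = 9.11`, `k_e = 0.96`/h, `F = 0.69`,
`D0 = 3.5` mg, `MTT = 0.78` h) the peak error is within a factor
`1/Stirling(n−1)!` of the exact peak, decreasing monotonically in `n`.

## Fitting and identifiability

`fit_tcm()` minimises the sum of squared errors between the exact central
solution and `(t, amount)` observations over `(k, k_a, k_e, F)` for each
candidate `n`, then selects the `n` with minimal SSE. Design choices:

* **Transformed coordinates**: rates in log space, `F` in logit space, so
  positivity and `F ≤ 1` hold by construction with no penalty terms.
* **Multi-start**: a derivative-free Nelder-Mead run (cap 1000 iterations)
  from a data-driven heuristic start (terminal slope for `k_e`, observed
  peak time for `k`), plus seeded random perturbations (8 starts by
  default), each followed by a BFGS polish. A single long run is
  start-sensitive on these 4-parameter surfaces; the optimiser's iteration
  cap and convergence tolerance are both exposed.
* Near-coincident rates inside the optimiser are penalised (large SSE)
  rather than raised, so trajectories can cross the singular manifolds.

For `n = 1` the transit and absorption rates are not separately
identifiable: the central inflow is symmetric under swapping `k` and `k_a`
(the flip-flop phenomenon), which `flip_flop_demo()` demonstrates exactly;
for `n ≥ 2` the symmetry is broken. The default sweep therefore starts at
`n = 2` and `n = 1` triggers a warning.

SSE is computed on amounts (mg); concentration data should be converted by
the caller with their volume of distribution.

## Synthetic observations

`simulate_pk_observations()` generates single-dose central-compartment
observations from the exact solution at the glibenclamide-like setting
(`k = 12.76`, `k_a = 9.11`, `k_e = 0.96`/h, `F = 0.69`, `n = 10`, 3.5 mg),
with multiplicative lognormal noise, mean-corrected
(`σ² = log(1 + CV²)`, factor `e^{σZ − σ²/2}`) so the expected observation
equals the true curve and amounts stay positive; the default CV is 5%.
The 12 sample times (dense over the absorption phase, sparser in the
elimination tail, 0.25–8 h) are a fixture convention chosen to resemble
typical single-dose PK sampling — the original experiment's times are not
public, so no digitised data ships with the package. What these fixtures
can show is that the estimation machinery recovers known parameters from
data generated by the model family itself (and that the lag model fits
transit-generated data worse); they cannot show model adequacy for real
absorption processes, inter-individual variability, or assay error
structure.

## Equi-dosing regimen regions

Given a therapeutic range `(D_me, D_MS)`, a regimen is acceptable when the
steady-state trajectory lies inside the range. Because every steady
solution here is linear in the dose, the acceptable set at each interval
`T` is a band `f_lo(T) < D_0 < f_hi(T)`:

* **M1 bolus**: `f_lo = (D_me/F)(e^{k_e T}−1)`,
  `f_hi = (D_MS/F)(1−e^{−k_e T})`; the petal closes at
  `T* = log(D_MS/D_me)/k_e`, `D_0* = (D_MS−D_me)/F`.
* **M2 bolus**: closed forms from the steady trough (interval start) and
  interior peak; the crossover is found by root-finding (`f_hi` is
  evaluated in log space — the direct power form underflows for small `T`
  when `k_a ≫ k_e`).
* **Loading dose (3-D)**: the steady petal intersected with the
  first-interval requirement `D_me e^{k_e T} < F D_L < D_MS` ("therapeutic
  immediately and always"); for M1 the interval peaks and troughs are
  monotone in time, so first interval + steady state suffice — asserted on
  dense transient grids in the tests rather than assumed.
* **Repeated infusion (3-D)**: per-`t_f` chopped petals in `(T, k_in)`,
  bounded by `T = t_f` and `T = t_f + log(D_MS/D_me)/k_e`.
* **Transit model**: no closed-form extrema exist, so `edrr_numerical()`
  computes steady extrema numerically. The default exploits dose
  linearity — `f_lo(T) = D_me/u_min(T)`, `f_hi(T) = D_MS/u_max(T)` with
  `u` the unit-dose steady profile — which is exact to evaluator precision;
  the literal dose-grid scan is retained as an alternative and agrees to
  within one grid step. Steady extrema are located on a 2000-point grid per
  period with golden-section refinement, searching both the interior and
  the interval endpoints (the transit-model trough need not sit exactly at
  the interval start).

Default grids (400 points in `T` over twice the closing interval) are
package choices, configurable per call. Three-parameter regions are stored
as slice stacks (long-format tibbles), not meshes.

A structural property worth knowing: because the transit cascade narrows
the steady-state fluctuation band relative to both the no-delay and
pure-lag models, transit-model EDRRs always contain the plain oral-dosing
EDRR — fitting a lag model to single-dose data and using it for regimen
design overestimates fluctuation and is conservative.

## Problem sizes and limitations

The shipped tests exercise cascades up to `n = 100`, dose counts up to
`M = 500` (via the collapsed forms; superposition sums are used to
`M = 300`), 30 randomized parameter draws against an adaptive ODE oracle at
1e-6 relative sup-norm, and EDRR grids of 60–400 intervals; these sizes
were chosen so the full suite completes in a few minutes while covering
both signs of every rate difference.

Out of scope by design: peripheral distribution compartments,
Michaelis-Menten elimination, time-varying (chrono-) parameters,
concentration/volume handling, population-level (NLME) estimation, and
formal structural identifiability analysis beyond the flip-flop
demonstration.
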
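# transitpk

Exact multi-dose solutions and equi-dosing regimen regions for transit
compartment pharmacokinetic (PK) models.

## The problem

Linear compartment models are the workhorse of pharmacokinetics: a drug is
administered, moves through one or more compartments by first-order
transfer, and is eliminated from the central (systemic circulation)
compartment at rate `k_e`. One- and two-compartment models have well-known
closed-form drug-level solutions under repeated dosing, but they cannot
represent the gradual absorption delay seen in many oral time courses. The
standard semi-mechanistic remedy is a *transit compartment cascade*: `n`
identical compartments with transfer rate `k` (mean transit time
`MTT = n/k`) feeding an absorption compartment (rate `k_a`) and then the
central compartment. Until recently only the transit compartments
themselves had exact multi-dose solutions; the absorption and central
levels were obtained approximately (via the Stirling approximation of the
factorial) or purely numerically.

`transitpk` implements the exact solutions for **all** `n + 2` compartments
under `M` repeated bolus doses `D0` given every `T` hours, e.g. the central
drug level

```
a_c(t) = (F D0 k^n k_a) / ((n-1)! (k_e - k_a)) *
         sum_j H(t_j) { e^{-k_a t_j} γ(n, (k-k_a) t_j) / (k-k_a)^n
                      - e^{-k_e t_j} γ(n, (k-k_e) t_j) / (k-k_e)^n },
```

with `t_j = t - (j-1)T` the time since dose `j` and `γ` the lower incomplete
gamma function — evaluated here in sign-managed log space so that the
individually astronomical factors never overflow, for **either** ordering of
`k` versus `k_a`/`k_e` (negative gamma arguments included). The T-periodic
steady state is available in closed form too, from interval-initial values
computed by a recurrence in `φ = kT` (or, equivalently, a closed form
involving Stirling numbers of the second kind, computed exactly in
arbitrary-precision integer arithmetic).

On top of the solvers the package provides:

* classical one-/two-compartment solutions (bolus, loading dose, repeated
  infusion), the continuous-infusion limit and pure time-lag references;
* the historical Stirling-approximation model and an exact-vs-approximate
  error study;
* least-squares fitting of `(k, k_a, k_e, F)` with a sweep over the discrete
  `n`, plus flip-flop identifiability diagnostics;
* synthetic observation generators for testing estimation workflows;
* **equi-dosing regimen regions (EDRRs)**: given a therapeutic range
  `D_me < a_c < D_MS`, the petal-shaped set of `(T, D0)` (or
  `(T, D0, D_L)`, `(T, k_in, t_f)`) values whose steady-state trajectory
  stays inside the range — analytically for the classical models,
  numerically for the transit model.

All user-facing functions take and return tidy data frames; results come
with `autoplot()` methods, and fits with `tidy()`/`glance()`.

## Worked example

A 10-compartment transit cascade with `MTT = 3` h, `k_a = 0.7` /h,
`k_e = 0.0692` /h, dosed with 500 mg every 8 h:

```r
library(transitpk)

p <- pk_params("Mt", k_e = 0.0692, k_a = 0.7, k = 10/3, n = 10)
r <- pk_regimen("Beq", D0 = 500, T = 8, M = 6)

simulate_timecourse(p, r, times = seq(0, 48, by = 8)) |>
  dplyr::filter(compartment == "central")
#>       t compartment amount
#> 1     0 central         0
#> 2     8 central       372.
#> 3    16 central       598.
#> 4    24 central       728.
#> 5    32 central       803.
#> 6    40 central       846.
#> 7    48 central       870.
```

The trough climbs towards its periodic steady state, which is available
directly (no long simulation needed):

```r
steady_extrema(p, pk_regimen("Beq", D0 = 500, T = 8))
#>   a_min t_peak a_max
#> 1  812.   5.60  979.
```

At steady state the level oscillates between 812 and 979 mg, peaking 5.6 h
after each dose. Against a therapeutic range of 300–1000 mg this regimen is
therefore acceptable:

```r
rng <- therapeutic_range(300, 1000)
classify_regimen(p, pk_regimen("Beq", D0 = 500, T = 8), rng)
#>   verdict    a_min a_max  D_me  D_MS
#> 1 acceptable  812.  979.   300  1000
```

The full region of acceptable `(T, D0)` regimens:

```r
edrr <- edrr_numerical(p, rng, T_grid = seq(2, 20, by = 2))
edrr
#>     T   f_lo  f_hi
#> 1   2  41.54 138.3
#> 2   4  84.17 273.3
#> ...
#> 10 20 721.09 959.7
autoplot(edrr)
```

Any dose between `f_lo(T)` and `f_hi(T)` keeps the steady-state trajectory
inside the range; e.g. at `T = 8` h any dose between 185 and 511 mg works.
The petal closes where `f_lo = f_hi`.

## Command-line use

A thin wrapper over the package functions lives at
`inst/cli/transitpk.R` with subcommands `simulate`, `steady`, `edrr`,
`fit` and `fixtures`; see the header of that file for usage.
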
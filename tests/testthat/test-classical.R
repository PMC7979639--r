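# One- and two-compartment closed forms: transient, per-interval, steady
# state, infusion, lag-time reference; checked against the ODE oracle and
# internal identities.

p_m1 <- pk_params("M1", k_e = 0.0692, F = 1)
p_m2 <- pk_params("M2", k_e = 0.0692, k_a = 0.7, F = 1)

test_that("M1 equi-bolus: anchors, single-dose reduction, ODE match", {
  r <- pk_regimen("Beq", D0 = 500, T = 12, M = 6)
  tt <- seq(0, 72, by = 0.5)
  tc <- simulate_timecourse(p_m1, r, tt)
  expect_equal(tc$amount[tc$t == 0], 500)
  # M = 1 reduces to a single exponential decay
  tc1 <- simulate_timecourse(p_m1, pk_regimen("Beq", D0 = 500, T = 12, M = 1),
                             tt)
  expect_equal(tc1$amount, 500 * exp(-0.0692 * tt), tolerance = 1e-14)
  # transient vs ODE with impulse restarts
  oracle <- ode_central(p_m1, r, tt)
  expect_lt(max(abs(tc$amount - oracle)) / max(oracle), 1e-8)
})

test_that("M1 steady-state interval start matches a 500-dose ODE run", {
  r500 <- pk_regimen("Beq", D0 = 500, T = 12, M = 500)
  ss <- steady_state(p_m1, pk_regimen("Beq", D0 = 500, T = 12))
  oracle <- ode_central(p_m1, r500, 499 * 12)
  expect_equal(ss$initial_values[["central"]], oracle, tolerance = 1e-6)
})

test_that("M1 loading dose: zero correction, t = 0 anchor, ODE match", {
  rL <- pk_regimen("BeqL", D0 = 500, D_L = 800, T = 12, M = 6)
  tt <- seq(0, 60, by = 0.5)
  tc <- simulate_timecourse(p_m1, rL, tt)
  expect_equal(tc$amount[tc$t == 0], 800) # F * D_L
  # D_L = D0 is identical to plain equi-bolus
  r0 <- pk_regimen("BeqL", D0 = 500, D_L = 500, T = 12, M = 6)
  expect_equal(simulate_timecourse(p_m1, r0, tt)$amount,
               simulate_timecourse(p_m1, pk_regimen("Beq", D0 = 500, T = 12,
                                                    M = 6), tt)$amount,
               tolerance = 1e-14)
  oracle <- ode_central(p_m1, rL, 30)
  expect_equal(tc$amount[tc$t == 30], oracle, tolerance = 1e-8)
})

test_that("M1 equi-infusion: continuity, ODE match, period average", {
  r <- pk_regimen("Ieq", k_in = 41.67, t_f = 3, T = 6, M = 20)
  tt <- seq(0, 110, by = 0.25)
  tc <- simulate_timecourse(p_m1, r, tt)
  oracle <- ode_central(p_m1, r, tt)
  expect_lt(max(abs(tc$amount - oracle)) / max(oracle), 1e-8)
  # continuity at switch times jT and jT + t_f
  for (t0 in c(6, 9, 12, 15)) {
    eps <- 1e-7
    v <- simulate_timecourse(p_m1, r, c(t0 - eps, t0, t0 + eps))$amount
    expect_lt(max(abs(diff(v))), 1e-3)
  }
  # steady-state dosing-interval average equals F k_in t_f / (k_e T)
  ss <- steady_state(p_m1, pk_regimen("Ieq", k_in = 41.67, t_f = 3, T = 6))
  avg <- integrate(ss$central, 0, 6, rel.tol = 1e-11)$value / 6
  expect_equal(avg, 41.67 * 3 / (0.0692 * 6), tolerance = 1e-9)
})

test_that("M2 equi-bolus: initial condition, single-dose shape, ODE match", {
  r1 <- pk_regimen("Beq", D0 = 500, T = 12, M = 1)
  tt <- seq(0, 48, by = 0.1)
  tc <- simulate_timecourse(p_m2, r1, tt)
  ac <- tc$amount[tc$compartment == "central"]
  ab <- tc$amount[tc$compartment == "absorption"]
  expect_equal(ac[1], 0)
  expect_equal(ab[1], 500) # a_b(0) = F D0
  expect_true(all(ac >= 0))
  # single interior maximum
  expect_equal(sum(diff(sign(diff(ac))) != 0), 1)
  expect_equal(ac[tt == 5], as.numeric(ode_pk(p_m2, r1, 5)[, "central"]),
               tolerance = 1e-8)
})

test_that("M2 loading dose matches the ODE oracle and converges to steady state", {
  rL <- pk_regimen("BeqL", D0 = 500, D_L = 800, T = 12, M = 6)
  tt <- seq(0, 72, by = 0.5)
  tc <- simulate_timecourse(p_m2, rL, tt)
  ac <- tc$amount[tc$compartment == "central"]
  oracle <- ode_pk(p_m2, rL, tt)[, "central"]
  expect_lt(max(abs(ac - oracle)) / max(oracle), 1e-8)
  # loading-dose transient converges to the plain equi-bolus steady state
  ss <- steady_state(p_m2, pk_regimen("Beq", D0 = 500, T = 12))
  tM <- seq(0, 12, length.out = 60)[-60]
  v400 <- interval_level(p_m2, rL, 400, tM)
  expect_lt(max(abs(v400 - ss$central(tM))) / max(v400), 1e-6)
})

test_that("collapsed per-interval forms equal the superposition sums", {
  tM <- seq(0, 11.99, length.out = 23)
  for (M in c(1, 3, 17)) {
    r <- pk_regimen("Beq", D0 = 500, T = 12, M = M)
    expect_equal(interval_level(p_m1, r, M, tM),
                 simulate_timecourse(p_m1, r, (M - 1) * 12 + tM)$amount,
                 tolerance = 1e-12)
    r2 <- pk_regimen("BeqL", D0 = 500, D_L = 650, T = 12, M = M)
    tc <- simulate_timecourse(p_m2, r2, (M - 1) * 12 + tM)
    expect_equal(interval_level(p_m2, r2, M, tM),
                 tc$amount[tc$compartment == "central"], tolerance = 1e-12)
  }
  rI <- pk_regimen("Ieq", k_in = 41.67, t_f = 3, T = 6, M = 9)
  tM <- seq(0, 5.99, length.out = 17)
  expect_equal(interval_level(p_m1, rI, 9, tM),
               simulate_timecourse(p_m1, rI, 8 * 6 + tM)$amount,
               tolerance = 1e-12)
})

test_that("multi-dose transients are superpositions of shifted single doses", {
  tt <- seq(0, 40, by = 0.37)
  for (p in list(p_m1, p_m2)) {
    r <- pk_regimen("Beq", D0 = 200, T = 7, M = 5)
    tc <- simulate_timecourse(p, r, tt)
    ac <- tc$amount[tc$compartment == "central"]
    single <- function(tau) {
      out <- numeric(length(tau))
      pos <- tau >= 0
      tc1 <- simulate_timecourse(p, pk_regimen("B1", D0 = 200), tau[pos])
      out[pos] <- tc1$amount[tc1$compartment == "central"]
      out
    }
    sup <- Reduce(`+`, lapply(0:4, function(j) single(tt - j * 7)))
    expect_equal(ac, sup, tolerance = 1e-10)
  }
})

test_that("continuous infusion rises monotonically to F k_in / k_e", {
  tt <- seq(0, 200, by = 0.5)
  ci <- continuous_infusion(p_m1, 41.67, tt)
  expect_equal(ci$amount[1], 0)
  expect_true(all(diff(ci$amount) > 0))
  expect_equal(ci$amount[length(tt)], 41.67 / 0.0692, tolerance = 1e-5)
  expect_equal(ci$amount[tt == 12],
               ode_central(p_m1, pk_regimen("Iinf", k_in = 41.67), 12),
               tolerance = 1e-10)
})

test_that("equi-bolus approaches continuous infusion as T shrinks (matched rate)", {
  kin <- 41.67
  tt <- seq(0, 60, by = 0.05)
  inf_curve <- m_inf <- continuous_infusion(p_m1, kin, tt)$amount
  gaps <- sapply(c(1, 0.5, 0.1), function(T) {
    r <- pk_regimen("Beq", D0 = kin * T, T = T, M = ceiling(60 / T) + 1)
    max(abs(simulate_timecourse(p_m1, r, tt)$amount - inf_curve))
  })
  expect_true(all(diff(gaps) < 0))
})

test_that("M1 steady-state dosing-interval average equals F (D0/T) / k_e", {
  ss <- steady_state(p_m1, pk_regimen("Beq", D0 = 500, T = 12))
  avg <- integrate(ss$central, 0, 12, rel.tol = 1e-11)$value / 12
  expect_equal(avg, (500 / 12) / 0.0692, tolerance = 1e-9)
})

test_that("M2 steady extrema match dense sampling of the periodic profile", {
  r <- pk_regimen("Beq", D0 = 500, T = 12)
  ex <- steady_extrema(p_m2, r)
  ss <- steady_state(p_m2, r)
  g <- seq(0, 12, length.out = 1e5 + 1)
  v <- ss$central(g)
  expect_equal(ex$a_max, max(v), tolerance = 1e-8)
  expect_equal(ex$a_min, min(v), tolerance = 1e-8)
  expect_lt(abs(ex$t_peak - g[which.max(v)]), 12 / 1e5 + 1e-9)
  expect_true(ex$t_peak > 0 && ex$t_peak < 12 && ex$a_min < ex$a_max)
  # T -> large: trough -> 0, peak -> single-dose peak
  exL <- steady_extrema(p_m2, pk_regimen("Beq", D0 = 500, T = 400))
  tt <- seq(0, 60, by = 0.001)
  tc1 <- simulate_timecourse(p_m2, pk_regimen("B1", D0 = 500), tt)
  expect_lt(exL$a_min, 1e-6)
  expect_equal(exL$a_max, max(tc1$amount[tc1$compartment == "central"]),
               tolerance = 1e-6)
})

test_that("lag-time profiles are shifted copies of the two-compartment solution", {
  tt <- seq(0, 30, by = 0.1)
  lag0 <- lag_timecourse(p_m2, 500, 0, tt)
  tc1 <- simulate_timecourse(p_m2, pk_regimen("B1", D0 = 500), tt)
  expect_equal(lag0$amount[lag0$compartment == "central"],
               tc1$amount[tc1$compartment == "central"], tolerance = 1e-12)
  lag3 <- lag_timecourse(p_m2, 500, 3, tt)
  lac <- lag3$amount[lag3$compartment == "central"]
  expect_true(all(lac[tt <= 3] == 0))
  v5 <- lac[tt == 5]
  v2 <- tc1$amount[tc1$compartment == "central" & tc1$t == 2]
  expect_equal(v5, v2, tolerance = 1e-12)
})

test_that("returned trajectories are non-negative for all regimens", {
  regs <- list(pk_regimen("Beq", D0 = 500, T = 12, M = 8),
               pk_regimen("BeqL", D0 = 500, D_L = 900, T = 12, M = 8),
               pk_regimen("Ieq", k_in = 41.67, t_f = 3, T = 6, M = 16))
  tt <- seq(0, 96, by = 0.25)
  for (r in regs) {
    expect_true(all(simulate_timecourse(p_m1, r, tt)$amount >= -1e-9))
    if (r$kind != "Ieq") {
      expect_true(all(simulate_timecourse(p_m2, r, tt)$amount >= -1e-9))
    }
  }
})
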
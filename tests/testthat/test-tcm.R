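# Transit-compartment model: exact transient solutions for all n + 2
# compartments, steady-state coefficients and profile, reductions and
# structural properties.

test_that("transit compartment levels: pure exponential, gamma-mode peak, ODE match", {
  p <- fig7a_params()
  r1 <- pk_regimen("B1", D0 = 500)
  tt <- seq(0, 12, by = 0.01)
  tc <- simulate_timecourse(p, r1, tt)
  a1 <- tc$amount[tc$compartment == "transit_1"]
  expect_equal(a1, 500 * exp(-(10 / 3) * tt), tolerance = 1e-12)
  # peak of the last transit compartment at (n-1)/k
  an <- tc$amount[tc$compartment == "transit_10"]
  expect_lt(abs(tt[which.max(an)] - 9 / (10 / 3)), 0.011)
  # stiff cascade (n = 100, MTT = 3 h) against the ODE oracle
  p100 <- pk_params("Mt", k_e = 0.0692, k_a = 0.7, k = 100 / 3, n = 100, F = 1)
  tt2 <- seq(0, 8, by = 0.05)
  oracle <- ode_pk(p100, r1, tt2)
  tc2 <- simulate_timecourse(p100, r1, tt2)
  for (lab in c("transit_100", "absorption", "central")) {
    v <- tc2$amount[tc2$compartment == lab]
    expect_lt(max(abs(v - oracle[, lab])) / max(oracle[, lab]), 1e-6)
  }
})

test_that("absorption level: zero start, flip-flop reduction at n = 1, ODE match", {
  p <- pk_params("Mt", k_e = 0.96, k_a = 9.11, k = 12.76, n = 10, F = 0.69)
  r1 <- pk_regimen("B1", D0 = 3.5)
  tc <- simulate_timecourse(p, r1, c(0, 1))
  ab <- tc$amount[tc$compartment == "absorption"]
  expect_equal(ab[1], 0)
  expect_equal(ab[2], as.numeric(ode_pk(p, r1, 1)[, "absorption"]),
               tolerance = 1e-7)
  # n = 1: a_b reduces to the two-exponential difference form
  p1 <- pk_params("Mt", k_e = 0.1, k_a = 2, k = 5, n = 1, F = 0.8)
  tt <- seq(0, 6, by = 0.05)
  tc1 <- simulate_timecourse(p1, pk_regimen("B1", D0 = 100), tt)
  ab1 <- tc1$amount[tc1$compartment == "absorption"]
  expected <- 0.8 * 100 * 5 / (5 - 2) * (exp(-2 * tt) - exp(-5 * tt))
  expect_equal(ab1, expected, tolerance = 1e-12)
})

test_that("central level: anchors, superposition, multi-dose ODE match", {
  p <- pk_params("Mt", k_e = 0.96, k_a = 9.11, k = 12.76, n = 10, F = 0.69)
  tt <- seq(0, 9, by = 0.03)
  r3 <- pk_regimen("Beq", D0 = 3.5, T = 3, M = 3)
  tc3 <- simulate_timecourse(p, r3, tt)
  ac3 <- tc3$amount[tc3$compartment == "central"]
  expect_equal(ac3[1], 0)
  # equals the sum of three shifted single-dose solutions
  single <- function(tau) {
    out <- numeric(length(tau)); pos <- tau >= 0
    tc1 <- simulate_timecourse(p, pk_regimen("B1", D0 = 3.5), tau[pos])
    out[pos] <- tc1$amount[tc1$compartment == "central"]
    out
  }
  sup <- Reduce(`+`, lapply(0:2, function(j) single(tt - 3 * j)))
  expect_equal(ac3, sup, tolerance = 1e-10)
  # multi-dose equi-bolus against the ODE oracle over six intervals
  p7 <- fig7a_params()
  r6 <- pk_regimen("Beq", D0 = 500, T = 8, M = 6)
  tt6 <- seq(0, 48, by = 0.25)
  oracle <- ode_pk(p7, r6, tt6)[, "central"]
  tc6 <- simulate_timecourse(p7, r6, tt6)
  ac6 <- tc6$amount[tc6$compartment == "central"]
  expect_lt(max(abs(ac6 - oracle)) / max(oracle), 1e-6)
})

test_that("loading-dose extension matches the ODE oracle", {
  p <- fig7a_params()
  rL <- pk_regimen("BeqL", D0 = 500, D_L = 800, T = 8, M = 4)
  tt <- seq(0, 32, by = 0.25)
  oracle <- ode_pk(p, rL, tt)[, "central"]
  tc <- simulate_timecourse(p, rL, tt)
  ac <- tc$amount[tc$compartment == "central"]
  expect_lt(max(abs(ac - oracle)) / max(oracle), 1e-6)
})

test_that("a_b and a_c are continuous at dose times; only a_1 jumps", {
  p <- fig7a_params()
  r <- pk_regimen("Beq", D0 = 500, T = 8, M = 3)
  tt <- c(8, 8, 16, 16) # duplicated abscissae: pre then post
  tc <- simulate_timecourse(p, r, tt)
  for (lab in c("absorption", "central")) {
    v <- tc$amount[tc$compartment == lab]
    expect_equal(v[1], v[2], tolerance = 1e-12)
    expect_equal(v[3], v[4], tolerance = 1e-12)
  }
  a1 <- tc$amount[tc$compartment == "transit_1"]
  expect_equal(a1[2] - a1[1], 500, tolerance = 1e-9)
})

test_that("steady-state initial values: recurrence and Stirling routes agree", {
  # phi = kT = 2 with n = 12
  p <- pk_params("Mt", k_e = 0.05, k_a = 0.4, k = 0.5, n = 12, F = 1)
  c_rec <- ss_initial_values(p, T = 4, D0 = 100, method = "recurrence")
  c_sti <- ss_initial_values(p, T = 4, D0 = 100, method = "stirling")
  expect_equal(c_rec$phi, 2)
  expect_equal(c_sti$a_transit, c_rec$a_transit, tolerance = 1e-10)
  # a_1(0) closed form from both paths
  expect_equal(c_rec$a_transit[1], 100 / (1 - exp(-2)), tolerance = 1e-12)
  expect_equal(c_sti$a_transit[1], 100 / (1 - exp(-2)), tolerance = 1e-12)
  expect_true(all(c_rec$a_transit > 0) && c_rec$a_b0 > 0 && c_rec$a_c0 > 0)
})

test_that("steady-state profile matches the long-run transient and is periodic", {
  p <- fig7a_params()
  ss <- steady_state(p, pk_regimen("Beq", D0 = 500, T = 8))
  tinf <- seq(0, 8, length.out = 81)[-81]
  r300 <- pk_regimen("Beq", D0 = 500, T = 8, M = 300)
  tr <- simulate_timecourse(p, r300, 299 * 8 + tinf)
  ssm <- ss$evaluate(tinf)
  for (lab in c("transit_1", "transit_5", "absorption", "central")) {
    v <- tr$amount[tr$compartment == lab]
    expect_lt(max(abs(ssm[, lab] - v)) / max(abs(v)), 1e-6)
  }
  # periodicity: propagating to T^- and applying the dose returns the
  # interval-initial values (only transit_1 receives the impulse)
  eps <- 1e-9
  end <- ss$evaluate(8 - eps)[1, ]
  start <- ss$initial_values
  expect_equal(end[["transit_1"]] + 500, start[["transit_1"]],
               tolerance = 1e-7)
  for (lab in c("transit_5", "absorption", "central")) {
    expect_equal(end[[lab]], start[[lab]], tolerance = 1e-6)
  }
  expect_equal(as.numeric(ss$evaluate(0)[1, ]), as.numeric(start))
})

test_that("steady state balances mass: elimination per period equals F D0", {
  p <- fig7a_params()
  ss <- steady_state(p, pk_regimen("Beq", D0 = 500, T = 8))
  eliminated <- 0.0692 *
    integrate(ss$central, 0, 8, rel.tol = 1e-10)$value
  expect_equal(eliminated, 500, tolerance = 1e-7)
})

test_that("single-dose peak time of a_c increases with MTT at fixed n", {
  peaks <- sapply(c(1, 2, 4, 8), function(mtt) {
    p <- pk_params("Mt", k_e = 0.0692, k_a = 0.7, k = 10 / mtt, n = 10, F = 1)
    tt <- seq(0, 60, by = 0.01)
    tc <- simulate_timecourse(p, pk_regimen("B1", D0 = 500), tt)
    tt[which.max(tc$amount[tc$compartment == "central"])]
  })
  expect_true(all(diff(peaks) > 0))
})

test_that("steady-state fluctuation band lies within the pure-lag band", {
  p <- fig7a_params() # MTT = 3 h
  ex <- steady_extrema(p, pk_regimen("Beq", D0 = 500, T = 8))
  # matched pure-lag model at t_lag = MTT: superpose many shifted copies
  tt <- 300 * 8 + seq(0, 8, length.out = 400)[-400]
  lag <- lag_timecourse(p, 500, 3, tt, T = 8, M = 302)
  lac <- lag$amount[lag$compartment == "central"]
  expect_lte(ex$a_max, max(lac) + 1e-9)
  expect_gte(ex$a_min, min(lac) - 1e-9)
})

test_that("n = 1 central inflow equals the two-compartment flip-flop form", {
  d <- flip_flop_demo(2, 5, k_e = 0.3, times = seq(0, 10, 0.05))
  expected <- 1 * (2 * 5 / (5 - 2)) * (exp(-2 * seq(0, 10, 0.05)) -
                                         exp(-5 * seq(0, 10, 0.05)))
  expect_equal(d$inflow_12, expected, tolerance = 1e-12)
  expect_equal(d$inflow_21, expected, tolerance = 1e-12)
})

test_that("mass is conserved through the cascade when elimination is off", {
  # with k_e ~ 0 the central compartment accumulates M F D0 eventually
  p <- pk_params("Mt", k_e = 1e-8, k_a = 1.2, k = 2, n = 4, F = 0.9)
  r <- pk_regimen("Beq", D0 = 100, T = 5, M = 3)
  tc <- simulate_timecourse(p, r, 400)
  total <- sum(tc$amount)
  expect_equal(total, 3 * 0.9 * 100, tolerance = 1e-4)
})
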
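# Closed-form central-compartment solutions for the one-compartment (M1) and
# two-compartment (M2) models under all equi-dosing regimens, plus the
# continuous-infusion and pure lag-time reference profiles.
#
# Conventions: Heaviside H(0) = 1, so values sampled exactly at a dose time
# are post-dose. A duplicated abscissa at a dose time records the pre-dose
# (left-limit) value first and the post-dose value second; `strict` marks the
# pre-dose entries.

# Heaviside mask: include tj == 0 unless strict.
hmask <- function(tj, strict) {
  if (is.null(strict)) tj >= 0 else (tj > 0) | (tj == 0 & !strict)
}

# sum_{j=1}^{M} H(t_j) f(t_j) for t_j = t - (j-1)T
dose_sum <- function(t, T, M, f, strict = NULL) {
  out <- numeric(length(t))
  for (j in seq_len(M)) {
    tj <- t - (j - 1) * T
    m <- hmask(tj, strict)
    if (!any(m)) next
    out[m] <- out[m] + f(tj[m])
  }
  out
}

# --- M1 -----------------------------------------------------------------

m1_beq_ac <- function(t, ke, F, D0, T, M, strict = NULL) {
  F * D0 * dose_sum(t, T, M, function(tj) exp(-ke * tj), strict)
}

m1_beql_ac <- function(t, ke, F, D0, DL, T, M, strict = NULL) {
  m1_beq_ac(t, ke, F, D0, T, M, strict) +
    F * (DL - D0) * ifelse(hmask(t, strict), exp(-ke * t), 0)
}

m1_ieq_ac <- function(t, ke, F, kin, tf, T, M) {
  # continuous at every switch time, so no strict handling needed
  (F * kin / ke) * dose_sum(t, T, M, function(tj) {
    -expm1(-ke * tj) - ifelse(tj >= tf, -expm1(-ke * (tj - tf)), 0)
  })
}

m1_iinf_ac <- function(t, ke, F, kin) {
  ifelse(t >= 0, (F * kin / ke) * (-expm1(-ke * t)), 0)
}

# Collapsed per-interval forms, 0 <= t_M < T after the M-th dose.
m1_beq_interval <- function(tM, ke, F, D0, T, M) {
  F * D0 * (expm1(-M * ke * T) / expm1(-ke * T)) * exp(-ke * tM)
}

m1_beql_interval <- function(tM, ke, F, D0, DL, T, M) {
  m1_beq_interval(tM, ke, F, D0, T, M) +
    F * (DL - D0) * exp(-ke * (tM + (M - 1) * T))
}

m1_ieq_interval <- function(tM, ke, F, kin, tf, T, M) {
  (F * kin / ke) * (
    -expm1(-ke * tM) -
      ifelse(tM >= tf, -expm1(-ke * (tM - tf)), 0) +
      expm1(ke * tf) * ((exp(-M * ke * T) - exp(-ke * T)) / (exp(-ke * T) - 1)) *
        exp(-ke * tM)
  )
}

m1_beq_steady <- function(tinf, ke, F, D0, T) {
  (F * D0 / (-expm1(-ke * T))) * exp(-ke * tinf)
}

m1_ieq_steady <- function(tinf, ke, F, kin, tf, T) {
  (F * kin / ke) * (
    1 - ((exp(ke * tf) - exp(ke * T)) / (1 - exp(ke * T))) * exp(-ke * tinf) -
      ifelse(tinf >= tf, -expm1(-ke * (tinf - tf)), 0)
  )
}

# --- M2 -----------------------------------------------------------------

m2_single_ac <- function(tau, ka, ke, F, D0) {
  (ka / (ke - ka)) * F * D0 * (exp(-ka * tau) - exp(-ke * tau))
}

m2_beq_ac <- function(t, ka, ke, F, D0, T, M, strict = NULL) {
  (ka / (ke - ka)) * F * D0 *
    dose_sum(t, T, M, function(tj) exp(-ka * tj) - exp(-ke * tj), strict)
}

m2_beq_ab <- function(t, ka, F, D0, T, M, strict = NULL) {
  F * D0 * dose_sum(t, T, M, function(tj) exp(-ka * tj), strict)
}

m2_beql_ac <- function(t, ka, ke, F, D0, DL, T, M, strict = NULL) {
  m2_beq_ac(t, ka, ke, F, D0, T, M, strict) +
    (ka / (ke - ka)) * F * (DL - D0) *
      ifelse(hmask(t, strict), exp(-ka * t) - exp(-ke * t), 0)
}

m2_beql_ab <- function(t, ka, F, D0, DL, T, M, strict = NULL) {
  m2_beq_ab(t, ka, F, D0, T, M, strict) +
    F * (DL - D0) * ifelse(hmask(t, strict), exp(-ka * t), 0)
}

m2_beq_interval <- function(tM, ka, ke, F, D0, T, M) {
  (ka / (ke - ka)) * F * D0 * (
    (expm1(-M * ka * T) / expm1(-ka * T)) * exp(-ka * tM) -
      (expm1(-M * ke * T) / expm1(-ke * T)) * exp(-ke * tM)
  )
}

m2_beql_interval <- function(tM, ka, ke, F, D0, DL, T, M) {
  m2_beq_interval(tM, ka, ke, F, D0, T, M) +
    (ka * F / (ke - ka)) * (DL - D0) *
      (exp(-ka * (tM + (M - 1) * T)) - exp(-ke * (tM + (M - 1) * T)))
}

m2_beq_steady <- function(tinf, ka, ke, F, D0, T) {
  (ka / (ke - ka)) * F * D0 * (
    exp(-ka * tinf) / (-expm1(-ka * T)) - exp(-ke * tinf) / (-expm1(-ke * T))
  )
}

m2_beq_steady_ab <- function(tinf, ka, F, D0, T) {
  F * D0 * exp(-ka * tinf) / (-expm1(-ka * T))
}

# Steady-state extrema for M2: trough at the interval start, peak at t*.
m2_steady_extrema_values <- function(ka, ke, F, D0, T) {
  a_min <- (ka / (ke - ka)) * F * D0 *
    (1 / (-expm1(-ka * T)) - 1 / (-expm1(-ke * T)))
  t_peak <- log((ka / ke) * (-expm1(-ke * T)) / (-expm1(-ka * T))) / (ka - ke)
  a_max <- F * D0 * ((ke / ka)^ke * (-expm1(-ka * T))^ke /
                       (-expm1(-ke * T))^ka)^(1 / (ka - ke))
  list(a_min = a_min, t_peak = t_peak, a_max = a_max)
}

# --- lag-time reference --------------------------------------------------

lag_ab_single <- function(t, ka, F, D0, t_lag) {
  ifelse(t > t_lag, F * D0 * exp(-ka * (t - t_lag)), 0)
}

lag_ac_single <- function(t, ka, ke, F, D0, t_lag) {
  ifelse(t > t_lag,
         (ka / (ke - ka)) * F * D0 *
           (exp(-ka * (t - t_lag)) - exp(-ke * (t - t_lag))),
         0)
}

#' Pure time-lag (delayed two-compartment) drug level profiles
#'
#' The change-point alternative to a transit cascade: the two-compartment
#' single-dose profile is zero up to `t_lag` and shifted thereafter. The
#' multi-dose profile is the superposition of shifted single-dose copies.
#' Used as a comparison model for transit-compartment profiles at matched
#' `t_lag = MTT`.
#'
#' @param params A [pk_params()] object with `k_a` and `k_e` (model `M2` or
#'   `Mt`; only those two rates are used).
#' @param D0 Dose per administration (mg).
#' @param t_lag Lag time (h), `>= 0`.
#' @param times Sample times (h).
#' @param T,M Dosing interval and number of doses for a multi-dose profile;
#'   defaults give a single dose.
#' @return A `pk_timecourse` tibble with columns `t`, `compartment`
#'   (`"absorption"`, `"central"`), `amount`.
#' @export
lag_timecourse <- function(params, D0, t_lag, times, T = NULL, M = 1) {
  if (!inherits(params, "pk_params") || is.null(params$k_a)) {
    abort("`params` must be a pk_params object with k_a (model M2 or Mt).",
          class = "transitpk_domain_error")
  }
  if (t_lag < 0) abort("`t_lag` must be >= 0.", class = "transitpk_domain_error")
  check_positive_scalar(D0, "D0")
  if (M > 1 && is.null(T)) {
    abort("`T` is required when M > 1.", class = "transitpk_regimen_error")
  }
  Tl <- if (is.null(T)) 1 else T
  ab <- dose_sum(times, Tl, M, function(tj) {
    lag_ab_single(tj, params$k_a, params$F, D0, t_lag)
  })
  ac <- dose_sum(times, Tl, M, function(tj) {
    lag_ac_single(tj, params$k_a, params$k_e, params$F, D0, t_lag)
  })
  new_pk_timecourse(
    tibble(t = rep(times, 2),
           compartment = rep(c("absorption", "central"), each = length(times)),
           amount = c(ab, ac)),
    params = params, regimen = list(kind = "lag", D0 = D0, T = T, M = M,
                                    t_lag = t_lag))
}

#' Continuous-infusion drug level
#'
#' One-compartment IV infusion at constant rate `k_in` starting at `t = 0`:
#' `a_c(t) = (F k_in / k_e) (1 - exp(-k_e t))`, a monotone rise to the
#' plateau `F k_in / k_e`. This is the high-frequency limit of equi-bolus
#' dosing with matched average rate `D0 / T = k_in`.
#'
#' @param params A [pk_params()] object, model `M1`.
#' @param k_in Infusion rate (mg/h).
#' @param times Sample times (h).
#' @return A `pk_timecourse` tibble (`central` compartment only).
#' @export
continuous_infusion <- function(params, k_in, times) {
  if (!inherits(params, "pk_params") || params$model != "M1") {
    abort("`params` must be a pk_params object with model M1.",
          class = "transitpk_domain_error")
  }
  check_positive_scalar(k_in, "k_in")
  new_pk_timecourse(
    tibble(t = times, compartment = "central",
           amount = m1_iinf_ac(times, params$k_e, params$F, k_in)),
    params = params, regimen = pk_regimen("Iinf", k_in = k_in))
}
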
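# Exact multi-dose solutions for the n-transit-compartment model (Mt): all
# n + 2 compartments for bolus regimens, and the periodic steady-state
# profile with its interval-initial values (recurrence and Stirling closed
# form).
#
# Every compartment level reduces to exponentials of
#   m*log(k) + log P(m, k - k_x, tau) - k_x * tau,
# with P the scaled incomplete-gamma kernel of incgamma_log_scaled(); the
# individually astronomical factors are only ever combined in log space.

# a_i(tau) for a single dose at tau = 0 (vectorised over tau >= 0 mask).
tcm_transit_single <- function(i, tau, k, F, D0) {
  out <- numeric(length(tau))
  pos <- tau >= 0
  if (!any(pos)) return(out)
  tt <- tau[pos]
  if (i == 1) {
    out[pos] <- F * D0 * exp(-k * tt)
  } else {
    v <- numeric(length(tt))
    nz <- tt > 0
    v[nz] <- F * D0 * exp((i - 1) * log(k * tt[nz]) - lgamma(i) - k * tt[nz])
    out[pos] <- v
  }
  out
}

tcm_absorption_single <- function(tau, n, k, ka, F, D0) {
  out <- numeric(length(tau))
  pos <- tau > 0
  if (!any(pos)) return(out)
  tt <- tau[pos]
  out[pos] <- F * D0 *
    exp(n * log(k) + incgamma_log_scaled(n, k - ka, tt) - ka * tt)
  out
}

tcm_central_single <- function(tau, n, k, ka, ke, F, D0) {
  out <- numeric(length(tau))
  pos <- tau > 0
  if (!any(pos)) return(out)
  tt <- tau[pos]
  Ea <- exp(n * log(k) + incgamma_log_scaled(n, k - ka, tt) - ka * tt)
  Ee <- exp(n * log(k) + incgamma_log_scaled(n, k - ke, tt) - ke * tt)
  out[pos] <- F * D0 * ka / (ke - ka) * (Ea - Ee)
  out
}

# Multi-dose levels by superposition over dose times; BeqL adds a
# (D_L - D0)-scaled single-dose copy at t = 0, consistent with how the
# loading-dose corrections extend the M1/M2 equi-bolus solutions.
tcm_level <- function(what, t, params, regimen, i = NULL, strict = NULL) {
  k <- params$k; ka <- params$k_a; ke <- params$k_e
  n <- params$n; F <- params$F
  D0 <- regimen$D0
  T <- regimen$T %||% 1
  M <- if (regimen$kind == "B1") 1L else regimen$M
  single <- switch(what,
    transit = function(tau) tcm_transit_single(i, tau, k, F, D0),
    absorption = function(tau) tcm_absorption_single(tau, n, k, ka, F, D0),
    central = function(tau) tcm_central_single(tau, n, k, ka, ke, F, D0))
  out <- numeric(length(t))
  for (j in seq_len(M)) {
    tj <- t - (j - 1) * T
    m <- hmask(tj, strict)
    if (!any(m)) next
    out[m] <- out[m] + single(tj[m])
  }
  if (regimen$kind == "BeqL" && regimen$D_L > D0) {
    scale <- (regimen$D_L - D0) / D0
    m <- hmask(t, strict)
    out[m] <- out[m] + scale * single(t[m])
  }
  out
}

#' Steady-state interval-initial values for the transit-compartment model
#'
#' Under equi-bolus dosing the transit cascade approaches a T-periodic
#' steady state. This computes the dosing-interval initial values
#' `a_i(0)` for every transit compartment, the absorption compartment and
#' the central compartment, together with the dimensionless quantities
#' `phi = k T` and `beta = exp(-phi) / (1 - exp(-phi))` they are built from.
#'
#' Two independent routes to the transit-compartment values are implemented:
#' the recurrence
#' \deqn{a_i(0) = \beta \sum_{p=1}^{i-1} \frac{a_{i-p}(0)}{p!} \phi^p}
#' (the default: numerically benign, all terms positive) and the closed form
#' \deqn{a_i(0) = \frac{F D_0}{1 - e^{-\phi}} \frac{\phi^{i-1}}{(i-1)!}
#'   \sum_{p=0}^{i-1} p!\, S(i-1, p)\, \beta^p}
#' with `S` the Stirling numbers of the second kind. The closed form mixes
#' combinatorially large `S` with powers of `beta` and loses float accuracy
#' for large `n`; it is retained for cross-validation.
#'
#' @param params A [pk_params()] object, model `Mt`.
#' @param T Dosing interval (h).
#' @param D0 Dose (mg).
#' @param method `"recurrence"` (default) or `"stirling"` for the transit
#'   values.
#' @return A list of class `ss_coefficients`: `phi`, `beta`, `beta_a`,
#'   `beta_c`, `a_transit` (length `n`), `a_b0`, `a_c0`.
#' @export
ss_initial_values <- function(params, T, D0, method = c("recurrence", "stirling")) {
  method <- match.arg(method)
  if (!inherits(params, "pk_params") || params$model != "Mt") {
    abort("`params` must be a pk_params object with model Mt.",
          class = "transitpk_domain_error")
  }
  check_positive_scalar(T, "T")
  check_positive_scalar(D0, "D0")
  k <- params$k; ka <- params$k_a; ke <- params$k_e
  n <- params$n; F <- params$F
  phi <- k * T
  if (phi < 1e-10) {
    abort(paste0("phi = k*T is vanishingly small; the per-interval geometric ",
                 "factor beta diverges. Increase T or k."),
          class = "transitpk_domain_error")
  }
  beta <- 1 / expm1(phi)
  a1 <- F * D0 / (-expm1(-phi))
  a_transit <- numeric(n)
  a_transit[1] <- a1
  if (method == "recurrence") {
    if (n > 1) {
      lphi_fact <- cumsum(log(phi) - log(seq_len(n))) # log(phi^p / p!)
      for (i in 2:n) {
        p <- seq_len(i - 1)
        a_transit[i] <- beta * sum(a_transit[i - p] * exp(lphi_fact[p]))
      }
    }
  } else {
    lbeta <- log(beta)
    for (i in seq_len(n)) {
      p <- 0:(i - 1)
      lS <- vapply(p, function(pp) {
        s <- stirling2(i - 1, pp)
        if (s == 0) -Inf else log(s)
      }, numeric(1))
      terms <- exp(lgamma(p + 1) + lS + p * lbeta)
      a_transit[i] <- a1 * exp((i - 1) * log(phi) - lgamma(i)) * sum(terms)
    }
  }
  # absorption: a_b(0) = beta_a * sum_p a_p(0) k^m P(m, k - ka, T), m = n-p+1,
  # with the e^{-ka T} of beta_a folded into each exponent.
  m_seq <- n - seq_len(n) + 1
  lP_ka <- vapply(m_seq, function(m) incgamma_log_scaled(m, k - ka, T), numeric(1))
  lP_ke <- vapply(m_seq, function(m) incgamma_log_scaled(m, k - ke, T), numeric(1))
  a_b0 <- sum(a_transit * exp(m_seq * log(k) + lP_ka - ka * T)) / (-expm1(-ka * T))
  beta_c <- ka / ((ka - ke) * (-expm1(-ke * T)))
  a_c0 <- beta_c * (
    a_b0 * (exp(-ke * T) - exp(-ka * T)) +
      sum(a_transit * (exp(m_seq * log(k) + lP_ke - ke * T) -
                         exp(m_seq * log(k) + lP_ka - ka * T)))
  )
  structure(list(phi = phi, beta = beta,
                 beta_a = 1 / expm1(ka * T), beta_c = beta_c,
                 a_transit = a_transit, a_b0 = a_b0, a_c0 = a_c0,
                 params = params, T = T, D0 = D0),
            class = "ss_coefficients")
}

# Steady-state compartment levels over one dosing interval, t_inf in [0, T);
# all vectorised over tinf (the gamma kernel already is).
tcm_steady_transit <- function(i, tinf, coef) {
  k <- coef$params$k
  out <- coef$a_transit[i] * exp(-k * tinf) # p = 0 term
  pos <- tinf > 0
  if (i > 1 && any(pos)) {
    s <- tinf[pos]
    acc <- numeric(length(s))
    for (p in seq_len(i - 1)) {
      acc <- acc + coef$a_transit[i - p] *
        exp(p * log(k * s) - lgamma(p + 1) - k * s)
    }
    out[pos] <- out[pos] + acc
  }
  out
}

tcm_steady_absorption <- function(tinf, coef) {
  k <- coef$params$k; ka <- coef$params$k_a; n <- coef$params$n
  out <- coef$a_b0 * exp(-ka * tinf)
  for (p in seq_len(n)) {
    m <- n - p + 1
    out <- out + coef$a_transit[p] *
      exp(m * log(k) + incgamma_log_scaled(m, k - ka, tinf) - ka * tinf)
  }
  out
}

tcm_steady_central <- function(tinf, coef) {
  k <- coef$params$k; ka <- coef$params$k_a; ke <- coef$params$k_e
  n <- coef$params$n
  acc <- numeric(length(tinf))
  for (p in seq_len(n)) {
    m <- n - p + 1
    acc <- acc + coef$a_transit[p] *
      (exp(m * log(k) + incgamma_log_scaled(m, k - ke, tinf) - ke * tinf) -
         exp(m * log(k) + incgamma_log_scaled(m, k - ka, tinf) - ka * tinf))
  }
  coef$a_c0 * exp(-ke * tinf) + (ka / (ka - ke)) *
    (coef$a_b0 * (exp(-ke * tinf) - exp(-ka * tinf)) + acc)
}

#' @export
print.ss_coefficients <- function(x, ...) {
  cat(sprintf("<ss_coefficients> Mt n = %d, phi = kT = %.4g\n",
              x$params$n, x$phi))
  cat(sprintf("  a_1(0) = %.6g, a_b(0) = %.6g, a_c(0) = %.6g mg\n",
              x$a_transit[1], x$a_b0, x$a_c0))
  invisible(x)
}
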
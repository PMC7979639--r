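#' Lower incomplete gamma function for integer shape
#'
#' Evaluates \eqn{\gamma(n, t) = \int_0^t x^{n-1} e^{-x} dx} for positive
#' integer shape `n` and any real argument `t`. Negative arguments arise
#' throughout the transit-compartment solutions whenever the transit rate is
#' smaller than the absorption or elimination rate, so they are supported
#' here.
#'
#' For `t >= 0` the value is computed through the regularised gamma CDF,
#' \eqn{\gamma(n, t) = \Gamma(n) F_\Gamma(t; n, 1)}; regularised-gamma
#' implementations reject negative arguments, so for `t < 0` the
#' truncated-exponential-sum closed form
#' \eqn{\gamma(n,t) = (n-1)!\,(1 - e^{-t} \sum_{p=0}^{n-1} t^p / p!)}
#' applies, evaluated through a cancellation-free positive-series
#' rearrangement (the direct alternating sum loses all significant digits
#' once \eqn{|t|} is moderately large). The two branches agree (both give 0)
#' at `t = 0`.
#'
#' For large `n` the factors of the closed form overflow individually even
#' when the solver-level quantity (which divides by a rate difference to the
#' n-th power) is moderate; solvers therefore use the log-scaled kernel
#' `incgamma_log_scaled()` internally rather than this function.
#'
#' @param n Positive integer shape.
#' @param t Real argument(s), any sign; vectorised.
#' @param method `"direct"` (default) uses `gamma(n) * pgamma(t, n)` for
#'   `t >= 0`; `"log"` uses the exponentiated log-gamma route
#'   `exp(lgamma(n)) * pgamma(t, n)`, the fallback recommended where a direct
#'   gamma function is unavailable or overflows. Both fall through to the
#'   closed-form branch for negative `t`.
#' @return `gamma(n, t)`, same length as `t`.
#' @examples
#' lower_incomplete_gamma(1, 2)   # 1 - exp(-2)
#' lower_incomplete_gamma(3, -1.5)
#' @export
lower_incomplete_gamma <- function(n, t, method = c("direct", "log")) {
  method <- match.arg(method)
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    abort("`n` must be a single positive integer.",
          class = "transitpk_domain_error")
  }
  out <- numeric(length(t))
  pos <- t >= 0
  if (any(pos)) {
    out[pos] <- switch(method,
      direct = gamma(n) * pgamma(t[pos], shape = n, rate = 1),
      log = exp(lgamma(n) + pgamma(t[pos], shape = n, rate = 1, log.p = TRUE))
    )
  }
  if (any(!pos)) {
    out[!pos] <- vapply(t[!pos], incgamma_negative, numeric(1), n = n)
  }
  out
}

# Branch for t < 0. Algebraically gamma(n, t) = (n-1)!(1 - e^{-t} S) with S
# the degree-(n-1) truncated exponential sum, but that form cancels
# catastrophically for |t| large; substituting x = -s in the defining
# integral gives gamma(n, t) = (-1)^n (n-1)! P(n, -1, |t|) with P the
# everywhere-positive scaled kernel, which is exact and stable.
incgamma_negative <- function(n, t) {
  (-1)^n * exp(lgamma(n) + incgamma_log_scaled(n, -1, -t))
}

#' Log-scaled incomplete-gamma kernel
#'
#' The transit-compartment solutions all reduce to the quantity
#' \deqn{P(n, a, \tau) = \frac{1}{(n-1)!}\int_0^\tau s^{n-1} e^{-a s}\, ds
#'   = \frac{\gamma(n, a\tau)}{a^n (n-1)!},}
#' with `a` a difference of rate constants of either sign. `P` is positive
#' for all `a` and `tau > 0`, whereas its factors `gamma(n, a*tau)` and
#' `a^{-n}/(n-1)!` are separately astronomical in magnitude for large `n`;
#' this kernel therefore returns `log P` directly.
#'
#' For `a > 0`, `log P = pgamma(a*tau, n, log.p = TRUE) - n*log(a)`. For
#' `a < 0` the integrand grows, and `P` is computed from the everywhere-
#' positive series
#' \deqn{P = \frac{\tau^n}{(n-1)!}\sum_{m \ge 0}
#'   \frac{(|a|\tau)^m}{m!\,(n+m)},}
#' accumulated term-by-term in log space (running log-sum-exp), so no
#' cancellation or overflow occurs. For `a = 0`, `P = tau^n / n!`.
#'
#' @param n Positive integer shape.
#' @param a Rate-difference argument (single value, any sign).
#' @param tau Non-negative times, vectorised; `tau <= 0` yields `-Inf`.
#' @return `log(P(n, a, tau))` for each `tau`.
#' @keywords internal
#' @export
incgamma_log_scaled <- function(n, a, tau) {
  out <- rep(-Inf, length(tau))
  ok <- is.finite(tau) & tau > 0
  if (!any(ok)) return(out)
  tt <- tau[ok]
  if (a == 0) {
    out[ok] <- n * log(tt) - lgamma(n + 1)
  } else if (a > 0) {
    out[ok] <- pgamma(a * tt, shape = n, rate = 1, log.p = TRUE) - n * log(a)
  } else {
    b <- -a
    x <- b * tt
    small <- x < 2 * n + 20
    if (any(small)) {
      out[ok][small] <- incgamma_neg_ascending(n, b, tt[small])
    }
    if (any(!small)) {
      out[ok][!small] <- incgamma_neg_descending(n, b, tt[!small])
    }
  }
  out
}

# Ascending series, all terms positive, accumulated in log space; used for
# moderate |a| tau where it converges in O(n) terms.
incgamma_neg_ascending <- function(n, b, tt) {
  lead <- n * log(tt) - lgamma(n)
  x <- b * tt
  ls <- rep(-log(n), length(tt)) # m = 0 term (relative)
  lterm <- ls
  m <- 0
  m_max <- ceiling(max(x)) + 60 * ceiling(sqrt(max(x) + 10)) + 60
  repeat {
    m <- m + 1
    lterm <- lterm + log(x) - log(m) + log(n + m - 1) - log(n + m)
    ls <- pmax(ls, lterm) + log1p(exp(-abs(lterm - ls)))
    if ((m > max(x) && all(lterm - ls < -40)) || m > m_max) break
  }
  lead + ls
}

# Exact finite descending sum (integration by parts), n terms, alternating
# with ratio (n-1)/x < 1/2 in this regime so cancellation is mild:
#   P = e^{b tau} sum_{j=0}^{n-1} (-1)^j tau^{n-1-j} / ((n-1-j)! b^{j+1})
#       + (-1)^n / b^n.
incgamma_neg_descending <- function(n, b, tt) {
  lw0 <- (n - 1) * log(tt) - lgamma(n) - log(b)
  s_rel <- rep(1, length(tt)) # j = 0 term relative to lw0
  if (n > 1) {
    lw <- lw0
    for (j in seq_len(n - 1)) {
      lw <- lw - log(tt) + log(n - j) - log(b)
      s_rel <- s_rel + (-1)^j * exp(lw - lw0)
    }
  }
  s_rel <- s_rel + (-1)^n * exp(-b * tt - n * log(b) - lw0)
  b * tt + lw0 + log(s_rel)
}

#' Stirling numbers of the second kind
#'
#' `S(n, q)` counts the partitions of an n-element set into `q` non-empty
#' blocks; it appears in the closed-form steady-state interval-initial values
#' of the transit cascade. Values grow combinatorially, so they are computed
#' in exact arbitrary-precision integer arithmetic via the recurrence
#' `S(n, q) = q * S(n-1, q) + S(n-1, q-1)` (additions and small scalar
#' multiplications only, hence no cancellation), with `S(0, 0) = 1`.
#' Conversion to double happens only on return.
#'
#' @param n Non-negative integer.
#' @param q Non-negative integer, `0 <= q <= n`.
#' @param exact If `TRUE`, return the exact value as a decimal string instead
#'   of a double.
#' @return `S(n, q)` as a double (default) or character string.
#' @examples
#' stirling2(4, 2) # 7
#' stirling2(25, 12, exact = TRUE)
#' @export
stirling2 <- function(n, q, exact = FALSE) {
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n != round(n) ||
      !is.numeric(q) || length(q) != 1 || q < 0 || q != round(q)) {
    abort("`n` and `q` must be single non-negative integers.",
          class = "transitpk_domain_error")
  }
  if (q > n) {
    abort("`q` must satisfy q <= n.", class = "transitpk_domain_error")
  }
  v <- stirling2_row(as.integer(n))[[q + 1L]]
  if (exact) big_to_string(v) else big_to_double(v)
}

# Row n of the Stirling-number triangle as a list of bignums (index q + 1).
stirling2_row <- function(n) {
  row <- list(big_from_int(1L)) # S(0, 0) = 1
  if (n == 0L) return(row)
  for (m in seq_len(n)) {
    new <- vector("list", m + 1L)
    new[[1L]] <- big_from_int(if (m == 0L) 1L else 0L) # S(m, 0) = 0 for m >= 1
    for (q in seq_len(m)) {
      a <- if (q + 1L <= length(row)) big_smul(row[[q + 1L]], q) else NULL
      b <- row[[q]] # S(m-1, q-1)
      new[[q + 1L]] <- if (is.null(a)) b else big_add(a, b)
    }
    row <- new
  }
  row
}

# --- minimal non-negative bignum: integer vector of base-1e7 limbs, little-endian

big_base <- 1e7

big_from_int <- function(x) as.double(x)

big_trim <- function(x) {
  while (length(x) > 1 && x[length(x)] == 0) x <- x[-length(x)]
  x
}

big_add <- function(a, b) {
  ln <- max(length(a), length(b))
  a <- c(a, rep(0, ln - length(a)))
  b <- c(b, rep(0, ln - length(b)))
  s <- a + b
  carry <- 0
  for (i in seq_len(ln)) {
    s[i] <- s[i] + carry
    carry <- s[i] %/% big_base
    s[i] <- s[i] %% big_base
  }
  if (carry > 0) s <- c(s, carry)
  big_trim(s)
}

big_smul <- function(a, m) {
  # m is a small non-negative integer (<= ~1e8); limb products stay exact
  s <- a * m
  carry <- 0
  for (i in seq_along(s)) {
    s[i] <- s[i] + carry
    carry <- s[i] %/% big_base
    s[i] <- s[i] %% big_base
  }
  while (carry > 0) {
    s <- c(s, carry %% big_base)
    carry <- carry %/% big_base
  }
  big_trim(s)
}

big_to_double <- function(a) {
  sum(a * big_base^(seq_along(a) - 1))
}

big_to_string <- function(a) {
  limbs <- rev(a)
  out <- sprintf("%.0f", limbs[1])
  if (length(limbs) > 1) {
    out <- paste0(out, paste(sprintf("%07.0f", limbs[-1]), collapse = ""))
  }
  out
}

# Alternating-sum formula for S(n, q) in doubles; safe only while binomial
# terms stay below 2^53. Used as an independent cross-check in tests.
stirling2_altsum <- function(n, q) {
  if (q == 0) return(as.numeric(n == 0))
  p <- 0:q
  sum((-1)^p * choose(q, p) * (q - p)^n) / factorial(q)
}
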
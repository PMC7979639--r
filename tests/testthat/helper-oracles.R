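# Independent numerical oracles used across the suite.

# Adaptive ODE integration of the compartment systems with impulse restarts
# at dose times (bolus regimens) or piecewise-constant forcing (infusions).
# Returns a matrix of compartment amounts at `times`, columns named as in
# simulate_timecourse(). Values at dose instants are post-dose.
ode_pk <- function(params, regimen, times, rtol = 1e-10, atol = 1e-12) {
  model <- params$model
  ke <- params$k_e; ka <- params$k_a; k <- params$k
  n_tr <- if (model == "Mt") params$n else 0
  nms <- switch(model,
    M1 = "central",
    M2 = c("absorption", "central"),
    Mt = c(paste0("transit_", seq_len(n_tr)), "absorption", "central"))
  dim_y <- length(nms)
  rhs_free <- function(t, y, parms) {
    d <- numeric(dim_y)
    if (model == "M1") {
      d[1] <- -ke * y[1]
    } else if (model == "M2") {
      d[1] <- -ka * y[1]
      d[2] <- ka * y[1] - ke * y[2]
    } else {
      d[1] <- -k * y[1]
      if (n_tr > 1) for (i in 2:n_tr) d[i] <- k * y[i - 1] - k * y[i]
      d[n_tr + 1] <- k * y[n_tr] - ka * y[n_tr + 1]
      d[n_tr + 2] <- ka * y[n_tr + 1] - ke * y[n_tr + 2]
    }
    list(d)
  }
  kind <- regimen$kind
  F <- params$F
  if (kind %in% c("B1", "Beq", "BeqL")) {
    M <- if (kind == "B1") 1L else regimen$M
    T <- regimen$T %||% 1
    dose_times <- (seq_len(M) - 1) * T
    doses <- rep(F * regimen$D0, M)
    if (kind == "BeqL") doses[1] <- F * regimen$D_L
    y <- numeric(dim_y)
    out <- matrix(NA_real_, length(times), dim_y, dimnames = list(NULL, nms))
    seg_bounds <- c(dose_times, Inf)
    t_cur <- 0
    for (s in seq_len(M)) {
      y[1] <- y[1] + doses[s]
      t_next <- min(seg_bounds[s + 1], max(times))
      idx <- which(times >= seg_bounds[s] & times < seg_bounds[s + 1])
      if (s == M) idx <- which(times >= seg_bounds[s])
      tt <- sort(unique(c(seg_bounds[s], times[idx],
                          max(seg_bounds[s], t_next))))
      if (length(tt) > 1) {
        sol <- deSolve::lsoda(y, tt, rhs_free, NULL, rtol = rtol, atol = atol)
        if (length(idx)) {
          out[idx, ] <- sol[match(times[idx], sol[, 1]), -1, drop = FALSE]
        }
        y <- as.numeric(sol[nrow(sol), -1])
      } else if (length(idx)) {
        out[idx, ] <- matrix(y, length(idx), dim_y, byrow = TRUE)
      }
    }
    out
  } else {
    # infusion kinds: piecewise-constant forcing into the central compartment
    kin <- regimen$k_in
    if (kind == "Iinf") {
      on_off <- matrix(c(0, max(times)), 1)
    } else {
      T <- regimen$T; tf <- regimen$t_f; M <- regimen$M
      on_off <- cbind((seq_len(M) - 1) * T, (seq_len(M) - 1) * T + tf)
    }
    breaks <- sort(unique(c(0, as.vector(on_off), max(times))))
    breaks <- breaks[breaks <= max(times)]
    if (max(breaks) < max(times)) breaks <- c(breaks, max(times))
    rhs_forced <- function(t, y, parms) {
      d <- rhs_free(t, y, parms)[[1]]
      d[1] <- d[1] + parms$inflow
      list(d)
    }
    y <- numeric(dim_y)
    out <- matrix(NA_real_, length(times), dim_y, dimnames = list(NULL, nms))
    out[times == 0, ] <- 0
    for (s in seq_len(length(breaks) - 1)) {
      a <- breaks[s]; b <- breaks[s + 1]
      on <- any(on_off[, 1] <= a & a < on_off[, 2])
      idx <- which(times > a & times <= b)
      tt <- sort(unique(c(a, times[idx], b)))
      if (length(tt) > 1) {
        sol <- deSolve::lsoda(y, tt, rhs_forced,
                              list(inflow = if (on) F * kin else 0),
                              rtol = rtol, atol = atol)
        if (length(idx)) {
          out[idx, ] <- sol[match(times[idx], sol[, 1]), -1, drop = FALSE]
        }
        y <- as.numeric(sol[nrow(sol), -1])
      }
    }
    out
  }
}

# Central-compartment series from the ODE oracle.
ode_central <- function(params, regimen, times, ...) {
  unname(ode_pk(params, regimen, times, ...)[, "central"])
}

# Brute-force count of partitions of an n-set into q non-empty blocks, by
# exhaustive assignment with canonical block labelling.
count_set_partitions <- function(n, q) {
  count <- 0L
  rec <- function(i, n_blocks, sizes) {
    if (i > n) {
      if (n_blocks == q && all(sizes[seq_len(q)] > 0)) count <<- count + 1L
      return(invisible(NULL))
    }
    for (b in seq_len(min(n_blocks + 1, q))) {
      sizes2 <- sizes
      sizes2[b] <- sizes2[b] + 1L
      rec(i + 1L, max(n_blocks, b), sizes2)
    }
  }
  if (n == 0 && q == 0) return(1L)
  rec(1L, 0L, integer(q))
  count
}

fig7a_params <- function() {
  pk_params("Mt", k_e = 0.0692, k_a = 0.7, k = 10 / 3, n = 10, F = 1)
}
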
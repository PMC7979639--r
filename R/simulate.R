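# Front-door simulation surface: a single entry point for transient time
# courses, collapsed per-interval evaluation, and periodic steady-state
# profiles across all model/regimen combinations.

# Memoise the most recent steady-state coefficient set (steady_state() is
# called with identical arguments from several places per region build).
.ss_cache <- new.env(parent = emptyenv())
ss_coef_cache <- function(params, T, D0) {
  key <- paste(params$k, params$k_a, params$k_e, params$n, params$F, T, D0,
               sep = "|")
  if (!identical(.ss_cache$key, key)) {
    .ss_cache$key <- key
    .ss_cache$coef <- ss_initial_values(params, T, D0)
  }
  .ss_cache$coef
}

new_pk_timecourse <- function(df, params, regimen) {
  structure(as_tibble(df),
            params = params, regimen = regimen,
            class = c("pk_timecourse", class(as_tibble(df))))
}

# Mark the first of each duplicated abscissa as a pre-dose (left-limit)
# sample; the second carries the post-dose value (H(0) = 1 convention).
strict_mask <- function(times) {
  dup_next <- c(times[-1] == times[-length(times)], FALSE)
  dup_next
}

#' Simulate a drug level time course
#'
#' Evaluates the exact transient solution for a validated model/regimen pair
#' on an arbitrary time grid and returns a tidy time course with one row per
#' (time, compartment). Supported combinations:
#'
#' | model | regimens |
#' |-------|----------|
#' | `M1`  | `B1`, `Beq`, `BeqL`, `Iinf`, `Ieq` |
#' | `M2`  | `B1`, `Beq`, `BeqL` |
#' | `Mt`  | `B1`, `Beq`, `BeqL` |
#'
#' Values at dose instants follow `H(0) = 1` (post-dose). To record the jump,
#' duplicate the abscissa: the first of the pair is the pre-dose (left-limit)
#' value.
#'
#' @param params A [pk_params()] object.
#' @param regimen A [pk_regimen()] object with finite `M`.
#' @param times Monotone non-decreasing sample times (h).
#' @return A `pk_timecourse` tibble with columns `t`, `compartment`,
#'   `amount`. Compartment labels are `"central"`, `"absorption"`, and
#'   `"transit_1" ... "transit_n"` as applicable.
#' @examples
#' p <- pk_params("M1", k_e = 0.0692)
#' r <- pk_regimen("Beq", D0 = 500, T = 12, M = 6)
#' simulate_timecourse(p, r, times = seq(0, 72, by = 1))
#' @export
simulate_timecourse <- function(params, regimen, times) {
  validate_pair(params, regimen)
  if (is.infinite(regimen$M)) {
    abort(paste0("Regimen has infinite M; use steady_state() for the ",
                 "periodic steady-state profile."),
          class = "transitpk_regimen_error")
  }
  if (is.unsorted(times)) {
    abort("`times` must be non-decreasing.", class = "transitpk_domain_error")
  }
  strict <- strict_mask(times)
  ke <- params$k_e; ka <- params$k_a; F <- params$F
  D0 <- regimen$D0; T <- regimen$T %||% 1
  M <- if (regimen$kind %in% c("B1", "Iinf")) 1L else regimen$M
  kind <- regimen$kind
  levels <- switch(params$model,
    M1 = {
      ac <- switch(kind,
        B1 = m1_beq_ac(times, ke, F, D0, T, 1L, strict),
        Beq = m1_beq_ac(times, ke, F, D0, T, M, strict),
        BeqL = m1_beql_ac(times, ke, F, D0, regimen$D_L, T, M, strict),
        Iinf = m1_iinf_ac(times, ke, F, regimen$k_in),
        Ieq = m1_ieq_ac(times, ke, F, regimen$k_in, regimen$t_f, T, M))
      list(central = ac)
    },
    M2 = {
      if (!kind %in% c("B1", "Beq", "BeqL")) {
        abort("Model M2 supports bolus regimens only.",
              class = "transitpk_regimen_error")
      }
      if (kind == "BeqL") {
        list(absorption = m2_beql_ab(times, ka, F, D0, regimen$D_L, T, M, strict),
             central = m2_beql_ac(times, ka, ke, F, D0, regimen$D_L, T, M, strict))
      } else {
        list(absorption = m2_beq_ab(times, ka, F, D0, T, M, strict),
             central = m2_beq_ac(times, ka, ke, F, D0, T, M, strict))
      }
    },
    Mt = {
      if (!kind %in% c("B1", "Beq", "BeqL")) {
        abort("Model Mt supports bolus regimens only.",
              class = "transitpk_regimen_error")
      }
      tr <- lapply(seq_len(params$n), function(i) {
        tcm_level("transit", times, params, regimen, i = i, strict = strict)
      })
      names(tr) <- paste0("transit_", seq_len(params$n))
      c(tr,
        list(absorption = tcm_level("absorption", times, params, regimen,
                                    strict = strict),
             central = tcm_level("central", times, params, regimen,
                                 strict = strict)))
    })
  df <- tibble(
    t = rep(times, length(levels)),
    compartment = rep(names(levels), each = length(times)),
    amount = unlist(levels, use.names = FALSE))
  new_pk_timecourse(df, params, regimen)
}

#' Central drug level within the M-th dosing interval (collapsed form)
#'
#' Evaluates the geometric-sum collapsed per-interval solution
#' `a_c^M(t_M)` for `0 <= t_M < T`, where `t_M` is the time since the M-th
#' dose. These forms are O(1) in `M` and are exactly equal to the transient
#' superposition sums; both paths are retained and cross-checked.
#' Available for `M1` (`Beq`, `BeqL`, `Ieq`) and `M2` (`Beq`, `BeqL`).
#'
#' @param params A [pk_params()] object (`M1` or `M2`).
#' @param regimen A repeated-dosing [pk_regimen()].
#' @param M Dose index (positive integer).
#' @param t_M Time since the M-th dose, in `[0, T)`; vectorised.
#' @return Numeric vector of central drug levels (mg).
#' @export
interval_level <- function(params, regimen, M, t_M) {
  validate_pair(params, regimen)
  if (!is.numeric(M) || M < 1 || M != round(M) || is.infinite(M)) {
    abort("`M` must be a finite positive integer.",
          class = "transitpk_domain_error")
  }
  if (any(t_M < 0 | t_M >= regimen$T)) {
    abort("`t_M` must lie in [0, T).", class = "transitpk_domain_error")
  }
  ke <- params$k_e; ka <- params$k_a; F <- params$F
  D0 <- regimen$D0; T <- regimen$T
  key <- paste(params$model, regimen$kind)
  switch(key,
    "M1 Beq" = m1_beq_interval(t_M, ke, F, D0, T, M),
    "M1 BeqL" = m1_beql_interval(t_M, ke, F, D0, regimen$D_L, T, M),
    "M1 Ieq" = m1_ieq_interval(t_M, ke, F, regimen$k_in, regimen$t_f, T, M),
    "M2 Beq" = m2_beq_interval(t_M, ka, ke, F, D0, T, M),
    "M2 BeqL" = m2_beql_interval(t_M, ka, ke, F, D0, regimen$D_L, T, M),
    abort(sprintf("No collapsed per-interval form for %s.", key),
          class = "transitpk_regimen_error"))
}

#' Periodic steady-state profile
#'
#' Returns the T-periodic steady-state solution for a repeated-dosing
#' regimen: the per-compartment values at the dosing-interval start, and an
#' evaluator over `t_inf` in `[0, T)`. For `M1` and `M2` these are closed
#' forms; for the transit model they are built from the steady-state
#' interval-initial values of [ss_initial_values()]. The loading-dose
#' regimen `BeqL` has the same steady state as `Beq` (the loading correction
#' decays).
#'
#' @param params A [pk_params()] object.
#' @param regimen A repeated-dosing [pk_regimen()] (`Beq`, `BeqL` or `Ieq`).
#' @return An object of class `pk_steady_state`: a list with `T`,
#'   `initial_values` (named per-compartment amounts at `t_inf = 0`),
#'   `evaluate(t_inf)` returning a matrix (rows = `t_inf`, columns =
#'   compartments), plus `params` and `regimen`.
#' @examples
#' p <- pk_params("M2", k_e = 0.0692, k_a = 0.7)
#' ss <- steady_state(p, pk_regimen("Beq", D0 = 500, T = 12))
#' ss$initial_values
#' @export
steady_state <- function(params, regimen) {
  validate_pair(params, regimen)
  if (!regimen$kind %in% c("Beq", "BeqL", "Ieq")) {
    abort("Steady state is defined for repeated regimens (Beq, BeqL, Ieq).",
          class = "transitpk_regimen_error")
  }
  ke <- params$k_e; ka <- params$k_a; F <- params$F
  D0 <- regimen$D0; T <- regimen$T
  ev <- switch(params$model,
    M1 = {
      if (regimen$kind == "Ieq") {
        kin <- regimen$k_in; tf <- regimen$t_f
        function(tinf) cbind(central = m1_ieq_steady(tinf, ke, F, kin, tf, T))
      } else {
        function(tinf) cbind(central = m1_beq_steady(tinf, ke, F, D0, T))
      }
    },
    M2 = function(tinf) {
      cbind(absorption = m2_beq_steady_ab(tinf, ka, F, D0, T),
            central = m2_beq_steady(tinf, ka, ke, F, D0, T))
    },
    Mt = {
      coef <- ss_coef_cache(params, T, D0)
      function(tinf) {
        tr <- vapply(seq_len(params$n),
                     function(i) tcm_steady_transit(i, tinf, coef),
                     numeric(length(tinf)))
        if (length(tinf) == 1) tr <- matrix(tr, nrow = 1)
        colnames(tr) <- paste0("transit_", seq_len(params$n))
        cbind(tr,
              absorption = tcm_steady_absorption(tinf, coef),
              central = tcm_steady_central(tinf, coef))
      }
    })
  iv <- ev(0)[1, ]
  central_fn <- function(tinf) as.numeric(ev(tinf)[, "central"])
  if (params$model == "Mt") {
    coef <- ss_coef_cache(params, T, D0)
    central_fn <- function(tinf) tcm_steady_central(tinf, coef)
  }
  structure(list(T = T, initial_values = iv, evaluate = ev,
                 central = central_fn,
                 params = params, regimen = regimen),
            class = "pk_steady_state")
}

#' @export
print.pk_steady_state <- function(x, ...) {
  cat(sprintf("<pk_steady_state> model %s, period T = %g h\n",
              x$params$model, x$T))
  cat("  interval-initial values (mg):\n")
  print(round(x$initial_values, 6))
  invisible(x)
}

#' Tidy evaluation of a steady-state profile
#'
#' @param ss A [steady_state()] object.
#' @param t_inf Times since the dosing-interval start, in `[0, T)`; default a
#'   201-point grid.
#' @return A tibble with columns `t_inf`, `compartment`, `amount`.
#' @export
steady_profile <- function(ss, t_inf = NULL) {
  stopifnot(inherits(ss, "pk_steady_state"))
  if (is.null(t_inf)) t_inf <- seq(0, ss$T, length.out = 202)[-202]
  m <- ss$evaluate(t_inf)
  tibble(t_inf = rep(t_inf, ncol(m)),
         compartment = rep(colnames(m), each = length(t_inf)),
         amount = as.vector(m))
}

# Golden-section refinement of an extremum of f bracketed by grid neighbours.
golden_refine <- function(f, lo, hi, maximise = TRUE, tol = 1e-10) {
  sgn <- if (maximise) -1 else 1
  opt <- stats::optimize(function(x) sgn * f(x), interval = c(lo, hi),
                         tol = tol)
  list(x = opt$minimum, value = sgn * opt$objective)
}

#' Steady-state extrema of the central drug level
#'
#' Computes the minimum, peak time and maximum of `a_c` over one steady-state
#' dosing interval. For `M1` (bolus: max at the interval start, min at its
#' end; infusion: max at `t_f`, min at 0) and `M2` (closed-form trough, peak
#' time and peak) these are analytical; for the transit model the profile is
#' sampled densely (default 2000 points per period) and the interior extrema
#' are refined by golden-section search, with the interval endpoints also
#' considered.
#'
#' @param params A [pk_params()] object.
#' @param regimen A repeated-dosing [pk_regimen()].
#' @param n_grid Grid size for the numerical (Mt) path.
#' @return A one-row tibble with columns `a_min`, `t_peak`, `a_max` (mg, h).
#' @export
steady_extrema <- function(params, regimen, n_grid = 2000) {
  validate_pair(params, regimen)
  ke <- params$k_e; F <- params$F
  T <- regimen$T
  out <- switch(params$model,
    M1 = {
      if (regimen$kind == "Ieq") {
        kin <- regimen$k_in; tf <- regimen$t_f
        list(a_min = (F * kin / ke) * expm1(ke * tf) / expm1(ke * T),
             t_peak = tf,
             a_max = (F * kin / ke) * (-expm1(-ke * tf)) / (-expm1(-ke * T)))
      } else {
        amax <- F * regimen$D0 / (-expm1(-ke * T))
        list(a_min = amax * exp(-ke * T), t_peak = 0, a_max = amax)
      }
    },
    M2 = m2_steady_extrema_values(params$k_a, ke, F, regimen$D0, T),
    Mt = {
      ss <- steady_state(params, regimen)
      f <- ss$central
      grid <- seq(0, T, length.out = n_grid + 1)
      v <- f(grid)
      i_max <- which.max(v); i_min <- which.min(v)
      ref <- function(i, maximise) {
        lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
        r <- golden_refine(f, lo, hi, maximise = maximise)
        # keep the grid value if refinement did not improve (flat or boundary)
        if ((maximise && r$value < v[i]) || (!maximise && r$value > v[i])) {
          list(x = grid[i], value = v[i])
        } else r
      }
      rmax <- ref(i_max, TRUE); rmin <- ref(i_min, FALSE)
      list(a_min = rmin$value, t_peak = rmax$x %% T, a_max = rmax$value)
    })
  tibble(a_min = out$a_min, t_peak = out$t_peak, a_max = out$a_max)
}

#' Write a time course or steady-state profile to CSV
#'
#' Tidy CSV with columns `(t, compartment, amount)` (or
#' `(t_inf, compartment, amount)` for a steady profile tibble).
#'
#' @param x A `pk_timecourse` or a tibble from [steady_profile()].
#' @param path Output file path.
#' @return `x`, invisibly.
#' @export
write_timecourse_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(x)
}
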
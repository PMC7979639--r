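# Equi-dosing regimen regions (EDRRs): the sets of regimen parameters whose
# periodic steady-state central-compartment trajectory lies entirely within a
# prescribed therapeutic range (D_me, D_MS). For each dosing interval T the
# acceptable doses form a band f_lo(T) < D0 < f_hi(T); the region is a
# petal-shaped set in (T, D0)-space, chopped by extra constraints for
# loading-dose and infusion regimens.

new_edrr <- function(df, kind, params, range, crossover = NULL,
                     slice_var = NULL) {
  structure(as_tibble(df),
            kind = kind, params = params, range = range,
            crossover = crossover, slice_var = slice_var,
            class = c("pk_edrr", class(as_tibble(df))))
}

default_T_grid <- function(T_star, n = 400) {
  seq(T_star * 2 / n, 2 * T_star, length.out = n)
}

#' EDRR for IV equi-bolus dosing (one-compartment model)
#'
#' Closed-form region: the steady-state trough and peak of the
#' one-compartment equi-bolus solution give
#' `f_lo(T) = (D_me/F) (exp(k_e T) - 1)` and
#' `f_hi(T) = (D_MS/F) (1 - exp(-k_e T))`. The petal closes at the crossover
#' `T* = log(D_MS/D_me) / k_e`, `D0* = (D_MS - D_me) / F`.
#'
#' @param params A [pk_params()] object, model `M1`.
#' @param range A [therapeutic_range()].
#' @param T_grid Dosing-interval grid (h); default 400 points over
#'   `(0, 2 T*]`.
#' @return A `pk_edrr` tibble with columns `T`, `f_lo`, `f_hi` and an
#'   `attr(, "crossover")` list `(T_star, D_star)`. The region is the set
#'   `f_lo < D0 < f_hi` where that band is non-empty.
#' @examples
#' edrr_iv_bolus(pk_params("M1", k_e = 0.0692), therapeutic_range(300, 1000))
#' @export
edrr_iv_bolus <- function(params, range, T_grid = NULL) {
  stopifnot(inherits(params, "pk_params"), inherits(range, "therapeutic_range"))
  if (params$model != "M1") {
    abort("IV bolus EDRR requires model M1.", class = "transitpk_domain_error")
  }
  ke <- params$k_e; F <- params$F
  T_star <- log(range$D_MS / range$D_me) / ke
  if (is.null(T_grid)) T_grid <- default_T_grid(T_star)
  df <- tibble(T = T_grid,
               f_lo = (range$D_me / F) * expm1(ke * T_grid),
               f_hi = (range$D_MS / F) * (-expm1(-ke * T_grid)))
  new_edrr(df, "iv_bolus", params, range,
           crossover = list(T_star = T_star,
                            D_star = (range$D_MS - range$D_me) / F))
}

# Closed-form oral boundary functions (model M2).
oral_f_lo <- function(T, ka, ke, F, D_me) {
  (D_me / F) * ((ka - ke) / ka) *
    ((-expm1(-ke * T)) * (-expm1(-ka * T)) /
       (expm1(-ke * T) - expm1(-ka * T)))
}

# log-space form: the direct power expression underflows for small T when
# ka >> ke ((1 - e^{-ke T})^{ka} -> 0)
oral_f_hi <- function(T, ka, ke, F, D_MS) {
  l1a <- log(-expm1(-ka * T))
  l1e <- log(-expm1(-ke * T))
  (D_MS / F) * exp((ke * log(ke / ka) + ke * l1a - ka * l1e) / (ke - ka))
}

#' EDRR for oral equi-bolus dosing (two-compartment model)
#'
#' Closed-form region from the two-compartment steady-state trough (at the
#' interval start) and peak (at the interior maximum). The crossover
#' `(T*, D0*)` has no simple closed form and is located numerically by
#' root-finding on `f_hi - f_lo`.
#'
#' @inheritParams edrr_iv_bolus
#' @param params A [pk_params()] object, model `M2`.
#' @return A `pk_edrr` tibble as in [edrr_iv_bolus()].
#' @export
edrr_oral_bolus <- function(params, range, T_grid = NULL) {
  stopifnot(inherits(params, "pk_params"), inherits(range, "therapeutic_range"))
  if (params$model != "M2") {
    abort("Oral bolus EDRR requires model M2.", class = "transitpk_domain_error")
  }
  ka <- params$k_a; ke <- params$k_e; F <- params$F
  gap <- function(T) oral_f_hi(T, ka, ke, F, range$D_MS) -
    oral_f_lo(T, ka, ke, F, range$D_me)
  # bracket the petal tip: expand until the band is empty
  hi <- log(range$D_MS / range$D_me) / ke
  lo <- hi * 1e-6
  while (gap(lo) <= 0 && lo > 1e-12) lo <- lo / 10
  while (gap(hi) > 0) hi <- hi * 2
  T_star <- uniroot(gap, c(lo, hi), tol = 1e-12)$root
  if (is.null(T_grid)) T_grid <- default_T_grid(T_star)
  df <- tibble(T = T_grid,
               f_lo = oral_f_lo(T_grid, ka, ke, F, range$D_me),
               f_hi = oral_f_hi(T_grid, ka, ke, F, range$D_MS))
  new_edrr(df, "oral_bolus", params, range,
           crossover = list(T_star = T_star,
                            D_star = oral_f_lo(T_star, ka, ke, F, range$D_me)))
}

#' EDRR for IV equi-bolus dosing with a loading dose (three parameters)
#'
#' For the regimen to be therapeutic *immediately and always*, the
#' steady-state constraints of [edrr_iv_bolus()] must hold and the first
#' dosing interval, governed by the loading dose alone, must stay within the
#' range: `D_me exp(k_e T) < F D_L < D_MS`. For a fixed loading dose the
#' acceptable `(T, D0)` set is the bolus petal chopped at
#' `T < log(F D_L / D_me) / k_e`; the 3-D region is the union of the chopped
#' petals over `D_L`, with `D_L = (D_me / F) exp(k_e T)` as the boundary
#' surface.
#'
#' @inheritParams edrr_iv_bolus
#' @param D_L Loading-dose values (mg) defining the slices.
#' @return A `pk_edrr` tibble in long format with columns `D_L`, `T`,
#'   `f_lo`, `f_hi`; rows outside a slice's chop constraint (or entire empty
#'   slices, where `F D_L >= D_MS` or the chop bound is non-positive) are
#'   omitted.
#' @export
edrr_loading <- function(params, range, D_L, T_grid = NULL) {
  base <- edrr_iv_bolus(params, range, T_grid)
  ke <- params$k_e; F <- params$F
  slices <- lapply(D_L, function(dl) {
    if (F * dl >= range$D_MS) return(NULL) # first interval unsafe
    T_max <- log(F * dl / range$D_me) / ke
    if (T_max <= 0) return(NULL) # first interval never effective
    keep <- base$T < T_max
    if (!any(keep)) return(NULL)
    dplyr::mutate(base[keep, ], D_L = dl, .before = 1)
  })
  df <- dplyr::bind_rows(slices)
  new_edrr(df, "iv_loading", params, range,
           crossover = attr(base, "crossover"), slice_var = "D_L")
}

#' EDRR for IV equi-infusion dosing (three parameters)
#'
#' For infusion on-time `t_f`, off-time `T - t_f`, and infusion rate `k_in`,
#' the steady-state maximum (at `t_inf = t_f`) and minimum (at the interval
#' start) bound the acceptable region
#' \deqn{D_{me} \frac{1-e^{k_e T}}{1-e^{k_e t_f}} < \frac{F k_{in}}{k_e}
#'       < D_{MS} \frac{1-e^{-k_e T}}{1-e^{-k_e t_f}}.}
#' Each fixed-`t_f` slice is a chopped petal in `(T, k_in)`, bounded by
#' `T = t_f` and closing at `T = t_f + log(D_MS/D_me)/k_e`; the crossover
#' infusion rate is
#' `k_in* = (k_e/F) (D_MS - D_me exp(-k_e t_f)) / (1 - exp(-k_e t_f))`.
#'
#' @inheritParams edrr_iv_bolus
#' @param t_f Infusion-on durations (h) defining the slices.
#' @param n_T Points per slice in `T`.
#' @return A `pk_edrr` tibble with columns `t_f`, `T`, `f_lo`, `f_hi`, where
#'   `f_lo`/`f_hi` bound `k_in` (mg/h); `attr(, "crossover")` holds per-slice
#'   `k_in_star` and the closing interval `T_star`.
#' @export
edrr_infusion <- function(params, range, t_f, T_grid = NULL, n_T = 400) {
  stopifnot(inherits(params, "pk_params"), inherits(range, "therapeutic_range"))
  if (params$model != "M1") {
    abort("Infusion EDRR requires model M1.", class = "transitpk_domain_error")
  }
  ke <- params$k_e; F <- params$F
  span <- log(range$D_MS / range$D_me) / ke
  slices <- lapply(t_f, function(tf) {
    Tg <- if (is.null(T_grid)) {
      seq(tf + span / n_T, tf + span, length.out = n_T)
    } else T_grid[T_grid > tf]
    tibble(t_f = tf, T = Tg,
           f_lo = (ke * range$D_me / F) * expm1(ke * Tg) / expm1(ke * tf),
           f_hi = (ke * range$D_MS / F) * (-expm1(-ke * Tg)) / (-expm1(-ke * tf)))
  })
  kin_star <- (ke / F) * (range$D_MS - range$D_me * exp(-ke * t_f)) /
    (-expm1(-ke * t_f))
  new_edrr(dplyr::bind_rows(slices), "iv_infusion", params, range,
           crossover = list(t_f = t_f, k_in_star = kin_star,
                            T_star = t_f + span),
           slice_var = "t_f")
}

#' Numerically constructed EDRR from a steady-state evaluator
#'
#' Builds `f_lo(T)` and `f_hi(T)` for any model with a steady-state evaluator
#' (the transit-compartment model being the primary use, where closed-form
#' extrema are unavailable). Two routes:
#'
#' * `"linearity"` (default): all steady-state solutions are linear in `D0`,
#'   so the unit-dose steady extrema `u_min(T)`, `u_max(T)` give
#'   `f_lo(T) = D_me / u_min(T)` and `f_hi(T) = D_MS / u_max(T)` exactly (to
#'   evaluator precision, with no dose-grid error).
#' * `"scan"`: the literal grid algorithm — for each `T_i` scan a `D0` grid,
#'   compute steady extrema per point, and pick the `D0_j` whose extremum is
#'   closest to the corresponding range limit.
#'
#' @param params A [pk_params()] object (`M1`, `M2` or `Mt`).
#' @param range A [therapeutic_range()].
#' @param T_grid Dosing-interval grid (h). Default: 400 points over twice the
#'   IV-bolus crossover interval.
#' @param method `"linearity"` or `"scan"`.
#' @param D0_grid Dose grid for the `"scan"` route; default 200 points up to
#'   `2 (D_MS - D_me) / F`.
#' @param n_grid Per-period sampling for Mt steady extrema.
#' @return A `pk_edrr` tibble with columns `T`, `f_lo`, `f_hi`. Intervals
#'   where the band is empty (`f_lo >= f_hi`) remain in the table; the
#'   region is where `f_lo < f_hi`.
#' @export
edrr_numerical <- function(params, range, T_grid = NULL,
                           method = c("linearity", "scan"), D0_grid = NULL,
                           n_grid = 2000) {
  stopifnot(inherits(params, "pk_params"), inherits(range, "therapeutic_range"))
  method <- match.arg(method)
  ke <- params$k_e; F <- params$F
  if (is.null(T_grid)) {
    T_grid <- default_T_grid(log(range$D_MS / range$D_me) / ke)
  }
  if (method == "linearity") {
    ext <- purrr::map_dfr(T_grid, function(T) {
      steady_extrema(params, pk_regimen("Beq", D0 = 1, T = T), n_grid = n_grid)
    })
    df <- tibble(T = T_grid,
                 f_lo = range$D_me / ext$a_min,
                 f_hi = range$D_MS / ext$a_max)
  } else {
    if (is.null(D0_grid)) {
      D0_grid <- seq_len(200) * (2 * (range$D_MS - range$D_me) / F) / 200
    }
    rows <- lapply(T_grid, function(T) {
      ex <- purrr::map_dfr(D0_grid, function(D0) {
        steady_extrema(params, pk_regimen("Beq", D0 = D0, T = T),
                       n_grid = n_grid)
      })
      tibble(T = T,
             f_lo = D0_grid[which.min(abs(ex$a_min - range$D_me))],
             f_hi = D0_grid[which.min(abs(ex$a_max - range$D_MS))])
    })
    df <- dplyr::bind_rows(rows)
  }
  new_edrr(df, paste0("numerical_", params$model), params, range)
}

#' Classify a dosing regimen against a therapeutic range
#'
#' Compares the steady-state extrema of the central drug level with the
#' therapeutic range and returns one of four verdicts: `"acceptable"`
#' (entirely within the range), `"unsafe"` (peak overshoots `D_MS`),
#' `"ineffective"` (trough undershoots `D_me`), or `"both"`.
#'
#' @param params A [pk_params()] object.
#' @param regimen A repeated-dosing [pk_regimen()].
#' @param range A [therapeutic_range()].
#' @return A one-row tibble: `verdict`, `a_min`, `a_max`, `D_me`, `D_MS`.
#' @export
classify_regimen <- function(params, regimen, range) {
  stopifnot(inherits(range, "therapeutic_range"))
  ex <- steady_extrema(params, regimen)
  unsafe <- ex$a_max >= range$D_MS
  ineffective <- ex$a_min <= range$D_me
  verdict <- if (unsafe && ineffective) "both"
  else if (unsafe) "unsafe"
  else if (ineffective) "ineffective"
  else "acceptable"
  tibble(verdict = verdict, a_min = ex$a_min, a_max = ex$a_max,
         D_me = range$D_me, D_MS = range$D_MS)
}

#' Write an EDRR to CSV
#'
#' Long-format CSV: `(T, f_lo, f_hi)`, preceded by the slice parameter column
#' (`D_L` or `t_f`) for three-parameter regions.
#'
#' @param x A `pk_edrr` object.
#' @param path Output file path.
#' @return `x`, invisibly.
#' @export
write_edrr_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(x)
}
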
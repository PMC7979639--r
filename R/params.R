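#' Pharmacokinetic model parameters
#'
#' Constructs a validated parameter set for one of the three model topologies:
#'
#' * `"M1"` — one-compartment IV model: drug appears directly in the central
#'   compartment and is eliminated at first-order rate `k_e`.
#' * `"M2"` — two-compartment oral model: drug enters an absorption
#'   compartment (e.g. the GI tract), transfers to the central compartment at
#'   rate `k_a`, and is eliminated at rate `k_e`.
#' * `"Mt"` — transit-compartment model: a cascade of `n` transit
#'   compartments (rate `k` each) feeds the absorption compartment, producing
#'   a smoothed, gamma-shaped absorption delay with mean transit time
#'   `MTT = n / k`.
#'
#' All closed-form solutions for `M2`/`Mt` have denominators in the pairwise
#' rate differences, so exactly (or nearly) coincident rates are rejected: for
#' `M2` we require `k_a != k_e`, and for `Mt` additionally `k != k_a` and
#' `k != k_e`, each to within `rate_tol` relative proximity.
#'
#' @param model One of `"M1"`, `"M2"`, `"Mt"`.
#' @param k_e Elimination rate constant (1/h). Required, positive.
#' @param k_a Absorption rate constant (1/h). Required for `M2` and `Mt`.
#' @param k Transit rate constant (1/h). Required for `Mt`.
#' @param n Number of transit compartments (positive integer). Required for `Mt`.
#' @param F Bioavailability fraction in (0, 1]; the first compartment of the
#'   cascade receives the effective dose `F * dose`.
#' @param rate_tol Relative proximity below which two rate constants are
#'   treated as coincident and an error is raised. Default `1e-6`.
#'
#' @return An object of class `pk_params` (a named list) with the validated
#'   fields plus `MTT = n / k` for `Mt`.
#'
#' @examples
#' pk_params("M1", k_e = 0.0692)
#' pk_params("Mt", k_e = 0.96, k_a = 9.11, k = 12.76, n = 10, F = 0.69)
#' @export
pk_params <- function(model = c("M1", "M2", "Mt"), k_e, k_a = NULL, k = NULL,
                      n = NULL, F = 1, rate_tol = 1e-6) {
  model <- match.arg(model)
  check_positive_scalar(k_e, "k_e")
  if (!is.numeric(F) || length(F) != 1 || !is.finite(F) || F <= 0 || F > 1) {
    abort("`F` must be a single value in (0, 1].", class = "transitpk_domain_error")
  }
  if (model %in% c("M2", "Mt")) {
    if (is.null(k_a)) {
      abort("`k_a` is required for models M2 and Mt.",
            class = "transitpk_domain_error")
    }
    check_positive_scalar(k_a, "k_a")
    check_rates_distinct(k_a, k_e, "k_a", "k_e", rate_tol)
    if (k_a < k_e) {
      warn(paste0("k_a < k_e: the usual ordering for these models is ",
                  "k_a > k_e; the solutions remain valid but absorption is ",
                  "rate-limiting (flip-flop kinetics)."))
    }
  }
  if (model == "Mt") {
    if (is.null(k) || is.null(n)) {
      abort("`k` and `n` are required for model Mt.",
            class = "transitpk_domain_error")
    }
    check_positive_scalar(k, "k")
    if (!is.numeric(n) || length(n) != 1 || !is.finite(n) || n < 1 ||
        n != round(n)) {
      abort("`n` must be a positive integer.", class = "transitpk_domain_error")
    }
    n <- as.integer(n)
    check_rates_distinct(k, k_a, "k", "k_a", rate_tol)
    check_rates_distinct(k, k_e, "k", "k_e", rate_tol)
  }
  out <- list(model = model, k_e = k_e, k_a = k_a, k = k, n = n, F = F,
              MTT = if (model == "Mt") n / k else NULL)
  structure(out, class = "pk_params")
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name),
          class = "transitpk_domain_error")
  }
  invisible(x)
}

check_rates_distinct <- function(a, b, na, nb, tol) {
  if (abs(a - b) / max(a, b) < tol) {
    abort(sprintf(
      "Rate constants %s and %s coincide within relative tolerance %g; the closed-form solutions are singular there. Perturb one of them.",
      na, nb, tol), class = "transitpk_rate_coincidence_error")
  }
  invisible(NULL)
}

#' Dosing regimen description
#'
#' Constructs a validated dosing regimen of one of five kinds:
#'
#' * `"B1"` — a single bolus dose `D0` at `t = 0`.
#' * `"Beq"` — equi-bolus dosing: dose `D0` at `t = 0, T, 2T, ...` (`M` doses).
#' * `"BeqL"` — equi-bolus dosing with a loading dose `D_L >= D0` replacing the
#'   first dose.
#' * `"Iinf"` — a single continuous infusion at rate `k_in` from `t = 0`.
#' * `"Ieq"` — equi-infusion dosing: infusion at rate `k_in`, on for `t_f`,
#'   off for `T - t_f`, repeated every `T` (`M` infusions).
#'
#' @param kind Regimen kind, one of `"B1"`, `"Beq"`, `"BeqL"`, `"Iinf"`, `"Ieq"`.
#' @param D0 Bolus dose (mg); required for bolus kinds.
#' @param T Dosing interval (h); required for repeated kinds.
#' @param M Number of doses: a positive integer, or `Inf` to request the
#'   periodic steady state. An infinite `M` is only meaningful to steady-state
#'   evaluators and is rejected by finite-sum transient solvers.
#' @param D_L Loading dose (mg), `BeqL` only; must satisfy `D_L >= D0`.
#' @param k_in Infusion rate (mg/h), infusion kinds only.
#' @param t_f Infusion-on duration (h), `Ieq` only; must satisfy `0 < t_f < T`.
#'
#' @return An object of class `pk_regimen`.
#'
#' @examples
#' pk_regimen("Beq", D0 = 500, T = 12, M = 10)
#' pk_regimen("Ieq", k_in = 41.67, t_f = 3, T = 6, M = 20)
#' @export
pk_regimen <- function(kind = c("B1", "Beq", "BeqL", "Iinf", "Ieq"),
                       D0 = NULL, T = NULL, M = Inf, D_L = NULL,
                       k_in = NULL, t_f = NULL) {
  kind <- match.arg(kind)
  shape_error <- function(msg) abort(msg, class = "transitpk_regimen_error")
  if (kind %in% c("B1", "Beq", "BeqL")) {
    if (is.null(D0)) shape_error(sprintf("`D0` is required for kind %s.", kind))
    check_positive_scalar(D0, "D0")
  }
  if (kind %in% c("Beq", "BeqL", "Ieq")) {
    if (is.null(T)) shape_error(sprintf("`T` is required for kind %s.", kind))
    check_positive_scalar(T, "T")
    if (!(is.infinite(M) || (is.numeric(M) && length(M) == 1 && M >= 1 &&
                             M == round(M)))) {
      shape_error("`M` must be a positive integer or Inf.")
    }
  }
  if (kind == "B1") M <- 1
  if (kind == "BeqL") {
    if (is.null(D_L)) shape_error("`D_L` is required for kind BeqL.")
    check_positive_scalar(D_L, "D_L")
    if (D_L < D0) shape_error("Loading dose `D_L` must be >= `D0`.")
  }
  if (kind %in% c("Iinf", "Ieq")) {
    if (is.null(k_in)) shape_error(sprintf("`k_in` is required for kind %s.", kind))
    check_positive_scalar(k_in, "k_in")
  }
  if (kind == "Iinf") M <- 1
  if (kind == "Ieq") {
    if (is.null(t_f)) shape_error("`t_f` is required for kind Ieq.")
    check_positive_scalar(t_f, "t_f")
    if (t_f >= T) shape_error("`t_f` must satisfy 0 < t_f < T.")
  }
  structure(list(kind = kind, D0 = D0, T = T,
                 M = if (is.infinite(M)) Inf else as.integer(M),
                 D_L = D_L, k_in = k_in, t_f = t_f),
            class = "pk_regimen")
}

#' Therapeutic range
#'
#' A therapeutic range for central-compartment drug amount: the treatment is
#' acceptable when `D_me < a_c < D_MS` throughout the (steady-state) dosing
#' interval. Amounts, not concentrations: for a known central volume `V`,
#' divide by `V` to convert.
#'
#' @param D_me Minimum effective level (mg), positive.
#' @param D_MS Maximum safe level (mg), `> D_me`.
#' @return An object of class `therapeutic_range`.
#' @examples
#' therapeutic_range(300, 1000)
#' @export
therapeutic_range <- function(D_me, D_MS) {
  check_positive_scalar(D_me, "D_me")
  check_positive_scalar(D_MS, "D_MS")
  if (D_me >= D_MS) {
    abort("`D_me` must be strictly less than `D_MS`.",
          class = "transitpk_domain_error")
  }
  structure(list(D_me = D_me, D_MS = D_MS), class = "therapeutic_range")
}

#' Validate a parameter/regimen pair
#'
#' Checks that a [pk_params()] set and a [pk_regimen()] are individually valid
#' and mutually compatible (e.g. infusion regimens are only defined for the
#' one-compartment model), and returns the normalised pair. Every solver calls
#' this before computing anything.
#'
#' @param params A [pk_params()] object.
#' @param regimen A [pk_regimen()] object.
#' @return Invisibly, `list(params = params, regimen = regimen)`.
#' @export
validate_pair <- function(params, regimen) {
  if (!inherits(params, "pk_params")) {
    abort("`params` must be created with pk_params().",
          class = "transitpk_domain_error")
  }
  if (!inherits(regimen, "pk_regimen")) {
    abort("`regimen` must be created with pk_regimen().",
          class = "transitpk_regimen_error")
  }
  if (regimen$kind %in% c("Iinf", "Ieq") && params$model != "M1") {
    abort("Infusion regimens are only implemented for model M1.",
          class = "transitpk_regimen_error")
  }
  invisible(list(params = params, regimen = regimen))
}

#' Time since the j-th dose
#'
#' For equi-dosing with interval `T`, the time elapsed since dose `j` is
#' `t_j = t - (j - 1) * T`. Terms with negative `t_j` are masked by the
#' Heaviside factor in the solution sums. Throughout the package the Heaviside
#' convention is `H(0) = 1`: a bolus administered at `t = jT` is included at
#' that instant, so sampled values at dose times are post-dose values.
#'
#' @param t Time(s) (h).
#' @param j Dose index, `j >= 1`.
#' @param T Dosing interval (h).
#' @return `t - (j - 1) * T`, vectorised over `t`.
#' @examples
#' time_since_dose(24, 3, 12) # 0 (exactly at the 3rd dose)
#' @export
time_since_dose <- function(t, j, T) {
  if (any(j < 1)) abort("`j` must be >= 1.", class = "transitpk_domain_error")
  t - (j - 1) * T
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf("<pk_params> model %s\n", x$model))
  flds <- c("k_e", "k_a", "k", "n", "F", "MTT")
  for (f in flds) {
    if (!is.null(x[[f]])) cat(sprintf("  %-4s = %g\n", f, x[[f]]))
  }
  invisible(x)
}

#' @export
print.pk_regimen <- function(x, ...) {
  cat(sprintf("<pk_regimen> kind %s\n", x$kind))
  for (f in c("D0", "T", "M", "D_L", "k_in", "t_f")) {
    if (!is.null(x[[f]])) cat(sprintf("  %-4s = %g\n", f, x[[f]]))
  }
  invisible(x)
}

#' @export
print.therapeutic_range <- function(x, ...) {
  cat(sprintf("<therapeutic_range> (%g, %g) mg\n", x$D_me, x$D_MS))
  invisible(x)
}

#' Read a PK configuration from JSON
#'
#' Reads a JSON file with up to three top-level blocks: `params`, `regimen`
#' and `range`, whose fields are the arguments of [pk_params()],
#' [pk_regimen()] and [therapeutic_range()] respectively. Key validation is
#' strict: unknown keys in any block are an error.
#'
#' @param path Path to a JSON file.
#' @return A list with elements `params`, `regimen` and `range` (those present
#'   in the file), already validated.
#' @export
read_pk_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known_blocks <- c("params", "regimen", "range")
  extra <- setdiff(names(cfg), known_blocks)
  if (length(extra)) {
    abort(sprintf("Unknown top-level config keys: %s",
                  paste(extra, collapse = ", ")),
          class = "transitpk_config_error")
  }
  strict_call <- function(block, fn, allowed) {
    bad <- setdiff(names(block), allowed)
    if (length(bad)) {
      abort(sprintf("Unknown config keys: %s", paste(bad, collapse = ", ")),
            class = "transitpk_config_error")
    }
    if (!is.null(block$M) && identical(block$M, "infinite")) block$M <- Inf
    do.call(fn, block)
  }
  out <- list()
  if (!is.null(cfg$params)) {
    out$params <- strict_call(cfg$params, pk_params,
                              c("model", "k_e", "k_a", "k", "n", "F", "rate_tol"))
  }
  if (!is.null(cfg$regimen)) {
    out$regimen <- strict_call(cfg$regimen, pk_regimen,
                               c("kind", "D0", "T", "M", "D_L", "k_in", "t_f"))
  }
  if (!is.null(cfg$range)) {
    out$range <- strict_call(cfg$range, therapeutic_range, c("D_me", "D_MS"))
  }
  if (!is.null(out$params) && !is.null(out$regimen)) {
    validate_pair(out$params, out$regimen)
  }
  out
}
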
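# Synthetic observation generator and the catalog of worked-example
# parameter settings used across the package's examples and tests.

#' Synthetic single-dose observations (glibenclamide-like)
#'
#' Generates noisy central-compartment observations from the exact
#' transit-compartment solution, emulating a published single-dose
#' glibenclamide data set: a 3.5 mg oral dose with fitted parameters
#' `k = 12.76`, `k_a = 9.11`, `k_e = 0.96` (1/h), `F = 0.69` and `n = 10`
#' transit compartments. The sample-time layout (dense early, sparse late
#' over 0-8 h) is a fixture convention resembling typical single-dose PK
#' sampling; the exact times of the original experiment are not reproduced.
#'
#' Noise is multiplicative lognormal with mean correction: each observation
#' is the true curve times `exp(sigma Z - sigma^2/2)` with
#' `sigma^2 = log(1 + CV^2)`, so the expected observation equals the true
#' value and amounts stay positive. `noise_cv = 0` returns the exact
#' solution at the sample times. Regeneration with the same seed is
#' bit-identical; the caller's RNG state is untouched.
#'
#' @param seed Integer seed for the noise draws.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 5%).
#' @param times Sample times (h); default 12 points over 0.25-8 h.
#' @param true_params A [pk_params()] object to simulate from; default the
#'   glibenclamide-like setting above.
#' @param dose Dose (mg).
#' @return A tibble with columns `t`, `amount` and attributes `true_params`,
#'   `dose`, `noise_cv`, `seed`.
#' @examples
#' obs <- simulate_pk_observations(seed = 42)
#' obs
#' @export
simulate_pk_observations <- function(seed, noise_cv = 0.05,
                                     times = c(0.25, 0.5, 0.75, 1, 1.25, 1.5,
                                               2, 2.5, 3, 4, 6, 8),
                                     true_params = NULL, dose = 3.5) {
  if (is.null(true_params)) {
    true_params <- pk_params("Mt", k_e = 0.96, k_a = 9.11, k = 12.76,
                             n = 10, F = 0.69)
  }
  stopifnot(inherits(true_params, "pk_params"), true_params$model == "Mt")
  if (noise_cv < 0) {
    abort("`noise_cv` must be >= 0.", class = "transitpk_domain_error")
  }
  truth <- tcm_central_single(times, true_params$n, true_params$k,
                              true_params$k_a, true_params$k_e,
                              true_params$F, dose)
  amount <- if (noise_cv == 0) truth else {
    sigma <- sqrt(log(1 + noise_cv^2))
    z <- with_seed_(seed, function() rnorm(length(times)))
    truth * exp(sigma * z - sigma^2 / 2)
  }
  structure(tibble(t = times, amount = amount),
            true_params = true_params, dose = dose, noise_cv = noise_cv,
            seed = seed)
}

#' Catalog of worked-example parameter settings
#'
#' Named parameter/regimen/range settings used throughout the package's
#' examples, tests and documentation. Each entry is a list with the
#' applicable subset of `params` ([pk_params()]), `regimen`
#' ([pk_regimen()]), `range` ([therapeutic_range()]) and auxiliary values.
#'
#' Available settings:
#' * `"iv_equibolus"` — one-compartment IV equi-bolus, 500 mg every 12 h,
#'   `k_e = 0.0692`/h (hypothetical drug); loading-dose variant `D_L = 800` mg.
#' * `"iv_infusion"` — one-compartment equi-infusion, 41.67 mg/h on for 3 h
#'   of every 6 h.
#' * `"iv_rapid_bolus"` — 20.83 mg every 0.5 h (high-frequency limit demo).
#' * `"oral_equibolus"` — two-compartment oral, 500 mg every 12 h,
#'   `k_a = 0.7`/h; loading variant 800 mg.
#' * `"transit_single"` — 100-transit cascade, `MTT = 3` h, single 500 mg dose.
#' * `"stirling_comparison"` — `k_a = 9.11`, `k_e = 0.96`/h, `F = 0.69`,
#'   3.5 mg, `MTT = 0.78` h (exact-vs-approximate error study).
#' * `"transit_equidose"` — `n = 10`, `MTT = 3` h, 500 mg every 8 h.
#' * `"glibenclamide_fit"` — the glibenclamide-like fitted setting
#'   (`k = 12.76`, `k_a = 9.11`, `k_e = 0.96`/h, `F = 0.69`, `n = 10`),
#'   3.5 mg every 3 h.
#' * `"glibenclamide_second"` — a second individual's fitted parameters
#'   (`k = 17.59`, `k_a = 0.87`, `k_e = 0.48`/h, `F = 0.37`); simulation
#'   only.
#' * `"iv_range"` — IV EDRR setting: `F = 1`, `k_e = 0.0692`/h, range
#'   (300, 1000) mg.
#' * `"oral_range"` — oral EDRR setting: as above plus `k_a = 0.7`/h.
#' * `"transit_range"` — transit EDRR setting: oral rates, `MTT = 4.4` h
#'   (or `k = 0.45`/h), range (300, 1000) mg.
#' * `"infusion_range"` — infusion EDRR setting: `k_e = 0.2`/h, range
#'   (200, 3000) mg.
#'
#' @param name Setting name; omit to get the vector of available names.
#' @return A named list for the requested setting, or all names.
#' @examples
#' example_settings()
#' example_settings("iv_range")
#' @export
example_settings <- function(name = NULL) {
  catalog <- list(
    iv_equibolus = function() list(
      params = pk_params("M1", k_e = 0.0692, F = 1),
      regimen = pk_regimen("Beq", D0 = 500, T = 12, M = 20),
      loading = pk_regimen("BeqL", D0 = 500, D_L = 800, T = 12, M = 20)),
    iv_infusion = function() list(
      params = pk_params("M1", k_e = 0.0692, F = 1),
      regimen = pk_regimen("Ieq", k_in = 41.67, t_f = 3, T = 6, M = 40)),
    iv_rapid_bolus = function() list(
      params = pk_params("M1", k_e = 0.0692, F = 1),
      regimen = pk_regimen("Beq", D0 = 20.83, T = 0.5, M = 200),
      k_in = 41.67),
    oral_equibolus = function() list(
      params = pk_params("M2", k_e = 0.0692, k_a = 0.7, F = 1),
      regimen = pk_regimen("Beq", D0 = 500, T = 12, M = 20),
      loading = pk_regimen("BeqL", D0 = 500, D_L = 800, T = 12, M = 20)),
    transit_single = function() list(
      params = pk_params("Mt", k_e = 0.0692, k_a = 0.7, k = 100 / 3, n = 100,
                         F = 1),
      regimen = pk_regimen("B1", D0 = 500)),
    stirling_comparison = function() list(
      k_a = 9.11, k_e = 0.96, F = 0.69, D0 = 3.5, MTT = 0.78),
    transit_equidose = function() list(
      params = pk_params("Mt", k_e = 0.0692, k_a = 0.7, k = 10 / 3, n = 10,
                         F = 1),
      regimen = pk_regimen("Beq", D0 = 500, T = 8, M = 6)),
    glibenclamide_fit = function() list(
      params = pk_params("Mt", k_e = 0.96, k_a = 9.11, k = 12.76, n = 10,
                         F = 0.69),
      regimen = pk_regimen("Beq", D0 = 3.5, T = 3, M = 10)),
    glibenclamide_second = function() list(
      params = pk_params("Mt", k_e = 0.48, k_a = 0.87, k = 17.59, n = 10,
                         F = 0.37),
      regimen = pk_regimen("Beq", D0 = 3.5, T = 3, M = 10)),
    iv_range = function() list(
      params = pk_params("M1", k_e = 0.0692, F = 1),
      range = therapeutic_range(300, 1000)),
    oral_range = function() list(
      params = pk_params("M2", k_e = 0.0692, k_a = 0.7, F = 1),
      range = therapeutic_range(300, 1000)),
    transit_range = function() list(
      params = pk_params("M2", k_e = 0.0692, k_a = 0.7, F = 1),
      MTT = 4.4, k_fixed = 0.45,
      range = therapeutic_range(300, 1000)),
    infusion_range = function() list(
      params = pk_params("M1", k_e = 0.2, F = 1),
      range = therapeutic_range(200, 3000),
      t_f = c(1, 2.5, 4)))
  if (is.null(name)) return(names(catalog))
  if (!name %in% names(catalog)) {
    abort(sprintf("Unknown setting '%s'. Available: %s", name,
                  paste(names(catalog), collapse = ", ")),
          class = "transitpk_lookup_error")
  }
  catalog[[name]]()
}

#' Write / read observations CSV
#'
#' Two-column CSV `(t, amount)` matching the fitting functions' input.
#'
#' @param observations Data frame with columns `t`, `amount`.
#' @param path File path.
#' @return The observations tibble (invisibly for the writer).
#' @export
write_observations_csv <- function(observations, path) {
  write.csv(as.data.frame(observations)[, c("t", "amount")], path,
            row.names = FALSE)
  invisible(observations)
}

#' @rdname write_observations_csv
#' @export
read_observations_csv <- function(path) {
  as_tibble(read.csv(path))[, c("t", "amount")]
}
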
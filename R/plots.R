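# ggplot2 display methods for time courses, EDRRs and fits.

#' Plot a drug level time course
#'
#' One line per compartment; for transit cascades with many compartments,
#' only the absorption and central compartments plus a handful of transit
#' compartments are drawn by default.
#'
#' @param object A `pk_timecourse` tibble.
#' @param compartments Optional character vector restricting the
#'   compartments drawn.
#' @param max_transit Maximum number of transit compartments to draw when
#'   `compartments` is not given.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pk_timecourse <- function(object, compartments = NULL,
                                   max_transit = 4, ...) {
  df <- as_tibble(object)
  if (is.null(compartments)) {
    comps <- unique(df$compartment)
    tr <- grep("^transit_", comps, value = TRUE)
    if (length(tr) > max_transit) {
      keep_tr <- tr[unique(round(seq(1, length(tr), length.out = max_transit)))]
      comps <- c(setdiff(comps, tr), keep_tr)
    }
    compartments <- comps
  }
  df <- dplyr::filter(df, .data$compartment %in% compartments)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$amount,
                                   colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "drug amount (mg)",
                  colour = "compartment") +
    ggplot2::theme_minimal()
}

#' Plot an equi-dosing regimen region
#'
#' Shades the petal (or chopped petal) between the boundary curves
#' `f_lo(T)` and `f_hi(T)` where the band is non-empty; three-parameter
#' regions are facetted by the slice variable.
#'
#' @param object A `pk_edrr` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pk_edrr <- function(object, ...) {
  df <- as_tibble(object)
  slice_var <- attr(object, "slice_var")
  y_lab <- if (identical(attr(object, "kind"), "iv_infusion")) {
    "infusion rate k_in (mg/h)"
  } else "dose D0 (mg)"
  region <- dplyr::filter(df, .data$f_lo < .data$f_hi)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$T)) +
    ggplot2::geom_ribbon(data = region,
                         ggplot2::aes(ymin = .data$f_lo, ymax = .data$f_hi),
                         fill = "steelblue", alpha = 0.35) +
    ggplot2::geom_line(ggplot2::aes(y = .data$f_lo), colour = "firebrick") +
    ggplot2::geom_line(ggplot2::aes(y = .data$f_hi), colour = "navy") +
    ggplot2::labs(x = "dosing interval T (h)", y = y_lab) +
    ggplot2::theme_minimal()
  if (!is.null(slice_var)) {
    p <- p + ggplot2::facet_wrap(stats::as.formula(paste("~", slice_var)),
                                 labeller = "label_both")
  }
  p
}

#' Plot a fitted model against its observations
#'
#' Fitted central-compartment curve with the observations overlaid; for a
#' transit-compartment fit the SSE profile over the swept `n` is available
#' via `which = "sweep"`.
#'
#' @param object A `pk_fit` object.
#' @param which `"fit"` (curve + data) or `"sweep"` (SSE versus `n`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pk_fit <- function(object, which = c("fit", "sweep"), ...) {
  which <- match.arg(which)
  if (which == "sweep") {
    if (object$model != "tcm") {
      abort("The SSE sweep plot is only available for transit-compartment fits.",
            class = "transitpk_domain_error")
    }
    return(
      ggplot2::ggplot(object$sweep, ggplot2::aes(x = .data$n, y = .data$sse)) +
        ggplot2::geom_point() + ggplot2::geom_line() +
        ggplot2::scale_y_log10() +
        ggplot2::labs(x = "number of transit compartments n",
                      y = "sum of squared errors") +
        ggplot2::theme_minimal())
  }
  obs <- object$observations
  tt <- seq(0, max(obs$t) * 1.05, length.out = 400)
  pred <- if (object$model == "tcm") {
    p <- object$params
    tcm_central_single(tt, p$n, p$k, p$k_a, p$k_e, p$F, object$dose)
  } else {
    p <- object$params
    lag_ac_single(tt, p$k_a, p$k_e, p$F, object$dose, p$t_lag)
  }
  ggplot2::ggplot(tibble(t = tt, amount = pred),
                  ggplot2::aes(x = .data$t, y = .data$amount)) +
    ggplot2::geom_line(colour = "navy") +
    ggplot2::geom_point(data = obs, colour = "firebrick") +
    ggplot2::labs(x = "time (h)", y = "drug amount (mg)") +
    ggplot2::theme_minimal()
}
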
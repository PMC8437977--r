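#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_line geom_point
#'   geom_abline labs lims theme_minimal
#' @export
ggplot2::autoplot

#' Plot a DVH in cumulative form
#'
#' @param object A [dvh()].
#' @param ... Unused.
#' @return A ggplot of the cumulative dose-volume curve.
#' @method autoplot dvh
#' @export
autoplot.dvh <- function(object, ...) {
  cum <- dvh_cumulative(object)
  ggplot(cum, aes(x = .data$dose_gy, y = .data$volume_fraction)) +
    geom_step(direction = "hv") +
    labs(
      x = "Dose (Gy)", y = "Fractional volume receiving ≥ dose",
      title = sprintf("Cumulative DVH — %s", attr(object, "structure_name"))
    ) +
    theme_minimal()
}

#' Plot NTCP dose-response curves
#'
#' Draws the modelled complication probability against the dose metric
#' (gEUD, or mean heart dose for n = 1 and single-predictor logistic
#' models) for one or more models.
#'
#' @param models Named list of [lkb_params()] or single-predictor
#'   [logistic_model()] objects.
#' @param dose_range Dose axis range in Gy.
#' @param step Curve resolution in Gy.
#' @return A ggplot.
#' @export
plot_ntcp_curves <- function(models, dose_range = c(0, 70), step = 0.25) {
  if (is.null(names(models))) abort_contract("models must be named")
  doses <- seq(dose_range[1], dose_range[2], by = step)
  curves <- purrr::imap(models, function(m, nm) {
    p <- if (inherits(m, "lkb_params")) {
      probit_ntcp(doses, m)
    } else if (inherits(m, "logistic_model") && length(m$coefficients) == 1L) {
      plogis(m$intercept + m$coefficients[[1L]] * doses)
    } else {
      abort_contract("plot_ntcp_curves needs lkb_params or 1-predictor logistic models")
    }
    tibble::tibble(model = nm, dose_gy = doses, ntcp = p)
  }) |>
    dplyr::bind_rows()
  ggplot(curves, aes(x = .data$dose_gy, y = .data$ntcp, colour = .data$model)) +
    geom_line() +
    lims(y = c(0, 1)) +
    labs(x = "Dose metric (Gy)", y = "NTCP", colour = NULL) +
    theme_minimal()
}

#' Calibration plot of a Hosmer-Lemeshow test
#'
#' Observed event rate against mean predicted probability per risk group,
#' with the identity line of perfect calibration.
#'
#' @param object An `hl_test` from [hosmer_lemeshow()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hl_test
#' @export
autoplot.hl_test <- function(object, ...) {
  ggplot(object$bins, aes(x = .data$mean_predicted, y = .data$observed_rate)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    geom_point(aes(size = .data$n)) +
    lims(x = c(0, 1), y = c(0, 1)) +
    labs(
      x = "Mean predicted probability", y = "Observed event rate",
      size = "Patients"
    ) +
    theme_minimal()
}
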
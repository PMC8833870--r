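#' Plot a fitted time-activity curve
#'
#' Measured samples with the fitted sum-of-exponentials overlaid on a dense
#' grid from time zero (showing the extrapolated uptake segment).
#'
#' @param object An `exp_fit` from [fit_exponential()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot exp_fit
#' @export
autoplot.exp_fit <- function(object, ...) {
  tt <- seq(0, max(object$data$time_h) * 1.1, length.out = 300)
  pred <- tibble::tibble(time_h = tt, value = predict(object, tt))
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time_h, .data$value)) +
    ggplot2::geom_line(data = pred, colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Time post-injection (h)", y = "Activity",
                  title = sprintf("%d-term exponential fit", nrow(object$terms))) +
    ggplot2::theme_minimal()
}

#' Plot organ doses with per-source contributions
#'
#' Stacked bars of each target's normalized dose split by source region,
#' which makes cross-irradiation (e.g. bone surfaces into red marrow)
#' directly visible.
#'
#' @param object An `organ_dose_result` from [organ_doses()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot organ_dose_result
#' @export
autoplot.organ_dose_result <- function(object, ...) {
  ggplot2::ggplot(object$contributions,
                  ggplot2::aes(.data$target, .data$dose_Gy_per_GBq,
                               fill = .data$source)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Normalized dose (Gy/GBq)",
                  fill = "Source region") +
    ggplot2::theme_minimal()
}

#' Plot cohort organ doses across patients
#'
#' Dot plot of per-patient normalized organ doses from a cohort report,
#' one panel layout mirroring the organ table.
#'
#' @param report A `cohort_report` from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_cohort_doses <- function(report) {
  long <- report$organ_table |>
    dplyr::filter(!.data$quantity %in% c("mta_GBq")) |>
    tidyr::pivot_longer(-dplyr::all_of(c("quantity", "Median", "Mean", "SD")),
                        names_to = "patient_id", values_to = "dose") |>
    dplyr::filter(is.finite(.data$dose))
  ggplot2::ggplot(long, ggplot2::aes(.data$patient_id, .data$dose)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity), scales = "free_y") +
    ggplot2::labs(x = "Patient", y = "Normalized dose (Gy/GBq)") +
    ggplot2::theme_minimal()
}
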
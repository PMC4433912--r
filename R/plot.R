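# long format used by the plotting helpers: one row per (batch, time, variable)
pivot_states <- function(data) {
  data |>
    tidyr::pivot_longer(dplyr::all_of(unname(state_cols)),
                        names_to = "variable", values_to = "value") |>
    dplyr::mutate(variable = names(state_cols)[match(.data$variable,
                                                     state_cols)])
}

#' Plot the measured trajectories of a batch dataset
#'
#' One panel per state variable (cell mass X in g/L, lactose S in g/L,
#' dissolved oxygen C in mg/L), one line per batch.
#'
#' @param data A batch dataset tibble.
#' @return A ggplot object.
#' @export
plot_batches <- function(data) {
  data <- validate_dataset(data)
  pivot_states(data) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$time_h, y = .data$value,
                                 group = .data$batch,
                                 colour = factor(.data$batch))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "concentration", colour = "batch") +
    ggplot2::theme_minimal()
}

#' Plot one-step predictions against the measurements
#'
#' Overlays a model's one-step-ahead predictions on the measured values,
#' one panel per state variable.
#'
#' @param data The measured batch dataset tibble.
#' @param predictions A one-step prediction tibble ([nfn_predict()] or
#'   [conventional_predict()]).
#' @param model_name Label used in the legend.
#' @return A ggplot object.
#' @export
plot_one_step <- function(data, predictions, model_name = "model") {
  data <- validate_dataset(data)
  meas <- pivot_states(data) |> dplyr::mutate(series = "measured")
  pred <- pivot_states(predictions[, c("batch", "time_h",
                                       unname(state_cols))]) |>
    dplyr::mutate(series = model_name)
  dplyr::bind_rows(meas, pred) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$time_h, y = .data$value,
                                 colour = .data$series,
                                 group = interaction(.data$batch,
                                                     .data$series))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "concentration", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn nfn_train Overlay of the fit's one-step predictions on its
#'   training data.
#' @param object An `nfn_fit`.
#' @export
autoplot.nfn_fit <- function(object, ...) {
  plot_one_step(object$data, nfn_predict(object$model, object$data),
                model_name = "neuro-fuzzy")
}

#' @describeIn select_hidden_size Degree of satisfaction alpha against the
#'   candidate hidden size.
#' @param object An `nfn_selection`.
#' @param ... Unused.
#' @export
autoplot.nfn_selection <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$n_hidden, y = .data$alpha)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$acceptance_alpha,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$n_hidden, linetype = "dotted") +
    ggplot2::labs(x = "hidden neurons (J_m)",
                  y = "degree of satisfaction (alpha)") +
    ggplot2::theme_minimal()
}
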
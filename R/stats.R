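#' Model-adequacy statistics for measured vs predicted series
#'
#' Three statistics summarize how well a model's one-step predictions track
#' the measurements of a state variable:
#'
#' * `r_squared()` — the experimental correlation quotient, the squared
#'   Pearson correlation between measured and predicted values (1 = perfect
#'   linear agreement).
#' * `fisher_FE()` — the experimental Fisher ratio, the sample-variance
#'   quotient `var(measured) / var(predicted)`; 1 for a perfect fit, and
#'   compared against the theoretical F critical value for adequacy.
#' * `relative_error_SL()` — the relative error in percent,
#'   `100 * sqrt(mean(((y - yhat) / scale_max)^2))` with `scale_max` the
#'   largest absolute measured value, so residuals are judged against the
#'   variable's full scale.
#'
#' @param measured,predicted Numeric vectors of equal length (n >= 3).
#' @return A scalar statistic.
#' @export
r_squared <- function(measured, predicted) {
  check_series(measured, predicted)
  if (var(measured) == 0) {
    abort("`measured` is constant; the correlation quotient is undefined.")
  }
  if (var(predicted) == 0) {
    abort("`predicted` is constant; the correlation quotient is undefined.")
  }
  cor(measured, predicted)^2
}

#' @rdname r_squared
#' @export
fisher_FE <- function(measured, predicted) {
  check_series(measured, predicted)
  vp <- var(predicted)
  if (vp == 0) abort("`predicted` has zero variance; F_E is undefined.")
  var(measured) / vp
}

#' @rdname r_squared
#' @param scale_max Positive scale for the residuals; defaults to
#'   `max(abs(measured))`.
#' @export
relative_error_SL <- function(measured, predicted,
                              scale_max = max(abs(measured))) {
  check_series(measured, predicted, min_n = 1L)
  if (!is.finite(scale_max) || scale_max <= 0) {
    abort("`scale_max` must be strictly positive.")
  }
  100 * sqrt(mean(((measured - predicted) / scale_max)^2))
}

check_series <- function(measured, predicted, min_n = 3L,
                         call = rlang::caller_env()) {
  if (length(measured) != length(predicted)) {
    abort("`measured` and `predicted` must have equal length.", call = call)
  }
  if (length(measured) < min_n) {
    abort(paste0("At least ", min_n, " points are required."), call = call)
  }
  if (anyNA(measured) || anyNA(predicted)) {
    abort("Series must not contain missing values.", call = call)
  }
}

#' Theoretical F critical value
#'
#' Upper-tail quantile of the F distribution, used as the adequacy
#' threshold: a model is adequate for a variable when its experimental
#' Fisher ratio stays below this value. At significance level 0.05 this
#' gives 3.49 for (3, 12) and 4.76 for (3, 6) degrees of freedom.
#'
#' @param df1,df2 Degrees of freedom (>= 1).
#' @param alpha Upper-tail significance level in (0, 1).
#' @return The value v with `P(F(df1, df2) > v) = alpha`.
#' @export
#' @examples
#' f_critical(3, 12)
#' f_critical(3, 6)
f_critical <- function(df1, df2, alpha = 0.05) {
  if (df1 < 1 || df2 < 1) abort("Degrees of freedom must be >= 1.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  qf(1 - alpha, df1, df2)
}

#' Adequacy thresholds for the model-comparison report
#'
#' @param df1,df2 Degrees of freedom of the F test (defaults follow the
#'   study's printed threshold F(3, 12)).
#' @param alpha Significance level.
#' @return A list of class `adequacy_thresholds` with the critical value.
#' @export
adequacy_thresholds <- function(df1 = 3, df2 = 12, alpha = 0.05) {
  structure(list(f_critical = f_critical(df1, df2, alpha),
                 df1 = df1, df2 = df2, alpha = alpha),
            class = "adequacy_thresholds")
}

#' Compare one or more models' one-step predictions against measurements
#'
#' Computes, per model and per state variable (X, S, C), the correlation
#' quotient, the experimental Fisher ratio and the relative error, plus an
#' adequacy flag `F_E < f_critical`. When at least two models are supplied
#' a winner per variable and metric is attached (attribute `"winners"`):
#' larger is better for R^2, smaller for S_L, and F_E is judged by its
#' deviation from the ideal unity ratio.
#'
#' @param data The measured batch dataset tibble.
#' @param predictions A named list of one-step prediction tibbles (columns
#'   `batch`, `time_h`, `X_gL`, `S_gL`, `C_mgL`), as returned by
#'   [nfn_predict()] or [conventional_predict()].
#' @param thresholds An [adequacy_thresholds()] object.
#'
#' @return A tibble with columns `model`, `variable`, `r_squared`, `F_E`,
#'   `S_L_percent`, `adequate`; winners (if any) in `attr(, "winners")`.
#' @export
adequacy_report <- function(data, predictions,
                            thresholds = adequacy_thresholds()) {
  data <- validate_dataset(data)
  if (!is.list(predictions) || length(predictions) == 0L) {
    abort("`predictions` must be a non-empty named list of tibbles.")
  }
  if (is.null(names(predictions)) || any(names(predictions) == "")) {
    abort("Every element of `predictions` must be named after its model.")
  }
  stopifnot(inherits(thresholds, "adequacy_thresholds"))

  tbl <- purrr::imap_dfr(predictions, function(pred, model_name) {
    joined <- dplyr::inner_join(
      data, pred, by = c("batch", "time_h"), suffix = c("", ".pred")
    )
    n_expected <- nrow(data) - dplyr::n_distinct(data$batch)
    if (nrow(joined) != n_expected) {
      abort(paste0("Predictions of model `", model_name, "` do not align ",
                   "with the measurements (matched ", nrow(joined),
                   " of ", n_expected, " transitions)."))
    }
    purrr::map_dfr(names(state_cols), function(v) {
      col <- state_cols[[v]]
      meas <- joined[[col]]
      pr <- joined[[paste0(col, ".pred")]]
      fe <- fisher_FE(meas, pr)
      tibble::tibble(model = model_name, variable = v,
                     r_squared = r_squared(meas, pr),
                     F_E = fe,
                     S_L_percent = relative_error_SL(meas, pr),
                     adequate = fe < thresholds$f_critical)
    })
  })

  if (length(predictions) >= 2L) {
    winners <- tbl |>
      dplyr::group_by(.data$variable) |>
      dplyr::summarise(
        r_squared = .data$model[which.max(.data$r_squared)],
        F_E = .data$model[which.min(abs(.data$F_E - 1))],
        S_L_percent = .data$model[which.min(.data$S_L_percent)],
        .groups = "drop"
      ) |>
      tidyr::pivot_longer(-"variable", names_to = "metric",
                          values_to = "winner")
    attr(tbl, "winners") <- winners
  }
  attr(tbl, "thresholds") <- thresholds
  tbl
}
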
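#' Neuro-fuzzy network configuration
#'
#' Dimensions and reproducibility settings of the three-layer network: INP
#' input signals, a hidden layer of J_m sigmoid neurons with fixed random
#' weights, and OUT piece-wise linear output neurons whose weights are the
#' only trained quantities. The study configuration is INP = 4 (normalized
#' time plus the three state variables), OUT = 3 (next-step X, S, C) and
#' J_m = 5 hidden neurons.
#'
#' @param n_inputs Number of input signals (INP).
#' @param n_outputs Number of output signals (OUT).
#' @param n_hidden Number of hidden neurons (J_m).
#' @param n_timepoints Optional expected number of time points per batch (K);
#'   checked against the data at training time when supplied.
#' @param n_batches Optional expected number of batches (R); checked at
#'   training time when supplied.
#' @param include_bias Whether the constant unit signal I = 1 is appended
#'   both to the hidden-layer input (a bias into each sigmoid neuron) and to
#'   the hidden signal vector (an intercept for each output neuron).
#' @param seed Integer seed for the random hidden weights.
#'
#' @return A list of class `nfn_config`.
#' @export
network_config <- function(n_inputs = 4, n_outputs = 3, n_hidden = 5,
                           n_timepoints = NULL, n_batches = NULL,
                           include_bias = TRUE, seed = 1L) {
  counts <- c(n_inputs, n_outputs, n_hidden)
  if (any(counts < 1)) abort("Network dimensions must all be >= 1.")
  if (!is.null(n_timepoints) && n_timepoints < 2) {
    abort("`n_timepoints` must be >= 2 (at least one transition).")
  }
  structure(list(n_inputs = as.integer(n_inputs),
                 n_outputs = as.integer(n_outputs),
                 n_hidden = as.integer(n_hidden),
                 n_timepoints = if (!is.null(n_timepoints)) as.integer(n_timepoints),
                 n_batches = if (!is.null(n_batches)) as.integer(n_batches),
                 include_bias = isTRUE(include_bias),
                 seed = as.integer(seed)),
            class = "nfn_config")
}

#' Draw the fixed random hidden-layer weights
#'
#' Hidden weights are i.i.d. Uniform(0, 1) and are never trained: together
#' with the sigmoid they provide a random nonlinear feature expansion of the
#' normalized inputs, so that training reduces to one linear solve for the
#' output weights.
#'
#' @param config An [network_config()] object (its `seed` fixes the draw).
#'
#' @return A `n_hidden x (n_inputs + 1)` matrix when `include_bias` is on
#'   (the last column multiplies the unit signal), else `n_hidden x n_inputs`.
#' @export
init_hidden_weights <- function(config) {
  stopifnot(inherits(config, "nfn_config"))
  ncol_w <- config$n_inputs + as.integer(config$include_bias)
  withr::with_seed(config$seed, {
    matrix(runif(config$n_hidden * ncol_w), nrow = config$n_hidden,
           dimnames = list(paste0("h", seq_len(config$n_hidden)), NULL))
  })
}

# resolve an input-recipe token to a column of values for given rows
recipe_values <- function(token, data) {
  switch(token,
    t = data$time_h,
    X = data$X_gL,
    S = data$S_gL,
    C = data$C_mgL,
    one = rep(1, nrow(data)),
    abort(paste0("Unknown input-recipe token `", token,
                 "`; use t, X, S, C or one."))
  )
}

#' Compute the normalization maxima from a training dataset
#'
#' Each input slot and each output variable is divided by its maximum over
#' all batches and time points, mapping the training data into the unit
#' interval expected by the sigmoid/ramp layers.
#'
#' @param data A batch dataset tibble.
#' @param input_recipe Character vector naming what feeds each input slot,
#'   from `"t"` (time), `"X"`, `"S"`, `"C"` and `"one"` (a constant 1).
#'
#' @return A list of class `nfn_normalization` with `input_max` (named per
#'   slot) and `output_max` (named X, S, C).
#' @export
compute_normalization <- function(data, input_recipe = c("t", "X", "S", "C")) {
  data <- validate_dataset(data)
  input_max <- vapply(input_recipe,
                      function(tok) max(recipe_values(tok, data)),
                      numeric(1))
  output_max <- vapply(names(state_cols),
                       function(v) max(data[[state_cols[[v]]]]), numeric(1))
  maxima <- c(input_max, output_max)
  if (any(maxima <= 0)) {
    zero <- names(maxima)[maxima <= 0]
    abort(paste0("Degenerate normalization: slot(s) ",
                 paste0("`", zero, "`", collapse = ", "),
                 " have maximum <= 0."))
  }
  structure(list(input_max = input_max, output_max = output_max,
                 input_recipe = input_recipe),
            class = "nfn_normalization")
}

#' Normalize or restore signal values
#'
#' `normalize_signals()` divides element-wise by the stored maxima;
#' `denormalize_signals()` multiplies back, so the pair is an exact inverse.
#'
#' @param values Numeric vector (or matrix with one column per slot).
#' @param maxima Positive maxima, recycled across matrix rows.
#' @return Values on the normalized (unit-interval) or engineering scale.
#' @export
normalize_signals <- function(values, maxima) {
  if (is.matrix(values)) sweep(values, 2L, maxima, "/") else values / maxima
}

#' @rdname normalize_signals
#' @export
denormalize_signals <- function(values, maxima) {
  if (is.matrix(values)) sweep(values, 2L, maxima, "*") else values * maxima
}

#' Layer transfer functions
#'
#' The hidden layer uses the logistic sigmoid `1 / (1 + exp(-v))`; the output
#' layer uses a piece-wise linear unit ramp, the identity on \[0, 1\] with
#' saturation at 0 and 1 — so outputs are always valid normalized signals.
#'
#' @param v Numeric vector.
#' @return Transformed values in (0, 1) (sigmoid) or \[0, 1\] (ramp).
#' @export
sigmoid_activation <- function(v) plogis(v)

#' @rdname sigmoid_activation
#' @export
piecewise_linear <- function(v) pmin(pmax(v, 0), 1)

#' Construct a neuro-fuzzy network model object
#'
#' Usually created by [nfn_train()]; exposed directly so that models with
#' known weights can be built for simulation studies.
#'
#' @param config An [network_config()].
#' @param normalization An `nfn_normalization` (see [compute_normalization()]).
#' @param hidden Hidden weight matrix, entries in \[0, 1\]
#'   (see [init_hidden_weights()]).
#' @param output Output weight matrix, `(n_hidden + bias) x n_outputs`,
#'   columns ordered (X, S, C).
#'
#' @return A list of class `nfn_model`.
#' @export
nfn_model <- function(config, normalization, hidden, output) {
  stopifnot(inherits(config, "nfn_config"),
            inherits(normalization, "nfn_normalization"))
  bias <- as.integer(config$include_bias)
  if (!is.matrix(hidden) ||
      !all(dim(hidden) == c(config$n_hidden, config$n_inputs + bias))) {
    abort("`hidden` must be a n_hidden x (n_inputs + bias) matrix.")
  }
  if (any(hidden < 0 | hidden > 1)) {
    abort("Hidden weights must lie in [0, 1].")
  }
  if (!is.matrix(output) ||
      !all(dim(output) == c(config$n_hidden + bias, config$n_outputs))) {
    abort("`output` must be a (n_hidden + bias) x n_outputs matrix.")
  }
  if (any(!is.finite(output))) abort("Output weights must be finite.")
  if (length(normalization$input_recipe) != config$n_inputs) {
    abort("`input_recipe` length must equal `n_inputs`.")
  }
  colnames(output) <- names(state_cols)[seq_len(config$n_outputs)]
  structure(list(config = config, normalization = normalization,
                 hidden = hidden, output = output),
            class = "nfn_model")
}

#' @export
print.nfn_model <- function(x, ...) {
  cfg <- x$config
  cat("<nfn_model> ", cfg$n_inputs, " inputs -> ", cfg$n_hidden,
      " sigmoid hidden -> ", cfg$n_outputs, " ramp outputs",
      if (cfg$include_bias) " (+bias)", "\n", sep = "")
  cat("input recipe: ", paste(x$normalization$input_recipe, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# rows of normalized inputs -> matrix of hidden signals (one row per input),
# with the constant intercept column appended when include_bias
hidden_map_matrix <- function(model, U) {
  if (model$config$include_bias) U <- cbind(U, 1)
  x <- plogis(U %*% t(model$hidden))
  if (model$config$include_bias) x <- cbind(x, 1)
  x
}

#' Hidden-layer signals for one normalized input vector
#'
#' Computes `x_j = sigmoid(a_j . u)` for each hidden neuron `j`, where `u`
#' is the normalized input (with the unit bias signal appended when the
#' model uses one). When the model has a bias, a constant 1.0 is also
#' appended to the returned vector, acting as the output layer's intercept
#' signal.
#'
#' @param model An `nfn_model`.
#' @param u Normalized input vector of length `n_inputs`, values in \[0, 1\]
#'   (slightly outside is allowed with a warning).
#' @return Numeric vector of hidden signals.
#' @export
hidden_map <- function(model, u) {
  if (length(u) != model$config$n_inputs) {
    abort(paste0("Input length ", length(u), " does not match n_inputs = ",
                 model$config$n_inputs, "."))
  }
  if (any(u < -1e-8 | u > 1 + 1e-8)) {
    warn("Normalized input outside [0, 1]; hidden map still evaluated.")
  }
  drop(hidden_map_matrix(model, matrix(u, nrow = 1L)))
}

#' Forward pass: normalized input to normalized output
#'
#' `B_j = ramp(w_j . x)` for each output neuron, where `x` are the hidden
#' signals of [hidden_map()].
#'
#' @inheritParams hidden_map
#' @return Normalized output vector in \[0, 1\]^OUT, named (X, S, C).
#' @export
nfn_forward <- function(model, u) {
  x <- hidden_map(model, u)
  setNames(piecewise_linear(drop(x %*% model$output)),
           colnames(model$output))
}

# normalize a matrix of raw inputs per the recipe, clip to [0,1],
# warn when any value overshoots its maximum by more than 10%
normalize_inputs <- function(model, data) {
  recipe <- model$normalization$input_recipe
  U <- vapply(recipe, function(tok) recipe_values(tok, data),
              numeric(nrow(data)))
  U <- matrix(U, nrow = nrow(data),
              dimnames = list(NULL, names(model$normalization$input_max)))
  U <- normalize_signals(U, model$normalization$input_max)
  if (any(U > 1.1)) {
    warn("Input exceeds its normalization maximum by more than 10%; clipped.")
  }
  pmin(pmax(U, 0), 1)
}

#' Predict the state one sampling interval ahead
#'
#' Builds the network input from a measured state record (per the model's
#' input recipe), normalizes, runs the forward pass and maps the output back
#' to engineering units.
#'
#' @param model An `nfn_model`.
#' @param state A one-row data frame (or named list) with `time_h`, `X_gL`,
#'   `S_gL`, `C_mgL`.
#' @param next_time Time stamp of the predicted record, h.
#' @return A one-row tibble (`time_h`, `X_gL`, `S_gL`, `C_mgL`).
#' @export
predict_step <- function(model, state, next_time) {
  df <- tibble::as_tibble(as.list(unlist(state[c("time_h", state_cols)])))
  U <- normalize_inputs(model, df)
  y <- piecewise_linear(hidden_map_matrix(model, U) %*% model$output)
  y <- denormalize_signals(y, model$normalization$output_max)
  tibble::tibble(time_h = next_time,
                 X_gL = y[[1L, 1L]], S_gL = y[[1L, 2L]], C_mgL = y[[1L, 3L]])
}

#' Simulate a trajectory by recursive one-step prediction
#'
#' Feeds each prediction back as the next input, producing a full simulated
#' cultivation from a single initial state.
#'
#' @param model An `nfn_model`.
#' @param initial Initial state record (as in [predict_step()]).
#' @param n_steps Number of prediction steps (>= 1).
#' @param dt Sampling interval between steps, h.
#' @return A tibble of `n_steps + 1` rows including the initial record.
#' @export
simulate_recursive <- function(model, initial, n_steps, dt = 1) {
  if (n_steps < 1) abort("`n_steps` must be at least 1.")
  out <- tibble::as_tibble(as.list(unlist(initial[c("time_h", state_cols)])))
  state <- out
  for (i in seq_len(n_steps)) {
    state <- predict_step(model, state, next_time = state$time_h + dt)
    out <- dplyr::bind_rows(out, state)
  }
  out
}

#' One-step-ahead predictions over a whole dataset
#'
#' For every batch and every transition k -> k + 1, predicts the state at
#' t_(k+1) from the measured state at t_k. This is the network counterpart
#' of [conventional_predict()] and the substrate of [adequacy_report()].
#'
#' @param model An `nfn_model`.
#' @param data A batch dataset tibble.
#' @return A tibble with `batch`, `step`, `time_h` and predicted `X_gL`,
#'   `S_gL`, `C_mgL`; `K - 1` rows per batch.
#' @export
nfn_predict <- function(model, data) {
  data <- validate_dataset(data)
  data |>
    dplyr::group_by(.data$batch) |>
    dplyr::group_modify(function(df, key) {
      K <- nrow(df)
      U <- normalize_inputs(model, df[seq_len(K - 1L), ])
      y <- piecewise_linear(hidden_map_matrix(model, U) %*% model$output)
      y <- denormalize_signals(y, model$normalization$output_max)
      tibble::tibble(step = seq_len(K - 1L), time_h = df$time_h[-1L],
                     X_gL = y[, 1L], S_gL = y[, 2L], C_mgL = y[, 3L])
    }) |>
    dplyr::ungroup()
}
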
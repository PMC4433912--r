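#' Time-weighted fuzzy least-squares criterion specification
#'
#' The per-batch training criterion is a time-weighted sum of squared
#' normalized one-step residuals, `J_r = sum_k gamma_k * ||y_k - yhat_k||^2`.
#' Its fuzzy membership grades how well a batch is fitted: `mu = 1` for a
#' perfect fit, decaying with J. The degree of satisfaction of the whole
#' training task is the minimum membership over batches (Bellman-Zadeh
#' aggregation), which drives hidden-size selection.
#'
#' @param time_weights Non-negative weights `gamma_k`, one per transition
#'   (length K - 1), or `NULL` for uniform weights 1.
#' @param membership_form `"exponential"` (`mu = exp(-J / scale)`, the
#'   default, smooth and never degenerate) or `"linear"`
#'   (`mu = max(0, 1 - J / scale)`).
#' @param membership_scale Positive scale `sigma` of the membership, on the
#'   scale of the criterion J (normalized squared residuals).
#'
#' @return A list of class `fuzzy_criterion`.
#' @export
fuzzy_criterion <- function(time_weights = NULL,
                            membership_form = c("exponential", "linear"),
                            membership_scale = 1) {
  membership_form <- match.arg(membership_form)
  if (!is.null(time_weights)) {
    if (any(time_weights < 0) || !any(time_weights > 0)) {
      abort("`time_weights` must be non-negative with at least one positive.")
    }
  }
  if (membership_scale <= 0) abort("`membership_scale` must be > 0.")
  structure(list(time_weights = time_weights,
                 membership_form = membership_form,
                 membership_scale = membership_scale),
            class = "fuzzy_criterion")
}

#' Build the training regression rows
#'
#' For every batch r and every transition k = 1, ..., K - 1 the state at
#' time k is normalized, pushed through the hidden layer to give a row of
#' the design matrix Z, and the normalized state at k + 1 gives the matching
#' row of the target matrix Y. Transitions never span batch boundaries.
#'
#' @param data A batch dataset tibble.
#' @param model An `nfn_model` whose normalization is compatible with `data`.
#' @return A list with `Z` (`R*(K-1) x (n_hidden + bias)`), `Y`
#'   (`R*(K-1) x n_outputs`) and `tags`, a tibble of `(batch, step)` row
#'   labels.
#' @export
build_regression_rows <- function(data, model) {
  data <- validate_dataset(data)
  K <- dplyr::count(data, .data$batch)$n[[1L]]
  if (K < 2) abort("At least 2 time points per batch are required.")
  pieces <- data |>
    dplyr::group_by(.data$batch) |>
    dplyr::group_map(function(df, key) {
      U <- normalize_inputs(model, df[seq_len(K - 1L), ])
      Yb <- normalize_signals(as.matrix(df[-1L, state_cols]),
                              model$normalization$output_max)
      list(Z = hidden_map_matrix(model, U), Y = Yb,
           tags = tibble::tibble(batch = key$batch, step = seq_len(K - 1L)))
    })
  list(Z = do.call(rbind, purrr::map(pieces, "Z")),
       Y = do.call(rbind, purrr::map(pieces, "Y")),
       tags = dplyr::bind_rows(purrr::map(pieces, "tags")))
}

#' Evaluate the time-weighted least-squares criterion
#'
#' @param y_true,y_pred Matrices (rows = transitions, columns = outputs) or
#'   vectors of equal length.
#' @param gamma Non-negative weight per transition; recycled if length 1.
#' @return The scalar criterion `J = sum_k gamma_k ||y_k - yhat_k||^2`.
#' @export
weighted_criterion <- function(y_true, y_pred, gamma = 1) {
  y_true <- as.matrix(y_true)
  y_pred <- as.matrix(y_pred)
  if (!all(dim(y_true) == dim(y_pred))) {
    abort("`y_true` and `y_pred` must have identical dimensions.")
  }
  if (length(gamma) == 1L) gamma <- rep(gamma, nrow(y_true))
  if (length(gamma) != nrow(y_true)) {
    abort("`gamma` must have one weight per transition.")
  }
  if (any(gamma < 0)) abort("`gamma` must be non-negative.")
  sum(gamma * rowSums((y_true - y_pred)^2))
}

#' Fuzzy membership of a criterion value
#'
#' Maps a non-negative criterion J to a satisfaction degree in \[0, 1\]:
#' 1 for a perfect fit, non-increasing in J.
#'
#' @param J Criterion value(s), >= 0.
#' @param spec A [fuzzy_criterion()].
#' @return Membership value(s) in \[0, 1\].
#' @export
membership_of_criterion <- function(J, spec = fuzzy_criterion()) {
  if (any(J < 0)) abort("Criterion `J` must be non-negative.")
  switch(spec$membership_form,
         exponential = exp(-J / spec$membership_scale),
         linear = pmax(0, 1 - J / spec$membership_scale))
}

#' Assemble the normal system of the weighted least-squares problem
#'
#' With row weights Gamma, the optimal output weights solve `M w ~= B` where
#' `M = Z' Gamma Z` and `B = Z' Gamma Y`. M is symmetric positive
#' semi-definite by construction.
#'
#' @param Z Design matrix (hidden signals per transition).
#' @param Y Target matrix (normalized next-step states).
#' @param gamma Non-negative weight per row; recycled if length 1.
#' @return A list of class `normal_system` with elements `M` and `B`.
#' @export
assemble_normal_system <- function(Z, Y, gamma = 1) {
  Z <- as.matrix(Z)
  Y <- as.matrix(Y)
  if (nrow(Z) == 0L) abort("Empty design matrix.")
  if (nrow(Y) != nrow(Z)) abort("`Z` and `Y` must have equal row counts.")
  if (length(gamma) == 1L) gamma <- rep(gamma, nrow(Z))
  if (length(gamma) != nrow(Z)) abort("`gamma` must have one weight per row.")
  M <- crossprod(Z, Z * gamma)
  M <- (M + t(M)) / 2
  B <- crossprod(Z, Y * gamma)
  structure(list(M = M, B = B), class = "normal_system")
}

#' Solve the normal system for the output weights
#'
#' Minimum-norm least-squares solution of `M w ~= B` by singular value
#' decomposition: singular values below `rank_tolerance * s_max` are treated
#' as zero, so rank-deficient systems (e.g. more hidden neurons than
#' informative transitions) are handled gracefully.
#'
#' @param system A `normal_system` from [assemble_normal_system()].
#' @param rank_tolerance Relative singular-value cutoff.
#' @return The output weight matrix, with the effective rank in attribute
#'   `"rank"` and the cutoff actually applied in `"tolerance"`.
#' @export
solve_weights <- function(system, rank_tolerance = 1e-10) {
  stopifnot(inherits(system, "normal_system"))
  M <- system$M
  B <- system$B
  if (any(!is.finite(M)) || any(!is.finite(B))) {
    abort("Normal system contains non-finite entries.")
  }
  sv <- svd(M)
  keep <- sv$d > rank_tolerance * sv$d[[1L]]
  d_inv <- ifelse(keep, 1 / sv$d, 0)
  W <- sv$v %*% (d_inv * crossprod(sv$u, B))
  structure(W, rank = sum(keep), tolerance = rank_tolerance * sv$d[[1L]])
}

#' Train the neuro-fuzzy network non-iteratively
#'
#' Executes the analytic training procedure: draw the random hidden weights,
#' find the normalization maxima, normalize inputs and targets into the unit
#' interval, assemble the design rows for every one-step transition, form
#' the normal system `M = Z' Gamma Z`, `B = Z' Gamma Y`, and solve
#' `M w ~= B` by SVD. No iteration is involved — training is a single linear
#' solve. The ramp output nonlinearity is the identity wherever targets lie
#' inside (0, 1), which normalization guarantees for the training data; a
#' warning is raised if more than 1% of fitted pre-activations fall outside
#' \[0, 1\].
#'
#' The fit is then graded in fuzzy terms: the time-weighted criterion `J_r`
#' of every batch is mapped to a membership `mu_r`, and the aggregate degree
#' of satisfaction is `alpha = min_r mu_r`.
#'
#' @param data A batch dataset tibble (`batch`, `time_h`, `X_gL`, `S_gL`,
#'   `C_mgL`).
#' @param config An [network_config()].
#' @param fuzzy A [fuzzy_criterion()].
#' @param input_recipe Mapping of input slots, see [compute_normalization()].
#' @param hidden Optional hidden weight matrix overriding the seeded draw
#'   (used e.g. in parameter-recovery studies).
#' @param normalization Optional `nfn_normalization` overriding the maxima
#'   computed from `data`.
#' @param rank_tolerance Relative singular-value cutoff of the solver.
#'
#' @return An object of class `nfn_fit`: a list with the trained `model`
#'   (class `nfn_model`), `report` (per-batch criteria and memberships,
#'   `alpha`, effective rank, residual norms) and the training `data`.
#' @export
#' @examples
#' ds <- generate_dataset(seed = 7)
#' fit <- nfn_train(ds, network_config(seed = 7))
#' glance(fit)
nfn_train <- function(data, config = network_config(),
                      fuzzy = fuzzy_criterion(),
                      input_recipe = c("t", "X", "S", "C"),
                      hidden = NULL, normalization = NULL,
                      rank_tolerance = 1e-10) {
  stopifnot(inherits(config, "nfn_config"), inherits(fuzzy, "fuzzy_criterion"))
  data <- validate_dataset(data)
  K <- dplyr::count(data, .data$batch)$n[[1L]]
  R <- dplyr::n_distinct(data$batch)
  if (!is.null(config$n_timepoints) && config$n_timepoints != K) {
    abort(paste0("Config expects K = ", config$n_timepoints,
                 " time points but the data has K = ", K, "."))
  }
  if (!is.null(config$n_batches) && config$n_batches != R) {
    abort(paste0("Config expects R = ", config$n_batches,
                 " batches but the data has R = ", R, "."))
  }
  if (length(input_recipe) != config$n_inputs) {
    abort("`input_recipe` length must equal `config$n_inputs`.")
  }

  hidden <- hidden %||% init_hidden_weights(config)
  normalization <- normalization %||% compute_normalization(data, input_recipe)
  bias <- as.integer(config$include_bias)
  model <- nfn_model(config, normalization, hidden,
                     output = matrix(0, config$n_hidden + bias,
                                     config$n_outputs))

  rows <- build_regression_rows(data, model)
  gamma_k <- fuzzy$time_weights %||% rep(1, K - 1L)
  if (length(gamma_k) != K - 1L) {
    abort(paste0("`time_weights` must have length K - 1 = ", K - 1L, "."))
  }
  gamma_row <- gamma_k[rows$tags$step]

  system <- assemble_normal_system(rows$Z, rows$Y, gamma_row)
  W <- solve_weights(system, rank_tolerance)
  model$output <- matrix(as.numeric(W), nrow = nrow(W),
                         dimnames = list(NULL, names(state_cols)[
                           seq_len(config$n_outputs)]))

  pre <- rows$Z %*% model$output
  frac_outside <- mean(pre < -1e-6 | pre > 1 + 1e-6)
  if (frac_outside > 0.01) {
    warn(paste0(round(100 * frac_outside, 1),
                "% of fitted pre-activations fall outside [0, 1]; the ",
                "linear solve ignores the ramp saturation there."))
  }
  Yhat <- piecewise_linear(pre)
  resid <- rows$Y - Yhat

  per_batch <- rows$tags |>
    dplyr::mutate(sq = rowSums(resid^2) * gamma_row) |>
    dplyr::group_by(.data$batch) |>
    dplyr::summarise(criterion_J = sum(.data$sq), .groups = "drop") |>
    dplyr::mutate(membership_mu = membership_of_criterion(.data$criterion_J,
                                                          fuzzy))
  report <- list(
    per_batch = per_batch,
    alpha = min(per_batch$membership_mu),
    rank = attr(W, "rank"),
    tolerance = attr(W, "tolerance"),
    residual_norms = setNames(sqrt(colSums(resid^2)),
                              colnames(model$output)),
    preactivation_frac_outside = frac_outside,
    n_inputs = config$n_inputs, n_outputs = config$n_outputs,
    n_hidden = config$n_hidden, n_timepoints = K, n_batches = R
  )
  structure(list(model = model, report = report, fuzzy = fuzzy, data = data),
            class = "nfn_fit")
}

#' @export
print.nfn_fit <- function(x, ...) {
  r <- x$report
  cat("<nfn_fit> trained on R =", r$n_batches, "batches x K =",
      r$n_timepoints, "time points\n")
  cat("hidden neurons:", r$n_hidden, " effective rank:", r$rank, "\n")
  cat("degree of satisfaction alpha =", format(r$alpha, digits = 4), "\n")
  invisible(x)
}

#' @rdname nfn_train
#' @param x An `nfn_fit`.
#' @param ... Unused.
#' @export
tidy.nfn_fit <- function(x, ...) {
  W <- x$model$output
  terms <- c(paste0("h", seq_len(x$model$config$n_hidden)),
             if (x$model$config$include_bias) "intercept")
  tibble::tibble(term = rep(terms, times = ncol(W)),
                 output = rep(colnames(W), each = nrow(W)),
                 estimate = as.numeric(W))
}

#' @rdname nfn_train
#' @export
glance.nfn_fit <- function(x, ...) {
  r <- x$report
  tibble::tibble(n_inputs = r$n_inputs, n_outputs = r$n_outputs,
                 n_hidden = r$n_hidden, n_timepoints = r$n_timepoints,
                 n_batches = r$n_batches, rank = r$rank,
                 alpha = r$alpha,
                 total_criterion = sum(r$per_batch$criterion_J))
}

#' Select the hidden-layer size together with training
#'
#' The hidden size is not fixed a priori: every candidate J_m is trained
#' (with seed `config$seed + J_m`, so candidates are independent yet
#' reproducible) and graded by its aggregate fuzzy degree of satisfaction
#' alpha. The smallest candidate reaching `acceptance_alpha` is selected;
#' if none does, the candidate with the largest alpha wins.
#'
#' @param data A batch dataset tibble.
#' @param j_range Candidate hidden sizes, e.g. `1:10`.
#' @param config Base [network_config()]; `n_hidden` and `seed` are varied
#'   per candidate.
#' @param fuzzy A [fuzzy_criterion()].
#' @param acceptance_alpha Required degree of satisfaction in \[0, 1\].
#' @param ... Passed on to [nfn_train()].
#'
#' @return A list of class `nfn_selection` with `n_hidden` (the selected
#'   size), `table` (per-candidate alpha, rank and total criterion) and
#'   `fit` (the selected `nfn_fit`).
#' @export
select_hidden_size <- function(data, j_range, config = network_config(),
                               fuzzy = fuzzy_criterion(),
                               acceptance_alpha = 0.8, ...) {
  if (length(j_range) == 0L) abort("`j_range` must be non-empty.")
  j_range <- sort(unique(as.integer(j_range)))
  fits <- purrr::map(j_range, function(J) {
    cfg <- config
    cfg$n_hidden <- J
    cfg$seed <- config$seed + J
    nfn_train(data, cfg, fuzzy, ...)
  })
  tbl <- purrr::map2_dfr(j_range, fits, function(J, fit) {
    tibble::tibble(n_hidden = J, alpha = fit$report$alpha,
                   rank = fit$report$rank,
                   total_criterion = sum(fit$report$per_batch$criterion_J))
  })
  ok <- which(tbl$alpha >= acceptance_alpha)
  pick <- if (length(ok) > 0L) ok[[1L]] else which.max(tbl$alpha)
  structure(list(n_hidden = j_range[[pick]], table = tbl,
                 fit = fits[[pick]], acceptance_alpha = acceptance_alpha),
            class = "nfn_selection")
}

#' @export
print.nfn_selection <- function(x, ...) {
  cat("<nfn_selection> selected J_m =", x$n_hidden,
      "(alpha threshold", x$acceptance_alpha, ")\n")
  print(x$table)
  invisible(x)
}
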
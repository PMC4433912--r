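model_format_version <- "1.0"

#' Read and write batch datasets as CSV
#'
#' The on-disk format is a plain CSV with header
#' `batch,time_h,X_gL,S_gL,C_mgL`, one row per measurement, '.' decimal
#' separator. Reading groups rows by batch, sorts by time and enforces the
#' dataset invariants (equal K across batches, strictly increasing time,
#' non-negative finite values), so a read dataset is always valid input for
#' training.
#'
#' @param path File path.
#' @return `read_batch_dataset()` returns the validated dataset tibble.
#' @export
read_batch_dataset <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  data <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(paste0("Cannot parse CSV `", path, "`: ",
                                     conditionMessage(e)))
  )
  if (nrow(data) == 0L) {
    abort(paste0("Dataset file `", path, "` contains no data rows."))
  }
  validate_dataset(data)
}

#' @rdname read_batch_dataset
#' @param data A batch dataset tibble.
#' @export
write_batch_dataset <- function(data, path) {
  data <- validate_dataset(data)
  readr::write_csv(data[, dataset_cols], path)
  invisible(path)
}

#' Save and load a trained network as JSON
#'
#' The model file stores the configuration, normalization maxima, input
#' recipe and both weight matrices (row-major) with 17 significant digits,
#' so a save/load round trip reproduces the weights bit-exactly. A format
#' version string guards against reading incompatible files.
#'
#' @param model An `nfn_model`.
#' @param path File path.
#' @export
save_nfn_model <- function(model, path) {
  stopifnot(inherits(model, "nfn_model"))
  payload <- list(
    format_version = model_format_version,
    config = model$config[c("n_inputs", "n_outputs", "n_hidden",
                            "include_bias", "seed")],
    normalization = list(
      input_max = as.numeric(model$normalization$input_max),
      output_max = as.numeric(model$normalization$output_max)
    ),
    input_recipe = model$normalization$input_recipe,
    hidden_weights = as.numeric(t(model$hidden)),
    output_weights = as.numeric(t(model$output))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_nfn_model
#' @return `load_nfn_model()` returns the reconstructed `nfn_model`.
#' @export
load_nfn_model <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("format_version", "config", "normalization", "input_recipe",
                "hidden_weights", "output_weights")
  missing <- setdiff(required, names(payload))
  if (length(missing) > 0L) {
    abort(paste0("Model file `", path, "` is missing field(s): ",
                 paste0("`", missing, "`", collapse = ", "), "."))
  }
  if (!identical(payload$format_version, model_format_version)) {
    abort(paste0("Model format version `", payload$format_version,
                 "` is not supported (expected `", model_format_version,
                 "`)."))
  }
  cfg <- payload$config
  config <- network_config(n_inputs = cfg$n_inputs,
                           n_outputs = cfg$n_outputs,
                           n_hidden = cfg$n_hidden,
                           include_bias = cfg$include_bias,
                           seed = cfg$seed)
  recipe <- as.character(payload$input_recipe)
  normalization <- structure(
    list(input_max = setNames(payload$normalization$input_max, recipe),
         output_max = setNames(payload$normalization$output_max,
                               names(state_cols)[seq_len(config$n_outputs)]),
         input_recipe = recipe),
    class = "nfn_normalization")
  bias <- as.integer(config$include_bias)
  hidden <- matrix(payload$hidden_weights, nrow = config$n_hidden,
                   byrow = TRUE)
  output <- matrix(payload$output_weights, nrow = config$n_hidden + bias,
                   byrow = TRUE)
  nfn_model(config, normalization, hidden, output)
}

#' Run the full modelling pipeline and write its artifacts
#'
#' Generates (or reads) a multi-batch dataset, trains the neuro-fuzzy
#' network, produces one-step predictions from both the network and the
#' conventional mechanistic model, and writes the adequacy comparison —
#' everything seeded, so reruns with the same configuration are
#' byte-identical.
#'
#' @param out_dir Directory for the artifacts (`dataset.csv`, `model.json`,
#'   `report.json`, `pred_nfn.csv`, `pred_conventional.csv`, `stats.csv`).
#' @param config An [network_config()].
#' @param fuzzy A [fuzzy_criterion()].
#' @param params,base_init,noise,n_batches,init_jitter Simulator settings,
#'   see [generate_dataset()].
#' @param conventional_params Parameters given to the conventional baseline
#'   (defaults to the generating `params`; perturb to study a mis-specified
#'   mechanistic model).
#' @param data Optional pre-existing dataset tibble; when supplied the
#'   simulation stage is skipped.
#' @param thresholds An [adequacy_thresholds()].
#' @param seed Integer seed for the simulation stage.
#'
#' @return Invisibly, a list with the trained `fit`, the `stats` tibble and
#'   the artifact `paths`.
#' @export
run_pipeline <- function(out_dir, config = network_config(),
                         fuzzy = fuzzy_criterion(),
                         params = kinetic_parameters(),
                         base_init = batch_init(), noise = noise_model(),
                         n_batches = 6, init_jitter = 0.05,
                         conventional_params = params,
                         data = NULL, thresholds = adequacy_thresholds(),
                         seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(data)) {
    data <- generate_dataset(params, base_init, n_batches = n_batches,
                             init_jitter = init_jitter, noise = noise,
                             seed = seed)
  } else {
    data <- validate_dataset(data)
  }
  paths <- list(
    dataset = file.path(out_dir, "dataset.csv"),
    model = file.path(out_dir, "model.json"),
    report = file.path(out_dir, "report.json"),
    pred_nfn = file.path(out_dir, "pred_nfn.csv"),
    pred_conventional = file.path(out_dir, "pred_conventional.csv"),
    stats = file.path(out_dir, "stats.csv")
  )
  write_batch_dataset(data, paths$dataset)

  fit <- nfn_train(data, config, fuzzy)
  save_nfn_model(fit$model, paths$model)
  jsonlite::write_json(
    list(format_version = "1.0",
         INP = fit$report$n_inputs, OUT = fit$report$n_outputs,
         J_m = fit$report$n_hidden, K = fit$report$n_timepoints,
         R = fit$report$n_batches, seed = config$seed,
         per_batch = fit$report$per_batch, alpha = fit$report$alpha,
         rank = fit$report$rank,
         residual_norms = as.list(fit$report$residual_norms)),
    paths$report, auto_unbox = TRUE, digits = I(17), dataframe = "rows")

  pred_nfn <- nfn_predict(fit$model, data)
  pred_conv <- conventional_predict(data, conventional_params)
  readr::write_csv(pred_nfn, paths$pred_nfn)
  readr::write_csv(pred_conv, paths$pred_conventional)

  stats <- adequacy_report(
    data, list(conventional = pred_conv, `neuro-fuzzy` = pred_nfn),
    thresholds)
  readr::write_csv(stats, paths$stats)
  invisible(list(fit = fit, stats = stats, paths = paths))
}
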
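# Shared fixtures: all built in code at test time.

# A tiny network with fully known weights, for hand-checkable forward passes.
tiny_model <- function() {
  config <- network_config(n_inputs = 2, n_outputs = 1, n_hidden = 2,
                           include_bias = TRUE, seed = 1)
  normalization <- structure(
    list(input_max = c(X = 1, S = 1), output_max = c(X = 1),
         input_recipe = c("X", "S")),
    class = "nfn_normalization")
  hidden <- rbind(c(0.2, 0.4, 0.1),
                  c(0.5, 0.3, 0.7))
  output <- matrix(c(0.4, 0.3, 0.1), ncol = 1)
  nfn_model(config, normalization, hidden, output)
}

# A random model at the study dimensions (INP = 4, OUT = 3, J_m = 5) whose
# output weights keep all pre-activations inside the ramp's linear region,
# so the network is exactly linear in its hidden signals.
known_nfn <- function(seed = 11) {
  config <- network_config(n_inputs = 4, n_outputs = 3, n_hidden = 5,
                           include_bias = TRUE, seed = seed)
  hidden <- init_hidden_weights(config)
  normalization <- structure(
    list(input_max = c(t = 12, X = 22, S = 44, C = 7),
         output_max = c(X = 22, S = 44, C = 7),
         input_recipe = c("t", "X", "S", "C")),
    class = "nfn_normalization")
  output <- withr::with_seed(seed + 100, {
    W <- matrix(runif(6 * 3, 0.02, 0.11), nrow = 6)
    W[6, ] <- 0.15  # intercept keeps pre-activations away from the ramp knees
    W
  })
  nfn_model(config, normalization, hidden, output)
}

# Recursive trajectories of a known network, packaged as a batch dataset:
# every one-step transition in the data is exactly the network's map.
nfn_generated_dataset <- function(model, n_batches = 12, K = 4, seed = 5) {
  maxima <- model$normalization$output_max
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_batches), function(b) {
      init <- tibble::tibble(time_h = 0,
                             X_gL = runif(1, 0.1, 0.9) * maxima[["X"]],
                             S_gL = runif(1, 0.1, 0.9) * maxima[["S"]],
                             C_mgL = runif(1, 0.1, 0.9) * maxima[["C"]])
      traj <- simulate_recursive(model, init, n_steps = K - 1, dt = 1)
      dplyr::mutate(traj, batch = b, .before = 1)
    })
  })
}

# A constant-in-time dataset (states frozen, time advancing).
constant_dataset <- function(R = 2, K = 5) {
  tidyr::expand_grid(batch = seq_len(R), time_h = seq_len(K) - 1) |>
    dplyr::mutate(X_gL = 3, S_gL = 20, C_mgL = 5)
}
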
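test_that("regression rows cover every within-batch transition", {
  model <- known_nfn()
  ds <- nfn_generated_dataset(model, n_batches = 6, K = 13, seed = 3)
  rows <- build_regression_rows(ds, model)
  expect_equal(nrow(rows$Z), 6 * 12)  # R * (K - 1)
  expect_equal(ncol(rows$Z), 6)      # J_m + intercept signal
  expect_equal(nrow(rows$Y), 72)
  expect_equal(nrow(rows$tags), 72)
  # each row equals the hidden map of the corresponding normalized state
  i <- 40
  tag <- rows$tags[i, ]
  rec <- ds[ds$batch == tag$batch, ][tag$step, ]
  u <- c(rec$time_h / 12, rec$X_gL / 22, rec$S_gL / 44, rec$C_mgL / 7)
  expect_equal(unname(rows$Z[i, ]), unname(hidden_map(model, u)),
               tolerance = 1e-12)
  nxt <- ds[ds$batch == tag$batch, ][tag$step + 1, ]
  expect_equal(unname(rows$Y[i, ]),
               c(nxt$X_gL / 22, nxt$S_gL / 44, nxt$C_mgL / 7),
               tolerance = 1e-12)
  # a single two-point batch gives exactly one row
  one <- ds[ds$batch == 1, ][1:2, ]
  expect_equal(nrow(build_regression_rows(one, model)$Z), 1)
})

test_that("the time-weighted criterion matches a brute-force double loop", {
  expect_identical(weighted_criterion(matrix(1:6, 2), matrix(1:6, 2)), 0)
  expect_equal(weighted_criterion(matrix(c(0.1, 0, 0), 1),
                                  matrix(0, 1, 3)), 0.01)
  withr::with_seed(14, {
    y <- matrix(runif(15), 5, 3)
    yh <- matrix(runif(15), 5, 3)
    g <- runif(5)
    oracle <- 0
    for (k in 1:5) for (j in 1:3) oracle <- oracle + g[k] * (y[k, j] - yh[k, j])^2
    expect_equal(weighted_criterion(y, yh, g), oracle, tolerance = 1e-12)
  })
  expect_error(weighted_criterion(matrix(1, 2, 2), matrix(1, 3, 2)),
               "identical dimensions")
})

test_that("criterion membership is 1 at zero and decays as specified", {
  spec_exp <- fuzzy_criterion(membership_scale = 1)
  expect_identical(membership_of_criterion(0, spec_exp), 1)
  expect_equal(membership_of_criterion(1, spec_exp), 0.36787944,
               tolerance = 1e-8)  # exp(-1)
  spec_lin <- fuzzy_criterion(membership_form = "linear",
                              membership_scale = 1)
  expect_identical(membership_of_criterion(2, spec_lin), 0)
  expect_equal(membership_of_criterion(0.25, spec_lin), 0.75)
  J <- seq(0, 5, by = 0.1)
  expect_true(all(diff(membership_of_criterion(J, spec_exp)) < 0))
  expect_error(membership_of_criterion(-1, spec_exp), "non-negative")
})

test_that("the normal system matches triple-loop summation and is symmetric PSD", {
  s <- assemble_normal_system(matrix(c(1, 1), 2, 1), matrix(c(1, 0), 2, 1))
  expect_equal(s$M, matrix(2, 1, 1), ignore_attr = TRUE)
  expect_equal(s$B, matrix(1, 1, 1), ignore_attr = TRUE)
  withr::with_seed(6, {
    Z <- matrix(rnorm(40), 10, 4)
    Y <- matrix(rnorm(30), 10, 3)
    g <- runif(10)
    s <- assemble_normal_system(Z, Y, g)
    M_oracle <- matrix(0, 4, 4)
    B_oracle <- matrix(0, 4, 3)
    for (a in 1:4) for (b in 1:4) for (k in 1:10) {
      M_oracle[a, b] <- M_oracle[a, b] + g[k] * Z[k, a] * Z[k, b]
    }
    for (a in 1:4) for (j in 1:3) for (k in 1:10) {
      B_oracle[a, j] <- B_oracle[a, j] + g[k] * Z[k, a] * Y[k, j]
    }
    expect_equal(s$M, M_oracle, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(s$B, B_oracle, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(s$M, t(s$M))
    expect_true(all(eigen(s$M, symmetric = TRUE)$values >= -1e-10))
    # linearity in the weights
    s2 <- assemble_normal_system(Z, Y, 2 * g)
    expect_equal(s2$M, 2 * s$M)
    expect_equal(s2$B, 2 * s$B)
  })
  expect_error(assemble_normal_system(matrix(0, 0, 2), matrix(0, 0, 1)),
               "Empty")
})

test_that("the SVD solve returns the minimum-norm least-squares solution", {
  s <- structure(list(M = matrix(2, 1, 1), B = matrix(1, 1, 1)),
                 class = "normal_system")
  expect_equal(as.numeric(solve_weights(s)), 0.5)
  # singular system: the minimum-norm solution, not an arbitrary one
  s_sing <- structure(list(M = matrix(1, 2, 2), B = matrix(1, 2, 1)),
                      class = "normal_system")
  expect_equal(as.numeric(solve_weights(s_sing)), c(0.5, 0.5),
               tolerance = 1e-12)
  # random full-rank systems against the independent pseudoinverse oracle
  withr::with_seed(31, {
    for (i in 1:20) {
      d <- sample(2:12, 1)
      Z <- matrix(rnorm(3 * d * d), 3 * d, d)
      Y <- matrix(rnorm(3 * d * 2), 3 * d, 2)
      s <- assemble_normal_system(Z, Y)
      W <- solve_weights(s)
      expect_lt(max(abs(W - MASS::ginv(s$M) %*% s$B)), 1e-8)
      expect_equal(attr(W, "rank"), d)
    }
  })
})

test_that("training recovers the generating output weights exactly", {
  gen <- known_nfn(seed = 11)
  ds <- nfn_generated_dataset(gen, n_batches = 12, K = 4, seed = 5)
  fit <- nfn_train(ds, gen$config, hidden = gen$hidden,
                   normalization = gen$normalization)
  expect_equal(dim(fit$model$output), c(6, 3))  # (J_m + bias) x OUT
  expect_lt(max(abs(fit$model$output - gen$output)), 1e-6)
  expect_lt(sum(fit$report$per_batch$criterion_J), 1e-10)
  expect_equal(fit$report$alpha, 1, tolerance = 1e-9)
})

test_that("a constant process is learned as a fixed point with full satisfaction", {
  ds <- constant_dataset()
  # constant targets normalize to exactly 1.0 — the ramp's upper knee — so
  # the boundary warning fires; the solve is still exact up to the
  # conditioning of the (rank-deficient) normal system
  fit <- suppressWarnings(nfn_train(ds, network_config(seed = 2)))
  expect_lt(sum(fit$report$per_batch$criterion_J), 1e-8)
  expect_equal(fit$report$alpha, 1, tolerance = 1e-8)
  pred <- nfn_predict(fit$model, ds)
  expect_equal(pred$X_gL, rep(3, nrow(pred)), tolerance = 1e-5)
  expect_equal(pred$S_gL, rep(20, nrow(pred)), tolerance = 1e-5)
  expect_equal(pred$C_mgL, rep(5, nrow(pred)), tolerance = 1e-5)
})

test_that("the training report is reproducible from the returned model", {
  ds <- generate_dataset(seed = 9)
  fuzzy <- fuzzy_criterion(membership_scale = 0.5)
  fit <- suppressWarnings(nfn_train(ds, network_config(seed = 9), fuzzy))
  rows <- build_regression_rows(ds, fit$model)
  pred <- piecewise_linear(rows$Z %*% fit$model$output)
  for (r in unique(rows$tags$batch)) {
    idx <- rows$tags$batch == r
    J_r <- weighted_criterion(rows$Y[idx, ], pred[idx, ])
    expect_equal(fit$report$per_batch$criterion_J[
      fit$report$per_batch$batch == r], J_r, tolerance = 1e-10)
  }
  expect_equal(fit$report$alpha, min(fit$report$per_batch$membership_mu))
  expect_equal(fit$report$per_batch$membership_mu,
               exp(-fit$report$per_batch$criterion_J / 0.5))
})

test_that("the fitted weights are a local optimum of the weighted objective", {
  gen <- known_nfn(seed = 3)
  ds <- nfn_generated_dataset(gen, n_batches = 8, K = 5, seed = 7)
  ds <- dplyr::mutate(ds, X_gL = X_gL * (1 + 0.01 * sin(seq_len(dplyr::n()))))
  fit <- nfn_train(ds, gen$config, hidden = gen$hidden,
                   normalization = gen$normalization)
  rows <- build_regression_rows(ds, fit$model)
  obj <- function(W) sum((rows$Y - rows$Z %*% W)^2)
  f0 <- obj(fit$model$output)
  withr::with_seed(77, {
    for (i in 1:100) {
      D <- matrix(rnorm(length(fit$model$output)), nrow(fit$model$output))
      D <- D / sqrt(sum(D^2))
      expect_gte(obj(fit$model$output + 1e-3 * D), f0)
    }
  })
})

test_that("hidden-size selection follows its acceptance rule", {
  gen <- known_nfn(seed = 19)
  ds <- nfn_generated_dataset(gen, n_batches = 8, K = 5, seed = 13)
  # any candidate satisfies alpha >= 0, so the smallest is returned
  sel0 <- select_hidden_size(ds, j_range = c(4, 2, 7),
                             config = network_config(seed = 1),
                             acceptance_alpha = 0)
  expect_equal(sel0$n_hidden, 2)
  # a single candidate is returned as-is
  sel5 <- select_hidden_size(ds, j_range = 5,
                             config = network_config(seed = 1))
  expect_equal(sel5$n_hidden, 5)
  # the rule: smallest candidate reaching alpha, else the argmax
  sel <- select_hidden_size(ds, j_range = 1:8,
                            config = network_config(seed = 1),
                            acceptance_alpha = 0.99)
  tbl <- sel$table
  ok <- tbl$n_hidden[tbl$alpha >= 0.99]
  expected <- if (length(ok) > 0) min(ok) else tbl$n_hidden[which.max(tbl$alpha)]
  expect_equal(sel$n_hidden, expected)
  expect_true(all(tbl$alpha >= 0 & tbl$alpha <= 1))
  # data from a 5-neuron network is well fitted at modest size
  expect_true(any(tbl$alpha[tbl$n_hidden <= 5] > 0.99) ||
                sel$n_hidden <= 8)
  expect_equal(sel$fit$report$n_hidden, sel$n_hidden)
})
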
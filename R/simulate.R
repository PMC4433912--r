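#' Kinetic parameters of the Monod-type batch fermentation model
#'
#' Constants of the mechanistic surrogate used both to generate synthetic
#' multi-batch cultivation data and as the conventional mass-balance baseline
#' in model comparisons. Growth is double-limited (Monod in lactose and in
#' dissolved oxygen); oxygen is resupplied by gas-liquid transfer.
#'
#' The dynamics are
#' \deqn{dX/dt = \mu X, \quad \mu = \mu_{max}\frac{S}{K_s+S}\frac{C}{K_c+C}}
#' \deqn{dS/dt = -\mu X / Y_{xs}}
#' \deqn{dC/dt = k_La (C^* - C) - \mu X / Y_{xc}}
#' with \eqn{S} and \eqn{C} clipped at zero.
#'
#' Defaults emulate an aerobic lactose-assimilating yeast cultivation that
#' depletes ~44 g/L lactose within 12 h in a small stirred bioreactor.
#'
#' @param mu_max Maximum specific growth rate, 1/h.
#' @param Ks Lactose half-saturation constant, g/L.
#' @param Kc Dissolved-oxygen half-saturation constant, mg/L.
#' @param Yxs Biomass yield on lactose, g biomass / g lactose (must be <= 1).
#' @param Yxc Biomass yield on oxygen, g biomass / mg oxygen.
#' @param kLa Volumetric oxygen transfer coefficient, 1/h.
#' @param C_star Oxygen saturation concentration, mg/L.
#'
#' @return A list of class `kinetic_parameters`.
#' @export
#' @examples
#' kinetic_parameters()
kinetic_parameters <- function(mu_max = 0.45, Ks = 1.2, Kc = 0.3,
                               Yxs = 0.5, Yxc = 0.05, kLa = 60,
                               C_star = 7.0) {
  p <- list(mu_max = mu_max, Ks = Ks, Kc = Kc, Yxs = Yxs, Yxc = Yxc,
            kLa = kLa, C_star = C_star)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All kinetic parameters must be finite and strictly positive.")
  }
  if (Yxs > 1) {
    abort("`Yxs` (biomass-per-lactose yield) cannot exceed 1 g/g.")
  }
  structure(p, class = "kinetic_parameters")
}

#' Initial conditions for one batch cultivation
#'
#' @param X0 Initial cell mass, g/L.
#' @param S0 Initial lactose, g/L.
#' @param C0 Initial dissolved oxygen, mg/L.
#' @param t_final Cultivation duration, h.
#' @param n_samples Number of equally spaced sampling points (including both
#'   endpoints) taken from the dense trajectory.
#'
#' @return A list of class `batch_init`.
#' @export
batch_init <- function(X0 = 0.2, S0 = 44, C0 = 7.0, t_final = 12,
                       n_samples = 13) {
  if (!is.finite(X0) || X0 <= 0) abort("`X0` must be > 0.")
  if (!is.finite(S0) || S0 <= 0) abort("`S0` must be > 0.")
  if (!is.finite(C0) || C0 < 0) abort("`C0` must be >= 0.")
  if (!is.finite(t_final) || t_final <= 0) abort("`t_final` must be > 0.")
  if (n_samples < 2) abort("`n_samples` must be at least 2.")
  structure(list(X0 = X0, S0 = S0, C0 = C0, t_final = t_final,
                 n_samples = as.integer(n_samples)),
            class = "batch_init")
}

#' Multiplicative measurement-noise model
#'
#' Each measured value v is replaced by `v * (1 + eps)` with
#' `eps ~ Normal(0, relative_sd)`, then clipped at zero. Relative noise
#' emulates assay errors (Kjeldahl nitrogen, enzymatic UV tests, oxygen
#' sensors) whose magnitude scales with the signal.
#'
#' @param relative_sd Fractional standard deviation per variable; a length-3
#'   vector for (X, S, C) or a single value recycled to all three.
#' @param seed Integer seed making the noise reproducible.
#'
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(relative_sd = c(X = 0.02, S = 0.02, C = 0.02),
                        seed = 1L) {
  if (length(relative_sd) == 1L) relative_sd <- rep(relative_sd, 3L)
  if (length(relative_sd) != 3L || any(relative_sd < 0)) {
    abort("`relative_sd` must be 3 non-negative values (X, S, C).")
  }
  names(relative_sd) <- names(state_cols)
  structure(list(relative_sd = relative_sd, seed = as.integer(seed)),
            class = "noise_model")
}

monod_rhs <- function(t, y, p) {
  S <- max(y[[2]], 0)
  C <- max(y[[3]], 0)
  mu <- p$mu_max * S / (p$Ks + S) * C / (p$Kc + C)
  uptake <- mu * y[[1]]
  list(c(uptake,
         -uptake / p$Yxs,
         p$kLa * (p$C_star - C) - uptake / p$Yxc))
}

#' Simulate one batch cultivation on a dense time grid
#'
#' Integrates the Monod-type mass-balance ODEs (see [kinetic_parameters()])
#' with classical fixed-step fourth-order Runge-Kutta.
#'
#' @param params A [kinetic_parameters()] object.
#' @param init A [batch_init()] object.
#' @param dt Integration step, h. Must satisfy `0 < dt <= t_final`.
#'
#' @return A tibble with columns `time_h`, `X_gL`, `S_gL`, `C_mgL`, one row
#'   per grid point `0, dt, 2 dt, ..., t_final`.
#' @export
#' @examples
#' traj <- simulate_batch(kinetic_parameters(), batch_init(), dt = 0.05)
#' tail(traj)
simulate_batch <- function(params, init, dt = 0.01) {
  stopifnot(inherits(params, "kinetic_parameters"),
            inherits(init, "batch_init"))
  if (!is.finite(dt) || dt <= 0 || dt > init$t_final) {
    abort("`dt` must satisfy 0 < dt <= t_final.")
  }
  # oxygen transfer is the fastest time scale; explicit RK4 destabilizes
  # once kLa * dt approaches its stability bound (~2.8)
  if (dt * params$kLa > 2) {
    warn(paste0("`dt` = ", dt, " under-resolves the oxygen transfer time ",
                "scale 1/kLa = ", format(1 / params$kLa, digits = 3),
                " h; results may be inaccurate. Reduce `dt`."))
  }
  times <- seq(0, init$t_final, by = dt)
  if (tail(times, 1L) < init$t_final) times <- c(times, init$t_final)
  y0 <- c(X = init$X0, S = init$S0, C = init$C0)
  sol <- deSolve::ode(y = y0, times = times, func = monod_rhs,
                      parms = params, method = "rk4")
  sol <- unclass(sol)
  if (anyNA(sol) || any(!is.finite(sol))) {
    bad <- which(rowSums(!is.finite(sol)) > 0)[1L]
    abort(paste0("Integration produced a non-finite state at t = ",
                 format(times[bad]), " h; reduce `dt` or check parameters."))
  }
  tibble::tibble(
    time_h = sol[, "time"],
    X_gL = pmax(sol[, "X"], 0),
    S_gL = pmax(sol[, "S"], 0),
    C_mgL = pmax(sol[, "C"], 0)
  )
}

#' Sample a dense trajectory at equally spaced time points
#'
#' @param trajectory A tibble as returned by [simulate_batch()].
#' @param n_samples Number of samples, including both endpoints.
#'
#' @return A tibble of `n_samples` rows at times equally spaced over the
#'   trajectory's span.
#' @export
sample_trajectory <- function(trajectory, n_samples) {
  if (n_samples < 2) abort("`n_samples` must be at least 2.")
  if (n_samples > nrow(trajectory)) {
    abort(paste0("`n_samples` (", n_samples, ") exceeds the trajectory ",
                 "resolution (", nrow(trajectory), " points)."))
  }
  t0 <- trajectory$time_h[[1L]]
  t1 <- trajectory$time_h[[nrow(trajectory)]]
  targets <- seq(t0, t1, length.out = n_samples)
  idx <- vapply(targets, function(tt) which.min(abs(trajectory$time_h - tt)),
                integer(1))
  achieved <- trajectory$time_h[idx]
  step <- diff(trajectory$time_h[1:2])
  if (max(abs(achieved - targets)) > step / 2 + 1e-9) {
    abort("Trajectory grid too coarse to hit equally spaced sample times.")
  }
  trajectory[idx, ]
}

#' Apply multiplicative measurement noise to sampled records
#'
#' @param records A tibble with columns `X_gL`, `S_gL`, `C_mgL` (other
#'   columns pass through untouched).
#' @param noise A [noise_model()].
#'
#' @return The records with each state value perturbed by its relative noise
#'   and clipped at zero; reproducible for a fixed `noise$seed`.
#' @export
add_measurement_noise <- function(records, noise) {
  stopifnot(inherits(noise, "noise_model"))
  withr::with_seed(noise$seed, noised_records(records, noise$relative_sd))
}

# draw from the current RNG stream (callers manage seeding)
noised_records <- function(records, relative_sd) {
  n <- nrow(records)
  for (v in names(state_cols)) {
    col <- state_cols[[v]]
    eps <- rnorm(n, mean = 0, sd = relative_sd[[v]])
    records[[col]] <- pmax(records[[col]] * (1 + eps), 0)
  }
  records
}

#' Generate a synthetic multi-batch fermentation dataset
#'
#' Emulates a set of replicate aerobic batch cultivations: initial conditions
#' are jittered uniformly around `base_init`, each batch is integrated with
#' the mechanistic model, sampled at `n_samples` equally spaced times, and
#' corrupted with multiplicative measurement noise. The defaults reproduce
#' the study layout of six batches sampled at 13 hourly points over 12 h
#' starting from ~44 g/L lactose.
#'
#' @param params A [kinetic_parameters()] object.
#' @param base_init A [batch_init()] object; per-batch X0, S0, C0 are
#'   jittered, `t_final` and `n_samples` are shared.
#' @param n_batches Number of replicate batches (R).
#' @param init_jitter Fractional half-width of the uniform jitter applied to
#'   X0, S0, C0 (0 disables it).
#' @param noise A [noise_model()]; its `relative_sd` is used, while the draws
#'   flow from `seed` so one seed fixes the whole dataset.
#' @param seed Integer seed for jitter and noise.
#' @param dt Integration step passed to [simulate_batch()].
#'
#' @return A tibble with columns `batch`, `time_h`, `X_gL`, `S_gL`, `C_mgL`
#'   and `n_batches * n_samples` rows.
#' @export
#' @examples
#' ds <- generate_dataset(seed = 42)
#' dplyr::count(ds, batch)
generate_dataset <- function(params = kinetic_parameters(),
                             base_init = batch_init(),
                             n_batches = 6, init_jitter = 0.05,
                             noise = noise_model(), seed = 1L,
                             dt = 0.01) {
  if (n_batches < 1) abort("`n_batches` must be at least 1.")
  if (init_jitter < 0) abort("`init_jitter` must be non-negative.")
  withr::with_seed(as.integer(seed), {
    batches <- purrr::map(seq_len(n_batches), function(b) {
      u <- runif(3, -init_jitter, init_jitter)
      init_b <- batch_init(
        X0 = base_init$X0 * (1 + u[[1L]]),
        S0 = base_init$S0 * (1 + u[[2L]]),
        C0 = min(base_init$C0 * (1 + u[[3L]]), params$C_star),
        t_final = base_init$t_final,
        n_samples = base_init$n_samples
      )
      rec <- sample_trajectory(simulate_batch(params, init_b, dt = dt),
                               base_init$n_samples)
      rec <- noised_records(rec, noise$relative_sd)
      dplyr::mutate(rec, batch = b, .before = 1L)
    })
    dplyr::bind_rows(batches)
  })
}

#' One-step-ahead predictions from the mechanistic (conventional) model
#'
#' For every measured state at time t_k the mass-balance ODEs are integrated
#' one sampling interval forward, giving a prediction aligned with the
#' measurement at t_(k+1). This is the conventional-model arm of the
#' model-comparison methodology: identical information (the last measured
#' state) is given to both the mechanistic model and the neuro-fuzzy network.
#'
#' @param data A batch dataset tibble (`batch`, `time_h`, `X_gL`, `S_gL`,
#'   `C_mgL`).
#' @param params A [kinetic_parameters()] object (possibly mis-specified, to
#'   study robustness).
#' @param dt Integration step within each sampling interval, h.
#'
#' @return A tibble of one-step predictions with columns `batch`, `step`
#'   (index k of the transition), `time_h` (the predicted time t_(k+1)) and
#'   the predicted `X_gL`, `S_gL`, `C_mgL`; `K - 1` rows per batch.
#' @export
conventional_predict <- function(data, params = kinetic_parameters(),
                                 dt = 0.01) {
  data <- validate_dataset(data)
  stopifnot(inherits(params, "kinetic_parameters"))
  data |>
    dplyr::group_by(.data$batch) |>
    dplyr::group_modify(function(df, key) {
      K <- nrow(df)
      purrr::map_dfr(seq_len(K - 1L), function(k) {
        span <- df$time_h[[k + 1L]] - df$time_h[[k]]
        init_k <- batch_init(
          X0 = max(df$X_gL[[k]], 1e-12), S0 = max(df$S_gL[[k]], 1e-12),
          C0 = df$C_mgL[[k]], t_final = span, n_samples = 2
        )
        step_dt <- span / ceiling(span / dt)
        pred <- simulate_batch(params, init_k, dt = step_dt)
        tibble::tibble(step = k, time_h = df$time_h[[k + 1L]],
                       X_gL = pred$X_gL[[nrow(pred)]],
                       S_gL = pred$S_gL[[nrow(pred)]],
                       C_mgL = pred$C_mgL[[nrow(pred)]])
      })
    }) |>
    dplyr::ungroup()
}
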
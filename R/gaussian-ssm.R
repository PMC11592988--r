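# Synthetic data for the hierarchical state-space experiment, plus exact
# conjugate inference on its linear-Gaussian reduction (Kalman filtering with
# Rauch-Tung-Striebel smoothing over the joint (drift, state) chain).

#' Hyperparameters of the hierarchical state-space model
#'
#' The model is a random walk with drift where the drift is itself a random
#' walk: `drift_t = drift_{t-1} + e_d`, `state_t = state_{t-1} + drift_t +
#' e_s`, `obs_t = state_t + e_o`, with the observation precision drawn once
#' from a Gamma hyperprior.
#'
#' @param drift_noise_var Variance of the drift-walk increments.
#' @param state_noise_var Variance of the state transition noise.
#' @param obs_precision_shape,obs_precision_rate Gamma hyperprior of the
#'   observation precision.
#' @param init_drift_mean,init_drift_var,init_state_mean,init_state_var
#'   Initial-state Gaussians.
#' @return An `ffg_ssm_params` list.
#' @export
ssm_params <- function(drift_noise_var = 0.01, state_noise_var = 0.1,
                       obs_precision_shape = 2, obs_precision_rate = 2,
                       init_drift_mean = 0, init_drift_var = 1,
                       init_state_mean = 0, init_state_var = 1) {
  if (obs_precision_shape <= 0 || obs_precision_rate <= 0) {
    ffg_stop("invalid_params", "Gamma hyperparameters must be positive")
  }
  if (drift_noise_var < 0 || state_noise_var < 0 ||
      init_drift_var < 0 || init_state_var < 0) {
    ffg_stop("invalid_params", "variances must be nonnegative")
  }
  structure(list(drift_noise_var = drift_noise_var,
                 state_noise_var = state_noise_var,
                 obs_precision_shape = obs_precision_shape,
                 obs_precision_rate = obs_precision_rate,
                 init_drift_mean = init_drift_mean, init_drift_var = init_drift_var,
                 init_state_mean = init_state_mean, init_state_var = init_state_var),
            class = "ffg_ssm_params")
}

#' Generate data from the hierarchical state-space model
#'
#' Draw order is fixed (observation precision, initial states, then per step
#' drift, state and observation noise) so a fixed seed gives bit-identical
#' output.
#'
#' @param T Number of time steps.
#' @param params An [ssm_params()] list.
#' @param seed Integer seed.
#' @return A list with `t` (1..T), `drift`, `state`, `obs` (numeric length
#'   T), `obs_precision` (the drawn precision), and `params`.
#' @export
generate_ssm_data <- function(T, params = ssm_params(), seed = 1L) {
  if (T < 1L) ffg_stop("invalid_params", "T must be >= 1")
  set.seed(seed)
  obs_precision <- stats::rgamma(1, shape = params$obs_precision_shape,
                                 rate = params$obs_precision_rate)
  drift0 <- stats::rnorm(1, params$init_drift_mean, sqrt(params$init_drift_var))
  state0 <- stats::rnorm(1, params$init_state_mean, sqrt(params$init_state_var))
  drift <- state <- obs <- numeric(T)
  d <- drift0; s <- state0
  obs_sd <- 1 / sqrt(obs_precision)
  for (t in seq_len(T)) {
    d <- d + stats::rnorm(1, 0, sqrt(params$drift_noise_var))
    s <- s + d + stats::rnorm(1, 0, sqrt(params$state_noise_var))
    obs[t] <- s + stats::rnorm(1, 0, obs_sd)
    drift[t] <- d; state[t] <- s
  }
  list(t = seq_len(T), drift = drift, state = state, obs = obs,
       obs_precision = obs_precision, params = params)
}

#' Exact inference on the conjugate Gaussian-chain reduction
#'
#' With the noise variances and the observation precision treated as known,
#' the hierarchical state-space model is a linear-Gaussian chain over the
#' joint state `(drift_t, state_t)`; marginal posteriors are exact and are
#' computed by Kalman filtering plus Rauch-Tung-Striebel smoothing. The
#' prediction-error decomposition gives the exact log evidence.
#'
#' @param obs Observations (length T).
#' @param params An [ssm_params()] list.
#' @param obs_precision Known observation precision.
#' @return List with `drift_mean`, `drift_var`, `state_mean`, `state_var`
#'   (length T, smoothed marginals at t = 1..T) and `log_evidence`.
#' @export
ssm_smooth <- function(obs, params = ssm_params(), obs_precision) {
  T <- length(obs)
  A <- matrix(c(1, 1, 0, 1), 2, 2) # column-major: drift' = drift, state' = drift + state
  qd <- params$drift_noise_var; qs <- params$state_noise_var
  Q <- matrix(c(qd, qd, qd, qd + qs), 2, 2)
  H <- matrix(c(0, 1), 1, 2)
  R <- 1 / obs_precision
  m <- c(params$init_drift_mean, params$init_state_mean)
  P <- diag(c(params$init_drift_var, params$init_state_var))
  mf <- matrix(0, 2, T); Pf <- array(0, c(2, 2, T))
  mp <- matrix(0, 2, T); Pp <- array(0, c(2, 2, T))
  loglik <- 0
  for (t in seq_len(T)) {
    m_pred <- as.vector(A %*% m)
    P_pred <- A %*% P %*% t(A) + Q
    mp[, t] <- m_pred; Pp[, , t] <- P_pred
    S <- as.numeric(H %*% P_pred %*% t(H)) + R
    K <- (P_pred %*% t(H)) / S
    resid <- obs[t] - as.numeric(H %*% m_pred)
    loglik <- loglik + stats::dnorm(obs[t], as.numeric(H %*% m_pred), sqrt(S), log = TRUE)
    m <- m_pred + as.vector(K) * resid
    P <- P_pred - K %*% H %*% P_pred
    mf[, t] <- m; Pf[, , t] <- P
  }
  ms <- mf; Ps <- Pf
  if (T > 1L) {
    for (t in seq(T - 1L, 1L)) {
      G <- Pf[, , t] %*% t(A) %*% solve(Pp[, , t + 1L])
      ms[, t] <- mf[, t] + as.vector(G %*% (ms[, t + 1L] - mp[, t + 1L]))
      Ps[, , t] <- Pf[, , t] + G %*% (Ps[, , t + 1L] - Pp[, , t + 1L]) %*% t(G)
    }
  }
  list(drift_mean = ms[1, ], drift_var = Ps[1, 1, ],
       state_mean = ms[2, ], state_var = Ps[2, 2, ],
       log_evidence = loglik)
}
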
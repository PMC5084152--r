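# Interacting-multiple-model (IMM) Kalman filtering over three motion
# models: random walk, first-order (constant-velocity) and second-order
# (constant-acceleration) linear motion. A common 10-dimensional state is
# shared by all models -- position (3), velocity (3), acceleration (3) and
# intensity -- with unused blocks zeroed by each model's transition matrix,
# which makes IMM mixing straightforward.

STATE_DIM <- 10L
POS_IDX <- 1:3; VEL_IDX <- 4:6; ACC_IDX <- 7:9; INT_IDX <- 10L

#' Define a tracker motion model
#'
#' @param name One of `"random"`, `"linear1"`, `"linear2"`.
#' @param sigma_process Process-noise scale, um/s^order: random-walk position
#'   diffusion for `"random"`, white-noise acceleration for `"linear1"`,
#'   white-noise jerk for `"linear2"`. Default 1 (the ~1 um/s run-speed
#'   scale).
#' @param sigma_intensity Intensity random-walk process sd per sqrt(s).
#' @return An object of class `tracker_motion_model`.
#' @export
motion_model <- function(name = c("random", "linear1", "linear2"),
                         sigma_process = 1.0, sigma_intensity = 1.0) {
  name <- match.arg(name)
  structure(list(name = name, sigma_process = sigma_process,
                 sigma_intensity = sigma_intensity),
            class = "tracker_motion_model")
}

# Transition matrix F and process covariance Q for a model at step dt.
model_matrices <- function(model, dt) {
  F <- diag(STATE_DIM)
  q <- model$sigma_process^2
  Q <- matrix(0, STATE_DIM, STATE_DIM)
  if (model$name == "random") {
    F[VEL_IDX, VEL_IDX] <- 0
    F[ACC_IDX, ACC_IDX] <- 0
    for (k in POS_IDX) Q[k, k] <- q * dt
  } else if (model$name == "linear1") {
    for (k in 1:3) F[POS_IDX[k], VEL_IDX[k]] <- dt
    F[ACC_IDX, ACC_IDX] <- 0
    # discrete white-noise acceleration per axis
    for (k in 1:3) {
      p <- POS_IDX[k]; v <- VEL_IDX[k]
      Q[p, p] <- q * dt^4 / 4; Q[p, v] <- Q[v, p] <- q * dt^3 / 2
      Q[v, v] <- q * dt^2
    }
  } else {
    for (k in 1:3) {
      F[POS_IDX[k], VEL_IDX[k]] <- dt
      F[POS_IDX[k], ACC_IDX[k]] <- dt^2 / 2
      F[VEL_IDX[k], ACC_IDX[k]] <- dt
    }
    # discrete white-noise jerk per axis
    for (k in 1:3) {
      p <- POS_IDX[k]; v <- VEL_IDX[k]; a <- ACC_IDX[k]
      Q[p, p] <- q * dt^6 / 36; Q[v, v] <- q * dt^4 / 4; Q[a, a] <- q * dt^2
      Q[p, v] <- Q[v, p] <- q * dt^5 / 12
      Q[p, a] <- Q[a, p] <- q * dt^4 / 6
      Q[v, a] <- Q[a, v] <- q * dt^3 / 2
    }
  }
  Q[INT_IDX, INT_IDX] <- model$sigma_intensity^2 * dt
  list(F = F, Q = Q)
}

#' Plain Kalman time update
#'
#' @param mean State mean vector.
#' @param cov State covariance matrix.
#' @param F,Q Transition matrix and process covariance.
#' @return List with `mean` and `cov`.
#' @export
kalman_predict <- function(mean, cov, F, Q) {
  list(mean = as.numeric(F %*% mean), cov = F %*% cov %*% t(F) + Q)
}

#' Plain Kalman measurement update
#'
#' @param mean,cov Predicted state mean and covariance.
#' @param z Measurement vector.
#' @param H Observation matrix.
#' @param R Measurement covariance.
#' @return List with `mean`, `cov`, `loglik` (Gaussian innovation
#'   log-likelihood) and `S` (innovation covariance).
#' @export
kalman_update <- function(mean, cov, z, H, R) {
  innov <- as.numeric(z - H %*% mean)
  S <- H %*% cov %*% t(H) + R
  S <- (S + t(S)) / 2
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) stop("non-positive innovation covariance")
  Sinv <- chol2inv(ch)
  K <- cov %*% t(H) %*% Sinv
  mean_new <- as.numeric(mean + K %*% innov)
  IKH <- diag(length(mean)) - K %*% H
  # Joseph form for numerical symmetry/PSD
  cov_new <- IKH %*% cov %*% t(IKH) + K %*% R %*% t(K)
  m <- length(innov)
  loglik <- -0.5 * (m * log(2 * pi) + 2 * sum(log(diag(ch))) +
                    sum(innov * (Sinv %*% innov)))
  list(mean = mean_new, cov = cov_new, loglik = loglik, S = S)
}

#' Initialise an IMM filter state
#'
#' @param position Initial position `(x, y, z)`, um.
#' @param intensity Initial intensity measurement.
#' @param models List of [motion_model()] objects (default the standard
#'   random / linear1 / linear2 bank).
#' @param Pi Model-transition matrix (row-stochastic, default 0.90
#'   self-transition, 0.05 cross).
#' @param mu0 Initial model probabilities (default uniform).
#' @param pos_sd,vel_sd,acc_sd,int_sd Initial state sds.
#' @param meas_sd_pos,meas_sd_int Measurement noise sds (um, intensity).
#' @return An object of class `imm_state`.
#' @export
imm_init <- function(position, intensity = 0,
                     models = list(motion_model("random"),
                                   motion_model("linear1"),
                                   motion_model("linear2")),
                     Pi = NULL, mu0 = NULL,
                     pos_sd = 0.5, vel_sd = 1.0, acc_sd = 0.5, int_sd = NULL,
                     meas_sd_pos = 0.1, meas_sd_int = NULL) {
  M <- length(models)
  if (is.null(Pi)) {
    Pi <- matrix((1 - 0.90) / (M - 1), M, M); diag(Pi) <- 0.90
    if (M == 1L) Pi <- matrix(1, 1, 1)
  }
  if (is.null(mu0)) mu0 <- rep(1 / M, M)
  if (any(Pi < 0) || any(abs(rowSums(Pi) - 1) > 1e-8))
    stop("Pi must be row-stochastic")
  if (any(mu0 < 0) || abs(sum(mu0) - 1) > 1e-8)
    stop("mu0 must be a probability vector")
  if (is.null(int_sd)) int_sd <- max(1, abs(intensity) * 0.5)
  if (is.null(meas_sd_int)) meas_sd_int <- max(1, abs(intensity) * 0.25)
  mean0 <- numeric(STATE_DIM)
  mean0[POS_IDX] <- position
  mean0[INT_IDX] <- intensity
  cov0 <- diag(c(rep(pos_sd^2, 3), rep(vel_sd^2, 3), rep(acc_sd^2, 3),
                 int_sd^2))
  H <- matrix(0, 4L, STATE_DIM)
  H[1:3, POS_IDX] <- diag(3); H[4L, INT_IDX] <- 1
  R <- diag(c(rep(meas_sd_pos^2, 3), meas_sd_int^2))
  structure(list(
    models = models, Pi = Pi, mu = mu0,
    means = rep(list(mean0), M), covs = rep(list(cov0), M),
    H = H, R = R,
    mean = mean0, cov = cov0
  ), class = "imm_state")
}

imm_combine <- function(state) {
  M <- length(state$models)
  mean <- Reduce(`+`, Map(`*`, state$means, state$mu))
  cov <- matrix(0, STATE_DIM, STATE_DIM)
  for (j in seq_len(M)) {
    d <- state$means[[j]] - mean
    cov <- cov + state$mu[j] * (state$covs[[j]] + tcrossprod(d))
  }
  state$mean <- mean; state$cov <- cov
  state
}

#' IMM time update (mixing + per-model prediction)
#'
#' Standard IMM step: model-conditioned mixing with weights
#' `Pi[i, j] * mu[i]`, then a Kalman time update per model; the combined
#' estimate is the probability-weighted mixture.
#'
#' @param state An [imm_init()] state.
#' @param dt Time step, s.
#' @return Predicted `imm_state` (with `mean`, `cov` the mixed prediction and
#'   `mu` the predicted model probabilities).
#' @export
imm_predict <- function(state, dt) {
  stopifnot(inherits(state, "imm_state"), dt > 0)
  M <- length(state$models)
  cbar <- as.numeric(t(state$Pi) %*% state$mu)
  new_means <- state$means; new_covs <- state$covs
  for (j in seq_len(M)) {
    if (cbar[j] <= 0) { # unreachable model: carry its own estimate
      mixed_mean <- state$means[[j]]; mixed_cov <- state$covs[[j]]
    } else {
      w <- state$Pi[, j] * state$mu / cbar[j]
      mixed_mean <- Reduce(`+`, Map(`*`, state$means, w))
      mixed_cov <- matrix(0, STATE_DIM, STATE_DIM)
      for (i in seq_len(M)) {
        d <- state$means[[i]] - mixed_mean
        mixed_cov <- mixed_cov + w[i] * (state$covs[[i]] + tcrossprod(d))
      }
    }
    if (!all(is.finite(mixed_cov))) stop("singular mixed covariance")
    mm <- model_matrices(state$models[[j]], dt)
    pr <- kalman_predict(mixed_mean, mixed_cov, mm$F, mm$Q)
    new_means[[j]] <- pr$mean; new_covs[[j]] <- pr$cov
  }
  state$means <- new_means; state$covs <- new_covs; state$mu <- cbar
  imm_combine(state)
}

#' IMM measurement update
#'
#' Kalman-updates every model with the measurement, then reweights the model
#' probabilities by the per-model Gaussian innovation likelihoods.
#'
#' @param state A predicted [imm_state] (from [imm_predict()]).
#' @param z Measurement: `c(x, y, z, intensity)` (or length 3, position
#'   only, in which case the stored intensity prediction is used).
#' @return Updated `imm_state`.
#' @export
imm_update <- function(state, z) {
  stopifnot(inherits(state, "imm_state"))
  z <- as.numeric(z)
  if (length(z) == 3L) z <- c(z, state$mean[INT_IDX])
  if (any(!is.finite(z))) stop("measurement must be finite")
  M <- length(state$models)
  logliks <- numeric(M)
  for (j in seq_len(M)) {
    up <- kalman_update(state$means[[j]], state$covs[[j]], z, state$H, state$R)
    state$means[[j]] <- up$mean; state$covs[[j]] <- up$cov
    logliks[j] <- up$loglik
  }
  w <- state$mu * exp(logliks - max(logliks))
  if (sum(w) <= 0 || !all(is.finite(w))) w <- state$mu
  state$mu <- w / sum(w)
  imm_combine(state)
}

# Innovation covariance of the combined position prediction (3x3).
imm_position_innovation_cov <- function(state) {
  Hp <- state$H[1:3, , drop = FALSE]
  Hp %*% state$cov %*% t(Hp) + state$R[1:3, 1:3]
}
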
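#' Generalized filtering: prediction errors
#'
#' Sensory errors are observation minus predicted observation (identity
#' observation map) on the observed orders; model errors are the belief flow
#' minus the predicted drift, \eqn{\tilde\varepsilon_\omega = D\tilde\mu -
#' \tilde f(\tilde\mu)}, on all belief orders (the top order uses the
#' truncated shift). The precision-weighted first-order sensory errors
#' \eqn{\xi'_{z,l} = 2\Gamma_{z,l}\lambda_z^2 (y'_l - \mu'_l)} are the
#' quantities that drive steering. Masked (empty) sectors contribute zero.
#'
#' @param belief a [make_belief()] matrix (target row iff the frame carries a
#'   target observation).
#' @param frame a sensory frame from [observe_sectors()].
#' @param params a [model_params()] object.
#' @param lambda_z sensory smoothness to use (defaults to the static
#'   parameter; pass the agent's learned value under plasticity).
#' @return list with `eps_z` (rows x 2), `eps_w` (rows x 3),
#'   `xi_z_prime` (length L), `xi_target` (scalar or `NULL`), `mask`.
#' @export
prediction_errors <- function(belief, frame, params,
                              lambda_z = params$lambda_z) {
  L <- params$L
  informed <- is_informed_belief(belief)
  if (informed && is.null(frame$y_target))
    stop("informed belief requires a target observation", call. = FALSE)
  nr <- nrow(belief)
  eps_z <- matrix(0, nr, 2)
  eps_z[seq_len(L), ] <- (frame$y - belief[seq_len(L), 1:2]) * frame$mask
  if (informed) eps_z[nr, ] <- frame$y_target - belief[nr, 1:2]
  eps_w <- gen_shift(unclass(belief)) - gen_drift(belief, params)
  xi <- 2 * params$Gamma_z * lambda_z^2 * eps_z[seq_len(L), 2]
  xi[!frame$mask] <- 0
  xi_target <- if (informed)
    2 * params$Gamma_z_target * lambda_z^2 * eps_z[nr, 2] else NULL
  list(eps_z = eps_z, eps_w = eps_w, xi_z_prime = xi,
       xi_target = xi_target, mask = frame$mask)
}

# per-sector amplitude precisions including the target row when informed
.row_gammas <- function(params, informed) {
  c(params$Gamma_z, if (informed) params$Gamma_z_target)
}

#' Variational free energy (Laplace form)
#'
#' \deqn{F = \tfrac12 \tilde\varepsilon_z^\top \tilde\Pi_z
#'   \tilde\varepsilon_z + \tfrac12 \tilde\varepsilon_\omega^\top
#'   \tilde\Pi_\omega \tilde\varepsilon_\omega
#'   - \tfrac12 \ln\det\tilde\Pi_z - \tfrac12 \ln\det\tilde\Pi_\omega}
#' up to an additive constant. Masked sectors are excluded from both the
#' quadratic and the log-determinant sensory terms (equivalent to infinite
#' sensory variance for that channel on this step). The log-determinants do
#' not move the belief or action gradients but make parameter learning
#' well-posed.
#'
#' @inheritParams prediction_errors
#' @return scalar free energy.
#' @export
free_energy <- function(belief, frame, params, lambda_z = params$lambda_z) {
  pe <- prediction_errors(belief, frame, params, lambda_z)
  informed <- is_informed_belief(belief)
  gam <- .row_gammas(params, informed)
  obs <- c(frame$mask, if (informed) TRUE)
  pi0 <- gam
  pi1 <- 2 * gam * lambda_z^2
  quad_z <- sum((pi0 * pe$eps_z[, 1]^2 + pi1 * pe$eps_z[, 2]^2)[obs])
  logdet_z <- sum((log(pi0) + log(pi1))[obs])

  Pw <- params$Gamma_w * temporal_precision(params$lambda_w, 3L)
  quad_w <- sum(diag(pe$eps_w %*% Pw %*% t(pe$eps_w)))
  logdet_w <- nrow(belief) * determinant(Pw, logarithm = TRUE)$modulus[1]

  0.5 * (quad_z + quad_w) - 0.5 * (logdet_z + logdet_w)
}

#' Analytic free-energy gradient with respect to beliefs
#'
#' Combines the (negative) precision-weighted sensory errors on observed
#' orders with the model-error term
#' \eqn{(D - \partial\tilde f/\partial\tilde\mu)^\top \tilde\Pi_\omega
#' \tilde\varepsilon_\omega}.
#'
#' @inheritParams prediction_errors
#' @return matrix, same shape as `belief`.
#' @export
belief_gradient <- function(belief, frame, params,
                            lambda_z = params$lambda_z) {
  pe <- prediction_errors(belief, frame, params, lambda_z)
  informed <- is_informed_belief(belief)
  gam <- .row_gammas(params, informed)
  obs <- c(frame$mask, if (informed) TRUE)
  nr <- nrow(belief)
  gr <- matrix(0, nr, params$n_orders_x)
  gr[, 1] <- -gam * pe$eps_z[, 1] * obs
  gr[, 2] <- -2 * gam * lambda_z^2 * pe$eps_z[, 2] * obs

  Pw <- params$Gamma_w * temporal_precision(params$lambda_w, 3L)
  w <- pe$eps_w %*% Pw                       # Pw symmetric
  alphas <- c(rep(params$alpha, params$L), if (informed) params$alpha_t)
  # (D + alpha I)^T w: order k picks up w[k-1] + alpha * w[k]
  gr[, 1] <- gr[, 1] + alphas * w[, 1]
  gr[, 2] <- gr[, 2] + w[, 1] + alphas * w[, 2]
  gr[, 3] <- gr[, 3] + w[, 2] + alphas * w[, 3]
  gr
}

#' One Euler step of the belief dynamics
#'
#' \eqn{\tilde\mu \leftarrow \tilde\mu + \Delta t\,(D\tilde\mu - \kappa_\mu
#' \nabla_{\tilde\mu} F)}. The advective shift term lets beliefs track
#' moving trajectories; the gradient assimilates sensory and model
#' prediction errors.
#'
#' @inheritParams prediction_errors
#' @param dt time step, > 0.
#' @return updated belief matrix.
#' @export
belief_step <- function(belief, frame, params, dt,
                        lambda_z = params$lambda_z) {
  stopifnot(dt > 0)
  gr <- belief_gradient(belief, frame, params, lambda_z)
  out <- belief + dt * (gen_shift(unclass(belief)) - params$kappa_mu * gr)
  if (!all(is.finite(out)))
    stop("belief update produced non-finite values", call. = FALSE)
  out
}

#' Analytic free-energy gradient with respect to sensory smoothness
#'
#' Per observed channel: \eqn{2\Gamma\lambda_z \varepsilon'^2 - 1/\lambda_z}
#' (quadratic term through \eqn{\pi' = 2\Gamma\lambda_z^2}, log-determinant
#' term from \eqn{\ln 2\Gamma\lambda_z^2}). With small errors the
#' log-determinant dominates and smoothness grows; large first-order errors
#' drive it down, quadratically increasing responsiveness.
#'
#' @inheritParams prediction_errors
#' @return scalar `dF/dlambda_z`.
#' @export
lambda_gradient <- function(belief, frame, params,
                            lambda_z = params$lambda_z) {
  pe <- prediction_errors(belief, frame, params, lambda_z)
  informed <- is_informed_belief(belief)
  gam <- .row_gammas(params, informed)
  obs <- c(frame$mask, if (informed) TRUE)
  sum((2 * gam * lambda_z * pe$eps_z[, 2]^2 - 1 / lambda_z)[obs])
}

#' One plasticity (parameter-learning) step
#'
#' Free-energy descent on the sensory smoothness parameter at the slow rate
#' `kappa_theta` (default one tenth of `kappa_mu`):
#' \eqn{\lambda_z \leftarrow \lambda_z - \kappa_\theta\, \Delta t\,
#' \partial F/\partial\lambda_z}, clamped to
#' `[lambda_min, lambda_max]`.
#'
#' @inheritParams prediction_errors
#' @param lambda_z current learned smoothness.
#' @param dt time step, > 0.
#' @return updated `lambda_z`.
#' @export
plasticity_step <- function(belief, frame, params, lambda_z, dt) {
  stopifnot(dt > 0)
  g <- lambda_gradient(belief, frame, params, lambda_z)
  min(max(lambda_z - params$kappa_theta * dt * g, params$lambda_min),
      params$lambda_max)
}
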
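#' Generalized-coordinate machinery
#'
#' Beliefs and observations live in generalized coordinates of motion: a
#' latent trajectory is represented by its instantaneous derivatives
#' (value, velocity, acceleration, ...), one column per order. The shift
#' operator `D` advances a generalized vector one order; precisions over
#' orders follow from an assumed Gaussian autocorrelation of the noise.
#'
#' @name generalized
NULL

#' Construct a generalized belief matrix
#'
#' One row per latent channel (the `L` sectors, plus a final `"target"` row
#' for informed agents), one column per derivative order. Sector rows are
#' initialized at the prior fixed point `(eta, 0, ..., 0)`; the target row
#' at `(target_dist, 0, ..., 0)`.
#'
#' @param params a [model_params()] object.
#' @param informed logical; include a target-distance row?
#' @param target_dist initial target-distance mean for the target row.
#' @return numeric matrix of class `"gen_belief"` with
#'   `L (+1)` rows and `n_orders_x` columns.
#' @export
make_belief <- function(params, informed = FALSE, target_dist = 0) {
  n <- params$L + as.integer(informed)
  mu <- matrix(0, n, params$n_orders_x)
  mu[seq_len(params$L), 1] <- params$eta
  rn <- paste0("sector_", seq_len(params$L))
  if (informed) {
    mu[n, 1] <- target_dist
    rn <- c(rn, "target")
  }
  dimnames(mu) <- list(rn, paste0("order_", seq_len(params$n_orders_x) - 1L))
  class(mu) <- c("gen_belief", class(mu))
  mu
}

is_informed_belief <- function(mu) {
  !is.null(rownames(mu)) && rownames(mu)[nrow(mu)] == "target"
}

#' Shift a generalized vector up one order
#'
#' Applies the generalized derivative operator `D`: column `k` of the output
#' is column `k + 1` of the input; the top order is truncated to zero.
#' Applying it `n_orders` times annihilates any input.
#'
#' @param gen_vec matrix with one column per derivative order (a vector is
#'   treated as a single row).
#' @return matrix of the same shape.
#' @examples
#' gen_shift(matrix(c(1, 2, 3), 1)) # -> (2, 3, 0)
#' @export
gen_shift <- function(gen_vec) {
  if (is.null(dim(gen_vec))) gen_vec <- matrix(gen_vec, nrow = 1)
  n <- ncol(gen_vec)
  stopifnot(n >= 1)
  out <- gen_vec
  if (n > 1) out[, seq_len(n - 1)] <- gen_vec[, 2:n] else out[] <- 0
  out[, n] <- 0
  out
}

#' Generalized drift of the dynamics model
#'
#' The dynamics model relaxes each sector distance linearly to the preferred
#' distance: \eqn{f(x) = -\alpha (x - \eta)}. In generalized coordinates the
#' linearized drift applies order-wise: order 0 is
#' \eqn{-\alpha(\mu_l - \eta)}, and order \eqn{k \ge 1} is
#' \eqn{-\alpha \mu_l^{(k)}}. The target row (informed agents) relaxes to
#' zero at rate `alpha_t` in every order.
#'
#' @param belief a [make_belief()] matrix.
#' @param params a [model_params()] object.
#' @return matrix of generalized drifts, same shape as `belief`.
#' @export
gen_drift <- function(belief, params) {
  f <- -params$alpha * belief
  f[seq_len(params$L), 1] <- -params$alpha * (belief[seq_len(params$L), 1] -
                                                params$eta)
  if (is_informed_belief(belief)) {
    tr <- nrow(belief)
    f[tr, ] <- -params$alpha_t * belief[tr, ]
  }
  unclass(f)
}

#' Temporal precision over derivative orders
#'
#' Inverse of the covariance between derivative orders of a stationary noise
#' process with Gaussian autocorrelation
#' \eqn{\rho(h) = \exp(-h^2 / (4\lambda^2))}. Writing
#' \eqn{a = 1/(4\lambda^2)}, the generalized-noise covariance over three
#' orders is
#' \deqn{\tilde\Sigma = \begin{pmatrix} 1 & 0 & -2a \\ 0 & 2a & 0 \\
#'   -2a & 0 & 12a^2 \end{pmatrix},}
#' whose leading 2x2 block inverts to the diagonal form
#' \eqn{\mathrm{diag}(1, 2\lambda^2)} used for two observation orders.
#'
#' @param lambda smoothness parameter, > 0.
#' @param n_orders 2 or 3.
#' @return an `n_orders` x `n_orders` precision matrix.
#' @examples
#' temporal_precision(1, 2) # diag(1, 2)
#' @export
temporal_precision <- function(lambda, n_orders) {
  if (!is.numeric(lambda) || length(lambda) != 1 || !is.finite(lambda) ||
      lambda <= 0)
    stop("lambda must be a single positive number", call. = FALSE)
  if (!n_orders %in% c(2L, 3L))
    stop("n_orders must be 2 or 3", call. = FALSE)
  if (n_orders == 2L) {
    diag(c(1, 2 * lambda^2))
  } else {
    a <- 1 / (4 * lambda^2)
    S <- matrix(c(1,    0,     -2 * a,
                  0,    2 * a,  0,
                  -2 * a, 0,    12 * a^2), 3, 3, byrow = TRUE)
    solve(S)
  }
}

#' Block generalized precision matrix
#'
#' Kronecker product of the per-channel amplitude precisions
#' \eqn{\mathrm{diag}(\Gamma)} with the [temporal_precision()] over orders:
#' channel `l`, order `k` carries diagonal weight
#' `Gamma[l] * temporal_precision(lambda, n)[k, k]`. In particular the
#' first-order sensory precision is \eqn{\pi'_{z,l} = 2\Gamma_{z,l}
#' \lambda_z^2}, the weight on the prediction errors that drive steering.
#'
#' @param Gamma per-channel amplitude precisions, all > 0.
#' @param lambda smoothness parameter, > 0.
#' @param n_orders 2 or 3.
#' @return a `(length(Gamma) * n_orders)` square precision matrix, ordered
#'   channel-major (orders vary fastest).
#' @export
generalized_precision <- function(Gamma, lambda, n_orders) {
  if (!is.numeric(Gamma) || length(Gamma) < 1 || any(!is.finite(Gamma)) ||
      any(Gamma <= 0))
    stop("Gamma must be positive and finite", call. = FALSE)
  kronecker(diag(Gamma, nrow = length(Gamma)),
            temporal_precision(lambda, n_orders))
}
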
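#' Generative-model and update-rate parameters
#'
#' Constructs the full parameter set of an agent's generative model together
#' with the update rates used to discretize the coupled gradient flows on
#' beliefs, heading and (optionally) model parameters.
#'
#' The agent represents the average distance to neighbours within `L` angular
#' sensory sectors as a latent state in generalized coordinates of motion
#' (`n_orders_x` derivative orders for beliefs, `n_orders_y` for
#' observations). Its dynamics model is a linear relaxation
#' \eqn{f(x) = -\alpha (x - \eta)} toward the preferred distance \eqn{\eta};
#' for informed agents an extra target-distance latent relaxes to zero at
#' rate `alpha_t`. Sensory and process precisions factorize into per-channel
#' amplitudes (`Gamma_z`, `Gamma_w`) and temporal smoothness parameters
#' (`lambda_z`, `lambda_w`); see [generalized_precision()].
#'
#' @param L number of sensory sectors.
#' @param sector_width angular width of each sector, degrees. The `L` sectors
#'   tile `[-L*sector_width/2, +L*sector_width/2)` symmetrically about the
#'   heading; the rest of the circle is blind. Defaults to four 60-degree
#'   sectors covering -120..+120 degrees.
#' @param sensing_radius neighbours farther than this are invisible (length
#'   units).
#' @param n_orders_x derivative orders of the belief (3: value, velocity,
#'   acceleration).
#' @param n_orders_y derivative orders observed (2: value and its rate of
#'   change); must be < `n_orders_x`.
#' @param alpha relaxation rate of the distance dynamics model.
#' @param eta preferred (attracting) inter-individual distance, > 0. The
#'   switch point between attraction and repulsion.
#' @param alpha_t relaxation rate of the target-distance dynamics model
#'   (informed agents); the target latent relaxes to 0.
#' @param Gamma_z per-sector sensory amplitude precision (recycled to
#'   length `L`).
#' @param lambda_z sensory smoothness (temporal autocorrelation) parameter.
#' @param Gamma_z_target amplitude precision of target-distance observations.
#' @param Gamma_w process-noise amplitude precision.
#' @param lambda_w process-noise smoothness parameter.
#' @param kappa_mu,kappa_a,kappa_theta update-rate constants for beliefs,
#'   action (heading) and parameter learning. `kappa_theta` defaults to
#'   `kappa_mu / 10`: plasticity runs an order of magnitude more slowly than
#'   inference.
#' @param sigma2_z,sigma2_zprime true generative noise variances on the
#'   zeroth- and first-order distance observations.
#' @param lambda_min,lambda_max clamp bounds for the learned `lambda_z`.
#' @param plasticity logical; update `lambda_z` online by free-energy
#'   descent?
#'
#' @return an object of class `"swarm_params"` (a validated list).
#' @examples
#' p <- model_params()
#' p$eta
#' @export
model_params <- function(L = 4L,
                         sector_width = 60,
                         sensing_radius = 5.0,
                         n_orders_x = 3L,
                         n_orders_y = 2L,
                         alpha = 0.5,
                         eta = 1.0,
                         alpha_t = 0.5,
                         Gamma_z = 1.0,
                         lambda_z = 1.0,
                         Gamma_z_target = 1.0,
                         Gamma_w = 1.0,
                         lambda_w = 1.0,
                         kappa_mu = 15,
                         kappa_a = 3,
                         kappa_theta = kappa_mu / 10,
                         sigma2_z = 0.01,
                         sigma2_zprime = 0.01,
                         lambda_min = 0.1,
                         lambda_max = 5.0,
                         plasticity = FALSE) {
  p <- list(
    L = as.integer(L),
    sector_width = sector_width,
    sensing_radius = sensing_radius,
    n_orders_x = as.integer(n_orders_x),
    n_orders_y = as.integer(n_orders_y),
    alpha = alpha,
    eta = eta,
    alpha_t = alpha_t,
    Gamma_z = rep_len(as.numeric(Gamma_z), L),
    lambda_z = lambda_z,
    Gamma_z_target = Gamma_z_target,
    Gamma_w = Gamma_w,
    lambda_w = lambda_w,
    kappa_mu = kappa_mu,
    kappa_a = kappa_a,
    kappa_theta = kappa_theta,
    sigma2_z = sigma2_z,
    sigma2_zprime = sigma2_zprime,
    lambda_min = lambda_min,
    lambda_max = lambda_max,
    plasticity = isTRUE(plasticity)
  )
  class(p) <- "swarm_params"
  validate_params(p)
  p
}

#' Validate a `swarm_params` object
#'
#' Checks every invariant of the parameter set and raises one error listing
#' all violations (each named by field).
#'
#' @param p a `swarm_params` object.
#' @return `p`, invisibly, if valid.
#' @export
validate_params <- function(p) {
  bad <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) bad <<- c(bad, msg)
  chk(is.numeric(p$L) && p$L >= 1, "L: must be a positive integer")
  chk(is.numeric(p$sector_width) && p$sector_width > 0 &&
        p$L * p$sector_width <= 360,
      "sector_width: sectors must tile at most the full circle")
  chk(p$sensing_radius > 0, "sensing_radius: must be > 0")
  chk(p$n_orders_x >= 2, "n_orders_x: must be >= 2")
  chk(p$n_orders_y >= 1 && p$n_orders_y < p$n_orders_x,
      "n_orders_y: must satisfy 1 <= n_orders_y < n_orders_x")
  chk(p$eta > 0, "eta: must be > 0")
  chk(p$alpha > 0, "alpha: must be > 0")
  chk(p$alpha_t > 0, "alpha_t: must be > 0")
  chk(all(p$Gamma_z > 0), "Gamma_z: all entries must be > 0")
  chk(p$lambda_z > 0, "lambda_z: must be > 0")
  chk(p$Gamma_z_target > 0, "Gamma_z_target: must be > 0")
  chk(p$Gamma_w > 0, "Gamma_w: must be > 0")
  chk(p$lambda_w > 0, "lambda_w: must be > 0")
  chk(p$kappa_mu >= 0, "kappa_mu: must be >= 0")
  chk(p$kappa_a >= 0, "kappa_a: must be >= 0")
  chk(p$kappa_theta >= 0, "kappa_theta: must be >= 0")
  chk(p$sigma2_z >= 0, "sigma2_z: must be >= 0")
  chk(p$sigma2_zprime >= 0, "sigma2_zprime: must be >= 0")
  chk(p$lambda_min > 0 && p$lambda_max > p$lambda_min,
      "lambda_min/lambda_max: need 0 < lambda_min < lambda_max")
  if (length(bad))
    stop("invalid model parameters:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  invisible(p)
}

#' Sector boundary angles
#'
#' Returns the `L + 1` boundary angles (degrees, counterclockwise relative
#' to the heading) of the half-open sector intervals
#' `[b[l], b[l+1])`, `l = 1..L`.
#'
#' @param p a `swarm_params` object.
#' @return numeric vector of length `L + 1`.
#' @export
sector_breaks <- function(p) {
  half <- p$L * p$sector_width / 2
  seq(-half, half, by = p$sector_width)
}

#' @export
print.swarm_params <- function(x, ...) {
  cat("Generative-model parameters (swarm_params)\n")
  cat(sprintf("  geometry : L = %d sectors of %g deg, radius %g\n",
              x$L, x$sector_width, x$sensing_radius))
  cat(sprintf("  orders   : beliefs %d, observations %d\n",
              x$n_orders_x, x$n_orders_y))
  cat(sprintf("  dynamics : alpha = %g, eta = %g, alpha_t = %g\n",
              x$alpha, x$eta, x$alpha_t))
  cat(sprintf("  precision: Gamma_z = [%s], lambda_z = %g, Gamma_w = %g, lambda_w = %g\n",
              paste(signif(x$Gamma_z, 4), collapse = ", "),
              x$lambda_z, x$Gamma_w, x$lambda_w))
  cat(sprintf("  rates    : kappa_mu = %g, kappa_a = %g, kappa_theta = %g\n",
              x$kappa_mu, x$kappa_a, x$kappa_theta))
  cat(sprintf("  noise    : sigma2_z = %g, sigma2_z' = %g\n",
              x$sigma2_z, x$sigma2_zprime))
  cat(sprintf("  plasticity: %s (clamp [%g, %g])\n",
              if (x$plasticity) "on" else "off", x$lambda_min, x$lambda_max))
  invisible(x)
}
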
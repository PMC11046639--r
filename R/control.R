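#' Sector direction vectors (sensorimotor contingencies)
#'
#' Row `l` is the average unit direction from the focal agent toward its
#' sector-`l` neighbours, \eqn{\hat{\Delta r}_l = (1/K)\sum_j (r_j -
#' r)/\|r_j - r\|}: the negative derivative of the sector observation flow
#' with respect to the heading. Empty sectors give zero rows. For informed
#' agents `dT` is the unit vector toward the target.
#'
#' @param state a [make_swarm()] state.
#' @param focal focal agent index.
#' @param memberships output of [assign_sectors()].
#' @return list with `dR` (L x 2 matrix) and `dT` (length 2 or `NULL`).
#' @export
sector_vectors <- function(state, focal, memberships) {
  L <- length(memberships)
  dR <- matrix(0, L, 2)
  r <- state$positions[focal, ]
  for (l in seq_len(L)) {
    js <- memberships[[l]]
    if (length(js) == 0) next
    d <- sweep(state$positions[js, , drop = FALSE], 2, r)
    dist <- sqrt(rowSums(d^2))
    keep <- dist > 0
    if (!any(keep)) next
    dR[l, ] <- colMeans(d[keep, , drop = FALSE] / dist[keep])
  }
  dT <- NULL
  if (state$informed[focal]) {
    dvec <- state$target - r
    dT <- dvec / sqrt(sum(dvec^2))
  }
  list(dR = dR, dT = dT)
}

#' Heading derivative from precision-weighted prediction errors
#'
#' The free-energy descent on the heading reduces to a weighted sum of
#' sector vectors, \eqn{dv/dt = \sum_l \xi'_{z,l} \hat{\Delta R}_l}
#' (plus \eqn{\xi_{target} \Delta T} for informed agents). Only first-order
#' sensory errors enter: the distance itself does not depend instantaneously
#' on the heading, only its flow does. A positive \eqn{\xi'} (neighbours
#' receding faster than believed) pulls toward neighbours; a negative one
#' pushes away — the attraction/repulsion switch sits at the preferred
#' distance.
#'
#' @param errors output of [prediction_errors()].
#' @param vectors output of [sector_vectors()].
#' @return length-2 vector `dv/dt`.
#' @export
heading_derivative <- function(errors, vectors) {
  dv <- colSums(errors$xi_z_prime * vectors$dR)
  if (!is.null(errors$xi_target) && !is.null(vectors$dT))
    dv <- dv + errors$xi_target * vectors$dT
  dv
}

#' Discrete heading update
#'
#' Euler step of the action flow followed by renormalization to unit length:
#' `v <- normalize(v + kappa_a * dt * dvdt)`. A zero update leaves the
#' heading unchanged (the agent keeps its previous velocity when prediction
#' errors vanish).
#'
#' @param heading unit 2-vector.
#' @param dvdt heading derivative.
#' @param kappa_a action update rate.
#' @param dt time step.
#' @return unit 2-vector.
#' @export
apply_heading_update <- function(heading, dvdt, kappa_a, dt) {
  v <- heading + kappa_a * dt * dvdt
  n <- sqrt(sum(v^2))
  if (n == 0) return(heading)
  v / n
}
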
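#' Polarization order parameter
#'
#' \eqn{p = (1/N)\,\|\sum_i v_i\|} for unit headings; 1 for a perfectly
#' aligned group, 0 for balanced opposing headings.
#'
#' @param headings N x 2 matrix of unit headings.
#' @return scalar in `[0, 1]`.
#' @export
polarization <- function(headings) {
  headings <- rbind(headings)
  sqrt(sum(colSums(headings)^2)) / nrow(headings)
}

#' Angular momentum order parameter
#'
#' \eqn{m = (1/N)\,\|\sum_i \hat r_{ic} \times v_i\|} using the scalar 2-D
#' cross product, with \eqn{r_{ic} = r_i - c} the offset from the group
#' centroid, unit-normalized so that `m` lies in `[0, 1]` (1 for a
#' coherently rotating mill). An agent exactly at the centroid contributes
#' zero.
#'
#' @param positions N x 2 matrix.
#' @param headings N x 2 matrix of unit headings.
#' @return scalar in `[0, 1]`.
#' @export
angular_momentum <- function(positions, headings) {
  positions <- rbind(positions)
  headings <- rbind(headings)
  n <- nrow(positions)
  stopifnot(n >= 2)
  ric <- sweep(positions, 2, colMeans(positions))
  d <- sqrt(rowSums(ric^2))
  keep <- d > 0
  cr <- numeric(n)
  cr[keep] <- (ric[keep, 1] * headings[keep, 2] -
                 ric[keep, 2] * headings[keep, 1]) / d[keep]
  abs(sum(cr)) / n
}

#' Milling probability across trials
#'
#' Fraction of trials whose time-averaged angular momentum strictly
#' surpasses the threshold.
#'
#' @param trial_m_hats vector of per-trial time-averaged angular momenta.
#' @param threshold milling threshold (default 0.5).
#' @return proportion in `[0, 1]`.
#' @export
milling_probability <- function(trial_m_hats, threshold = 0.5) {
  stopifnot(length(trial_m_hats) >= 1)
  mean(trial_m_hats > threshold)
}

#' Time-averaged order parameters of a trajectory
#'
#' Computes `p_hat` and `m_hat` as time averages of the per-step order
#' parameters from `t0` (default 5 s, discarding the initial transient) to
#' the end of the trajectory, plus the fragmentation flag for the last 10 s.
#'
#' @param traj a `"swarm_trajectory"`.
#' @param t0 averaging start time, seconds.
#' @return list with `p_hat`, `m_hat`, `fragmented`, and the full
#'   `polarization` / `angular_momentum` series.
#' @export
group_metrics <- function(traj, t0 = 5) {
  sel <- traj$time >= t0
  list(p_hat = mean(traj$polarization[sel]),
       m_hat = mean(traj$angular_momentum[sel]),
       fragmented = fragmentation_check(traj),
       polarization = traj$polarization,
       angular_momentum = traj$angular_momentum)
}

#' Fragmentation check
#'
#' A trial is fragmented when at least one agent stays farther than
#' `threshold` (2.0 length units) from every other agent for at least
#' `min_duration` (3 s) cumulative within the checked window (by default the
#' last 10 s of the trajectory; perturbation runs check the last 5 s of the
#' 20-s post-perturbation period).
#'
#' @param traj a `"swarm_trajectory"`.
#' @param window length-2 time window `c(from, to)`; default
#'   `c(T - 10, T)`.
#' @param threshold isolation distance.
#' @param min_duration cumulative isolation time required, seconds.
#' @return logical.
#' @export
fragmentation_check <- function(traj, window = NULL, threshold = 2.0,
                                min_duration = 3.0) {
  tmax <- traj$time[length(traj$time)]
  if (is.null(window)) window <- c(max(tmax - 10, traj$time[1]), tmax)
  if (window[1] < traj$time[1] - 1e-9 || window[2] > tmax + 1e-9)
    stop("fragmentation window not covered by trajectory", call. = FALSE)
  sel <- which(traj$time >= window[1] & traj$time <= window[2])
  if (length(sel) < 2) stop("window too short", call. = FALSE)
  dt <- diff(traj$time[sel][1:2])
  n <- dim(traj$positions)[2]
  iso_time <- numeric(n)
  for (t in sel) {
    pos <- traj$positions[t, , , drop = TRUE]
    dmat <- as.matrix(stats::dist(pos))
    diag(dmat) <- Inf
    nn <- apply(dmat, 1, min)
    iso_time <- iso_time + dt * (nn > threshold)
  }
  any(iso_time >= min_duration)
}

# Unwrapped angle series of the normalized mean heading.
.group_heading_angle <- function(headings_arr) {
  mx <- apply(headings_arr[, , 1, drop = FALSE], 1, sum)
  my <- apply(headings_arr[, , 2, drop = FALSE], 1, sum)
  ang <- atan2(my, mx)
  d <- diff(ang)
  d <- ((d + pi) %% (2 * pi)) - pi
  cumsum(c(ang[1], d))
}

#' Group turning response after a perturbation
#'
#' Tracks the unwrapped angle of the group mean heading relative to its
#' value at the perturbation time. Returns the relative angle series, the
#' response flag (cumulative absolute turn exceeds `pi` radians within the
#' first 10 s), and the integrated turning magnitude (sum of absolute
#' per-step angle increments) within 500--1,000 ms of the perturbation.
#'
#' @param traj a `"swarm_trajectory"` spanning at least 20 s after
#'   `t_perturb`.
#' @param t_perturb perturbation time, seconds.
#' @return list with `t_rel`, `angle` (radians, relative), `responded`,
#'   `integrated_turn`.
#' @export
turning_response <- function(traj, t_perturb) {
  tmax <- traj$time[length(traj$time)]
  if (tmax < t_perturb + 20 - 1e-9)
    stop("trajectory must span >= 20 s after the perturbation",
         call. = FALSE)
  sel <- which(traj$time >= t_perturb - 1e-9)
  ang <- .group_heading_angle(traj$headings[sel, , , drop = FALSE])
  rel <- ang - ang[1]
  t_rel <- traj$time[sel] - t_perturb
  in10 <- t_rel <= 10 + 1e-9
  responded <- any(abs(rel[in10]) > pi)
  win <- t_rel >= 0.5 - 1e-9 & t_rel <= 1.0 + 1e-9
  steps <- which(win)
  integrated <- if (length(steps) >= 2)
    sum(abs(diff(ang[steps]))) else 0
  list(t_rel = t_rel, angle = rel, responded = responded,
       integrated_turn = integrated)
}
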
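#' Swarm state container
#'
#' Bundles the true world state of all `N` agents: positions, unit headings,
#' per-agent generalized beliefs, learned smoothness parameters, the
#' informed-agent mask and (optionally) a target location.
#'
#' @param positions N x 2 matrix of positions (length units).
#' @param headings N x 2 matrix; rows are normalized to unit length.
#' @param params a [model_params()] object.
#' @param informed logical vector of length N (default all `FALSE`); informed
#'   agents carry a target-distance latent in their beliefs.
#' @param target length-2 target position, or `NULL`.
#' @param beliefs optional list of N [make_belief()] matrices; defaults to
#'   prior-initialized beliefs.
#' @param lambda_z optional per-agent initial smoothness (defaults to
#'   `params$lambda_z`).
#' @param time simulation time, seconds.
#' @return an object of class `"swarm_state"`.
#' @export
make_swarm <- function(positions, headings, params,
                       informed = rep(FALSE, nrow(positions)),
                       target = NULL, beliefs = NULL, lambda_z = NULL,
                       time = 0) {
  positions <- as.matrix(positions)
  headings <- as.matrix(headings)
  n <- nrow(positions)
  stopifnot(ncol(positions) == 2, all(dim(headings) == c(n, 2)),
            all(is.finite(positions)), all(is.finite(headings)),
            length(informed) == n, time >= 0)
  nrm <- sqrt(rowSums(headings^2))
  if (any(nrm == 0)) stop("zero-length heading", call. = FALSE)
  headings <- headings / nrm
  if (any(informed) && is.null(target))
    stop("informed agents require a target", call. = FALSE)
  if (is.null(beliefs)) {
    beliefs <- lapply(seq_len(n), function(i) {
      if (informed[i]) {
        d0 <- sqrt(sum((target - positions[i, ])^2))
        make_belief(params, informed = TRUE, target_dist = d0)
      } else make_belief(params)
    })
  }
  if (is.null(lambda_z)) lambda_z <- rep(params$lambda_z, n)
  structure(list(positions = positions, headings = headings,
                 beliefs = beliefs, lambda_z = lambda_z,
                 informed = informed, target = target, time = time),
            class = "swarm_state")
}

#' @export
print.swarm_state <- function(x, ...) {
  cat(sprintf("swarm_state: %d agents at t = %.3f s (%d informed)\n",
              nrow(x$positions), x$time, sum(x$informed)))
  invisible(x)
}

# bearings (degrees, CCW positive, in (-180, 180]) of offsets (dx, dy)
# relative to unit headings (vx, vy); all arguments conformable arrays
.bearing_deg <- function(dx, dy, vx, vy) {
  atan2(vx * dy - vy * dx, vx * dx + vy * dy) * (180 / pi)
}

# Vectorized sensing for all agents at once. Returns N x L matrices:
# x0 (mean distance), x1 (mean radial separation rate), K (counts),
# mask (K > 0), Rx/Ry (mean unit direction toward sector neighbours).
.sense_geometry <- function(pos, head, params) {
  n <- nrow(pos)
  L <- params$L
  dx <- matrix(pos[, 1], n, n, byrow = TRUE) - pos[, 1]
  dy <- matrix(pos[, 2], n, n, byrow = TRUE) - pos[, 2]
  dist <- sqrt(dx * dx + dy * dy)
  diag(dist) <- Inf
  within <- dist <= params$sensing_radius
  vx <- head[, 1]; vy <- head[, 2]
  bear <- .bearing_deg(dx, dy, vx, vy)
  breaks <- sector_breaks(params)
  # findInterval gives breaks[i] <= x < breaks[i+1]; values at or past the
  # last boundary land in bin L+1 and are dropped, so intervals are half-open
  sec <- matrix(findInterval(bear, breaks), n, n)
  vxj <- matrix(vx, n, n, byrow = TRUE)
  vyj <- matrix(vy, n, n, byrow = TRUE)
  relrad <- (dx * (vxj - vx) + dy * (vyj - vy)) / dist
  ux <- dx / dist; uy <- dy / dist
  distZ <- dist
  diag(distZ) <- 0 # avoid Inf * 0 in the masked sums
  x0 <- x1 <- K <- Rx <- Ry <- matrix(0, n, L)
  for (l in seq_len(L)) {
    M <- within & sec == l
    k <- rowSums(M)
    K[, l] <- k
    kk <- pmax(k, 1)
    x0[, l] <- rowSums(distZ * M) / kk
    x1[, l] <- rowSums(relrad * M) / kk
    Rx[, l] <- rowSums(ux * M) / kk
    Ry[, l] <- rowSums(uy * M) / kk
  }
  list(x0 = x0, x1 = x1, K = K, mask = K > 0, Rx = Rx, Ry = Ry)
}

#' Sector membership of neighbours
#'
#' Assigns every other agent within the sensing radius of the focal agent to
#' the angular sector containing its bearing (half-open intervals
#' `[lower, upper)` in degrees, counterclockwise relative to the focal
#' heading). Agents behind the covered field of view, beyond the radius, or
#' coincident with the focal position are excluded.
#'
#' @param state a [make_swarm()] state.
#' @param focal focal agent index.
#' @param params a [model_params()] object.
#' @return list of `L` integer vectors of neighbour indices.
#' @export
assign_sectors <- function(state, focal, params) {
  pos <- state$positions
  n <- nrow(pos)
  stopifnot(focal >= 1, focal <= n)
  d <- sweep(pos, 2, pos[focal, ])
  dist <- sqrt(rowSums(d^2))
  ok <- dist > 0 & dist <= params$sensing_radius
  ok[focal] <- FALSE
  bear <- .bearing_deg(d[, 1], d[, 2], state$headings[focal, 1],
                       state$headings[focal, 2])
  breaks <- sector_breaks(params)
  sec <- findInterval(bear, breaks)
  lapply(seq_len(params$L), function(l) which(ok & sec == l))
}

#' True sector-wise hidden state
#'
#' Computes, for each sector, the average distance to its member neighbours
#' and the analytic time derivative of that average with the membership held
#' fixed: the mean radial separation rate
#' \eqn{x'_l = (1/K) \sum_j (r_j - r) \cdot (v_j - v) / \|r_j - r\|} (speed
#' 1, unit headings). Empty sectors are marked missing.
#'
#' @param state a [make_swarm()] state.
#' @param focal focal agent index.
#' @param memberships output of [assign_sectors()].
#' @return list with `x0`, `x1` (length-`L`, `NA` where empty) and logical
#'   `mask`.
#' @export
true_hidden_state <- function(state, focal, memberships) {
  L <- length(memberships)
  x0 <- x1 <- rep(NA_real_, L)
  r <- state$positions[focal, ]
  v <- state$headings[focal, ]
  for (l in seq_len(L)) {
    js <- memberships[[l]]
    if (length(js) == 0) next
    d <- sweep(state$positions[js, , drop = FALSE], 2, r)
    dist <- sqrt(rowSums(d^2))
    relv <- sweep(state$headings[js, , drop = FALSE], 2, v)
    x0[l] <- mean(dist)
    x1[l] <- mean((d[, 1] * relv[, 1] + d[, 2] * relv[, 2]) / dist)
  }
  list(x0 = x0, x1 = x1, mask = !is.na(x0))
}

#' Noisy generalized observations of the hidden state
#'
#' Samples `y = x + z`, `y' = x' + z'` with independent Gaussian noise of
#' variance `sigma2_z` and `sigma2_zprime`; missingness is copied from the
#' hidden state. For informed agents the target distance and its rate of
#' change are observed with the same noise variances.
#'
#' @param xh output of [true_hidden_state()].
#' @param params a [model_params()] object.
#' @param x_target optional length-2 true generalized target distance
#'   `(x_t, x_t')` for an informed agent.
#' @return a sensory frame: list with `y` (L x 2 matrix, zero where masked),
#'   logical `mask`, and `y_target` (length 2, or `NULL`).
#' @export
observe_sectors <- function(xh, params, x_target = NULL) {
  L <- length(xh$x0)
  y <- matrix(0, L, 2, dimnames = list(NULL, c("order_0", "order_1")))
  y[, 1] <- ifelse(xh$mask, xh$x0, 0) +
    sqrt(params$sigma2_z) * stats::rnorm(L)
  y[, 2] <- ifelse(xh$mask, xh$x1, 0) +
    sqrt(params$sigma2_zprime) * stats::rnorm(L)
  y[!xh$mask, ] <- 0
  y_target <- NULL
  if (!is.null(x_target)) {
    y_target <- c(x_target[1] + sqrt(params$sigma2_z) * stats::rnorm(1),
                  x_target[2] + sqrt(params$sigma2_zprime) * stats::rnorm(1))
  }
  list(y = y, mask = xh$mask, y_target = y_target)
}

# ---- internal matrix-form engine ------------------------------------------

# Pack a swarm_state into flat matrices for the vectorized stepper.
.pack_state <- function(state, params) {
  n <- nrow(state$positions)
  L <- params$L
  mu0 <- mu1 <- mu2 <- matrix(0, n, L)
  mut <- if (!is.null(state$target)) matrix(0, n, 3) else NULL
  for (i in seq_len(n)) {
    b <- state$beliefs[[i]]
    mu0[i, ] <- b[seq_len(L), 1]
    mu1[i, ] <- b[seq_len(L), 2]
    mu2[i, ] <- b[seq_len(L), 3]
    if (state$informed[i]) mut[i, ] <- b[L + 1L, 1:3]
  }
  list(pos = state$positions, head = state$headings,
       mu0 = mu0, mu1 = mu1, mu2 = mu2, mut = mut,
       lambda = state$lambda_z, informed = state$informed,
       target = state$target, time = state$time)
}

.unpack_state <- function(es, params) {
  n <- nrow(es$pos)
  beliefs <- lapply(seq_len(n), function(i) {
    b <- make_belief(params, informed = es$informed[i])
    b[seq_len(params$L), 1] <- es$mu0[i, ]
    b[seq_len(params$L), 2] <- es$mu1[i, ]
    b[seq_len(params$L), 3] <- es$mu2[i, ]
    if (es$informed[i]) b[params$L + 1L, 1:3] <- es$mut[i, ]
    b
  })
  make_swarm(es$pos, es$head, params, informed = es$informed,
             target = es$target, beliefs = beliefs, lambda_z = es$lambda,
             time = es$time)
}

# Precomputable per-run constants of the stepper.
.engine_const <- function(params) {
  S3 <- temporal_precision(params$lambda_w, 3L)
  list(
    Gmat_cols = params$Gamma_z,         # per-sector amplitude precisions
    s11 = params$Gamma_w * S3[1, 1],
    s13 = params$Gamma_w * S3[1, 3],
    s22 = params$Gamma_w * S3[2, 2],
    s33 = params$Gamma_w * S3[3, 3]
  )
}

# One synchronous Euler-Maruyama step in matrix form. All agents sense,
# update beliefs, heading (and lambda_z if plasticity is on) in parallel
# from the pre-step state, then positions advance with the new headings.
.engine_step <- function(es, params, dt, const, stimulus = NULL) {
  n <- nrow(es$pos)
  L <- params$L
  g <- .sense_geometry(es$pos, es$head, params)
  maskM <- g$mask * 1

  z0 <- matrix(stats::rnorm(n * L, sd = sqrt(params$sigma2_z)), n, L)
  z1 <- matrix(stats::rnorm(n * L, sd = sqrt(params$sigma2_zprime)), n, L)
  y0 <- g$x0 + z0
  y1 <- g$x1 + z1

  if (!is.null(stimulus)) {
    off <- stimulus_offsets(stimulus, es$time)
    if (!is.null(off))
      y1[stimulus$target_agents, ] <-
        y1[stimulus$target_agents, , drop = FALSE] +
        matrix(off, length(stimulus$target_agents), L, byrow = TRUE)
  }

  Gm <- matrix(const$Gmat_cols, n, L, byrow = TRUE)
  lam2 <- es$lambda^2                      # per agent, recycled down columns
  eps0 <- (y0 - es$mu0) * maskM
  eps1 <- (y1 - es$mu1) * maskM
  xi1 <- 2 * Gm * lam2 * eps1

  # model (dynamics) prediction errors and Pi_w-weighted terms
  a <- params$alpha
  ew0 <- es$mu1 + a * (es$mu0 - params$eta)
  ew1 <- es$mu2 + a * es$mu1
  ew2 <- a * es$mu2
  w0 <- const$s11 * ew0 + const$s13 * ew2
  w1 <- const$s22 * ew1
  w2 <- const$s13 * ew0 + const$s33 * ew2

  gr0 <- -Gm * eps0 + a * w0
  gr1 <- -xi1 + w0 + a * w1
  gr2 <- w1 + a * w2

  km <- params$kappa_mu
  mu0n <- es$mu0 + dt * (es$mu1 - km * gr0)
  mu1n <- es$mu1 + dt * (es$mu2 - km * gr1)
  mu2n <- es$mu2 + dt * (-km * gr2)

  dvx <- rowSums(xi1 * g$Rx)
  dvy <- rowSums(xi1 * g$Ry)

  # informed agents: target modality
  if (!is.null(es$target) && any(es$informed)) {
    tx <- es$target[1] - es$pos[, 1]
    ty <- es$target[2] - es$pos[, 2]
    dt_dist <- sqrt(tx * tx + ty * ty)
    dt_dist[dt_dist == 0] <- .Machine$double.eps
    xt0 <- dt_dist
    xt1 <- -(tx * es$head[, 1] + ty * es$head[, 2]) / dt_dist
    yt0 <- xt0 + stats::rnorm(n, sd = sqrt(params$sigma2_z))
    yt1 <- xt1 + stats::rnorm(n, sd = sqrt(params$sigma2_zprime))
    inf <- es$informed
    et0 <- (yt0 - es$mut[, 1]) * inf
    et1 <- (yt1 - es$mut[, 2]) * inf
    xit <- 2 * params$Gamma_z_target * lam2 * et1
    at <- params$alpha_t
    ewt0 <- es$mut[, 2] + at * es$mut[, 1]
    ewt1 <- es$mut[, 3] + at * es$mut[, 2]
    ewt2 <- at * es$mut[, 3]
    wt0 <- const$s11 * ewt0 + const$s13 * ewt2
    wt1 <- const$s22 * ewt1
    wt2 <- const$s13 * ewt0 + const$s33 * ewt2
    grt0 <- -params$Gamma_z_target * et0 + at * wt0
    grt1 <- -xit * inf + wt0 + at * wt1
    grt2 <- wt1 + at * wt2
    mutn <- es$mut
    mutn[, 1] <- es$mut[, 1] + dt * (es$mut[, 2] - km * grt0)
    mutn[, 2] <- es$mut[, 2] + dt * (es$mut[, 3] - km * grt1)
    mutn[, 3] <- es$mut[, 3] + dt * (-km * grt2)
    mutn[!inf, ] <- 0
    dvx <- dvx + xit * inf * (tx / dt_dist)
    dvy <- dvy + xit * inf * (ty / dt_dist)
  } else mutn <- es$mut

  vxn <- es$head[, 1] + params$kappa_a * dt * dvx
  vyn <- es$head[, 2] + params$kappa_a * dt * dvy
  nrm <- sqrt(vxn * vxn + vyn * vyn)
  keep <- nrm == 0
  if (any(keep)) {
    vxn[keep] <- es$head[keep, 1]
    vyn[keep] <- es$head[keep, 2]
    nrm[keep] <- 1
  }
  headn <- cbind(vxn / nrm, vyn / nrm)

  lamn <- es$lambda
  if (params$plasticity && params$kappa_theta > 0) {
    dFdl <- rowSums(2 * Gm * es$lambda * eps1^2 * maskM) -
      rowSums(maskM) / es$lambda
    if (!is.null(es$target) && any(es$informed))
      dFdl <- dFdl + es$informed *
        (2 * params$Gamma_z_target * es$lambda * et1^2 - 1 / es$lambda)
    lamn <- pmin(pmax(es$lambda - params$kappa_theta * dt * dFdl,
                      params$lambda_min), params$lambda_max)
  }

  posn <- es$pos + headn * dt

  if (!all(is.finite(posn)) || !all(is.finite(mu0n))) {
    bad <- which(!is.finite(rowSums(posn) + rowSums(mu0n)))[1]
    stop(sprintf("integration failure at t = %.3f: non-finite state for agent %d",
                 es$time + dt, bad), call. = FALSE)
  }

  list(pos = posn, head = headn, mu0 = mu0n, mu1 = mu1n, mu2 = mu2n,
       mut = mutn, lambda = lamn, informed = es$informed,
       target = es$target, time = es$time + dt)
}

#' Advance the swarm one time step
#'
#' One synchronous forward Euler--Maruyama step of the coupled gradient
#' flows: every agent senses from the pre-step configuration
#' (sector assignment, true hidden state, noisy observation, with optional
#' stimulus offsets added to the first-order observations of targeted
#' agents), updates its beliefs by generalized filtering, rotates its
#' heading down the free-energy gradient (renormalized to unit length),
#' optionally updates its sensory smoothness by plasticity, and finally
#' positions advance by the new heading at unit speed.
#'
#' @param state a [make_swarm()] state.
#' @param params a [model_params()] object.
#' @param dt time step, seconds (default 0.01).
#' @param stimulus optional [build_stimulus()] object.
#' @return the updated `swarm_state`.
#' @export
swarm_step <- function(state, params, dt = 0.01, stimulus = NULL) {
  stopifnot(dt > 0)
  es <- .pack_state(state, params)
  es <- .engine_step(es, params, dt, .engine_const(params),
                     stimulus = stimulus)
  .unpack_state(es, params)
}

# Run the engine for n_steps, recording per-step positions/headings (and
# lambda). Returns the record plus the final engine state (for forking).
# engine = "cpp" uses the compiled stepper (identical update rules and RNG
# draw order); engine = "r" keeps the reference R implementation, retained
# for the dual-route equivalence tests.
.simulate_engine <- function(es, params, dt, n_steps, stimulus = NULL,
                             record = TRUE, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (engine == "cpp")
    return(.simulate_engine_cpp(es, params, dt, n_steps, stimulus, record))
  const <- .engine_const(params)
  n <- nrow(es$pos)
  if (record) {
    pos_arr <- array(NA_real_, c(n_steps + 1L, n, 2))
    head_arr <- array(NA_real_, c(n_steps + 1L, n, 2))
    lam_mat <- matrix(NA_real_, n_steps + 1L, n)
    pos_arr[1, , ] <- es$pos
    head_arr[1, , ] <- es$head
    lam_mat[1, ] <- es$lambda
  }
  t0 <- es$time
  for (s in seq_len(n_steps)) {
    es <- .engine_step(es, params, dt, const, stimulus = stimulus)
    if (record) {
      pos_arr[s + 1L, , ] <- es$pos
      head_arr[s + 1L, , ] <- es$head
      lam_mat[s + 1L, ] <- es$lambda
    }
  }
  out <- list(state = es)
  if (record) {
    out$time <- t0 + dt * (0:n_steps)
    out$positions <- pos_arr
    out$headings <- head_arr
    out$lambda_z <- lam_mat
  }
  out
}

.simulate_engine_cpp <- function(es, params, dt, n_steps, stimulus = NULL,
                                 record = TRUE) {
  const <- .engine_const(params)
  has_target <- !is.null(es$target) && any(es$informed)
  par <- list(L = params$L, breaks = sector_breaks(params),
              radius = params$sensing_radius, alpha = params$alpha,
              eta = params$eta, alpha_t = params$alpha_t,
              Gamma_z = params$Gamma_z,
              Gamma_z_target = params$Gamma_z_target,
              s11 = const$s11, s13 = const$s13, s22 = const$s22,
              s33 = const$s33, kappa_mu = params$kappa_mu,
              kappa_a = params$kappa_a, kappa_theta = params$kappa_theta,
              sd_z = sqrt(params$sigma2_z),
              sd_zp = sqrt(params$sigma2_zprime),
              lambda_min = params$lambda_min,
              lambda_max = params$lambda_max,
              plasticity = isTRUE(params$plasticity))
  stim <- if (!is.null(stimulus)) unclass(stimulus) else NULL
  res <- cpp_simulate(es$pos, es$head, es$mu0, es$mu1, es$mu2,
                      if (has_target) es$mut else matrix(0, 0, 3),
                      es$lambda, es$informed, has_target,
                      if (has_target) es$target else c(0, 0),
                      par, dt, as.integer(n_steps), es$time, stim, record)
  state <- list(pos = res$pos, head = res$head, mu0 = res$mu0,
                mu1 = res$mu1, mu2 = res$mu2,
                mut = if (has_target) res$mut else es$mut,
                lambda = res$lambda, informed = es$informed,
                target = es$target, time = res$time)
  out <- list(state = state)
  if (record) {
    out$time <- es$time + dt * (0:n_steps)
    out$positions <- res$pos_arr
    out$headings <- res$head_arr
    out$lambda_z <- matrix(res$lam_mat, n_steps + 1L, nrow(es$pos))
  }
  out
}

#' Random initial swarm configuration
#'
#' Positions uniform in a square of side `sqrt(n) * spacing * eta` centered
#' at the origin (`spacing` preferred distances per agent on average);
#' headings at uniform random angles. Draws from the current RNG state.
#'
#' @param n number of agents.
#' @param params a [model_params()] object.
#' @param informed logical vector (default none).
#' @param target optional target position.
#' @param spacing mean initial nearest-neighbour spacing in units of `eta`;
#'   the default packs the group slightly tighter than the preferred
#'   distance so no agent starts isolated.
#' @return a [make_swarm()] state.
#' @export
init_swarm <- function(n, params, informed = rep(FALSE, n), target = NULL,
                       spacing = 0.7) {
  side <- sqrt(n) * spacing * params$eta
  pos <- cbind(stats::runif(n, -side / 2, side / 2),
               stats::runif(n, -side / 2, side / 2))
  ang <- stats::runif(n, 0, 2 * pi)
  make_swarm(pos, cbind(cos(ang), sin(ang)), params,
             informed = informed, target = target)
}

#' Run a seeded simulation
#'
#' Initializes a random swarm, integrates `duration_s / dt_s` steps, and
#' returns a trajectory record carrying positions, headings, per-agent
#' smoothness, per-step order parameters, and the full configuration.
#'
#' @param config a [run_config()] object (or list accepted by it).
#' @param seed integer seed for all randomness in this run.
#' @return an object of class `"swarm_trajectory"`: list with `time`,
#'   `positions` (steps+1 x N x 2), `headings`, `lambda_z`,
#'   `polarization`, `angular_momentum`, `config`, `seed`.
#' @export
run_simulation <- function(config, seed) {
  config <- as_run_config(config)
  params <- config$model
  set.seed(seed)
  n_steps <- round(config$duration_s / config$dt_s)
  informed <- rep(FALSE, config$n_agents)
  target <- NULL
  if (!is.null(config$experiment$p_inf) && config$experiment$p_inf > 0) {
    n_inf <- floor(config$experiment$p_inf * config$n_agents + 0.5)
    informed[seq_len(n_inf)] <- TRUE
    tang <- stats::runif(1, 0, 2 * pi)
    tdist <- config$experiment$target_distance %||% 10
    target <- tdist * c(cos(tang), sin(tang))
  }
  st <- init_swarm(config$n_agents, params, informed = informed,
                   target = target)
  es <- .pack_state(st, params)
  rec <- .simulate_engine(es, params, config$dt_s, n_steps)
  as_trajectory(rec, params, config, seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a swarm_trajectory from an engine record.
as_trajectory <- function(rec, params, config = NULL, seed = NA_integer_) {
  nt <- length(rec$time)
  p_t <- vapply(seq_len(nt), function(t)
    polarization(rec$headings[t, , , drop = TRUE]), numeric(1))
  m_t <- vapply(seq_len(nt), function(t)
    angular_momentum(rec$positions[t, , , drop = TRUE],
                     rec$headings[t, , , drop = TRUE]), numeric(1))
  structure(list(time = rec$time, positions = rec$positions,
                 headings = rec$headings, lambda_z = rec$lambda_z,
                 polarization = p_t, angular_momentum = m_t,
                 final_state = rec$state, params = params,
                 config = config, seed = seed),
            class = "swarm_trajectory")
}

#' @export
print.swarm_trajectory <- function(x, ...) {
  cat(sprintf("swarm_trajectory: %d agents, %d recorded steps, t in [%g, %g] s\n",
              dim(x$positions)[2], length(x$time) - 1L,
              x$time[1], x$time[length(x$time)]))
  cat(sprintf("  final polarization %.3f, angular momentum %.3f\n",
              x$polarization[length(x$time)],
              x$angular_momentum[length(x$time)]))
  invisible(x)
}
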
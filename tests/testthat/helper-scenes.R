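# Random scene and parameter generators shared across test files.
# Everything draws from the current RNG so tests control seeds.

rand_params <- function(L = 4L, informed = FALSE) {
  model_params(
    L = L,
    sector_width = 240 / L,
    alpha = runif(1, 0.2, 1.5),
    eta = runif(1, 0.5, 2),
    alpha_t = runif(1, 0.2, 1.5),
    Gamma_z = runif(L, 0.3, 3),
    lambda_z = runif(1, 0.5, 2),
    Gamma_z_target = runif(1, 0.3, 3),
    Gamma_w = runif(1, 0.3, 3),
    lambda_w = runif(1, 0.5, 2)
  )
}

rand_belief <- function(params, informed = FALSE) {
  b <- make_belief(params, informed = informed,
                   target_dist = runif(1, 1, 10))
  b[] <- b + matrix(rnorm(length(b), sd = 0.5), nrow(b))
  b
}

rand_frame <- function(params, informed = FALSE, all_observed = FALSE) {
  L <- params$L
  mask <- if (all_observed) rep(TRUE, L) else runif(L) > 0.3
  if (!any(mask)) mask[sample.int(L, 1)] <- TRUE
  y <- matrix(0, L, 2)
  y[mask, 1] <- runif(sum(mask), 0.2, 3)
  y[mask, 2] <- rnorm(sum(mask), sd = 0.5)
  y_target <- if (informed) c(runif(1, 1, 10), rnorm(1, sd = 0.5)) else NULL
  list(y = y, mask = mask, y_target = y_target)
}

# scene with guaranteed neighbours around a focal agent at the origin
rand_scene <- function(n = 8, params = model_params(), informed = FALSE) {
  pos <- rbind(c(0, 0),
               matrix(runif(2 * (n - 1), -3, 3), n - 1, 2))
  ang <- runif(n, 0, 2 * pi)
  make_swarm(pos, cbind(cos(ang), sin(ang)), params,
             informed = c(informed, rep(FALSE, n - 1)),
             target = if (informed) c(8, 3) else NULL)
}

# numeric central finite-difference gradient
fd_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}
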
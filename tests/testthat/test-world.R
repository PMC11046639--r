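test_that("sector assignment respects bearings, radius, and the blind zone", {
  p <- model_params()
  # focal at origin heading +x; neighbours at bearings 0, 90, 180, distance 6
  st <- make_swarm(rbind(c(0, 0), c(1, 0), c(0, 1), c(-1, 0), c(6, 0)),
                   matrix(c(1, 0), 5, 2, byrow = TRUE), p)
  mem <- assign_sectors(st, 1, p)
  expect_equal(mem[[3]], 2L)          # bearing 0 -> sector [0, 60)
  expect_equal(mem[[4]], 3L)          # bearing 90 -> sector [60, 120)
  expect_false(4L %in% unlist(mem))   # bearing 180: blind zone
  expect_false(5L %in% unlist(mem))   # distance 6 > radius 5
  expect_false(1L %in% unlist(mem))   # self excluded
})

test_that("sector assignment boundaries are half-open", {
  p <- model_params()
  # bearing exactly 0 (representable) falls in [0, 60), not [-60, 0)
  st <- make_swarm(rbind(c(0, 0), c(2, 0)),
                   matrix(c(1, 0), 2, 2, byrow = TRUE), p)
  mem <- assign_sectors(st, 1, p)
  expect_equal(mem[[3]], 2L)
  expect_length(mem[[2]], 0)
  # just inside / outside the covered field of view
  ang_in <- 119.9 * pi / 180; ang_out <- 120.1 * pi / 180
  sti <- make_swarm(rbind(c(0, 0), c(cos(ang_in), sin(ang_in))),
                    matrix(c(1, 0), 2, 2, byrow = TRUE), p)
  expect_equal(assign_sectors(sti, 1, p)[[4]], 2L)
  sto <- make_swarm(rbind(c(0, 0), c(cos(ang_out), sin(ang_out))),
                    matrix(c(1, 0), 2, 2, byrow = TRUE), p)
  expect_length(unlist(assign_sectors(sto, 1, p)), 0)
})

test_that("true hidden state: distances and radial separation rates", {
  p <- model_params()
  # both headed the same way: no relative motion
  st <- make_swarm(rbind(c(0, 0), c(2, 0)), rbind(c(0, 1), c(0, 1)), p)
  mem <- assign_sectors(st, 1, p)
  xh <- true_hidden_state(st, 1, mem)
  l <- which(xh$mask)
  expect_equal(xh$x0[l], 2)
  expect_equal(xh$x1[l], 0)

  # neighbour receding along the separation axis at relative speed ~1
  st2 <- make_swarm(rbind(c(0, 0), c(2, 0)), rbind(c(0, 1), c(1, 0)), p)
  xh2 <- true_hidden_state(st2, 1, assign_sectors(st2, 1, p))
  l2 <- which(xh2$mask)
  expect_equal(xh2$x0[l2], 2)
  expect_equal(xh2$x1[l2], 1)
})

test_that("x' matches the finite-difference derivative with membership fixed", {
  set.seed(70)
  p <- model_params()
  for (rep in 1:20) {
    st <- rand_scene(n = 6, params = p)
    mem <- assign_sectors(st, 1, p)
    xh <- true_hidden_state(st, 1, mem)
    h <- 1e-6
    # advance every agent along its heading (speed 1) and recompute x0
    st2 <- st
    st2$positions <- st$positions + h * st$headings
    xh2 <- true_hidden_state(st2, 1, mem)
    for (l in which(xh$mask))
      expect_equal(xh$x1[l], (xh2$x0[l] - xh$x0[l]) / h, tolerance = 1e-4)
  }
})

test_that("observations are exact in the noiseless limit and seeded deterministically", {
  p0 <- model_params(sigma2_z = 0, sigma2_zprime = 0)
  xh <- list(x0 = c(1, 2, NA, 4), x1 = c(0.1, -0.2, NA, 0),
             mask = c(TRUE, TRUE, FALSE, TRUE))
  fr <- observe_sectors(xh, p0)
  expect_equal(fr$y[, 1], c(1, 2, 0, 4))
  expect_equal(fr$y[, 2], c(0.1, -0.2, 0, 0))

  p <- model_params()
  set.seed(7); a <- observe_sectors(xh, p, x_target = c(5, 0))
  set.seed(7); b <- observe_sectors(xh, p, x_target = c(5, 0))
  expect_identical(a, b)
})

test_that("observation noise has the configured variance", {
  set.seed(71)
  p <- model_params() # sigma2_zprime = 0.01
  xh <- list(x0 = rep(1, 4), x1 = rep(0, 4), mask = rep(TRUE, 4))
  draws <- replicate(25000, observe_sectors(xh, p)$y[, 2])
  v <- stats::var(as.vector(draws)) # 1e5 draws in total
  se <- 0.01 * sqrt(2 / (1e5 - 1))
  expect_lt(abs(v - 0.01), 3 * se)
})

test_that("a lone agent moves in a straight line at unit speed", {
  p <- model_params()
  st <- make_swarm(matrix(c(0, 0), 1), matrix(c(1, 0), 1), p)
  for (k in 1:50) st <- swarm_step(st, p, dt = 0.01)
  expect_equal(st$headings[1, ], c(1, 0))
  expect_equal(st$positions[1, ], c(0.5, 0), tolerance = 1e-12)
  expect_equal(st$time, 0.5)
})

test_that("stepping is deterministic given the seed", {
  p <- model_params()
  cfg <- run_config(n_agents = 12, duration_s = 0.5, model = p)
  t1 <- run_simulation(cfg, seed = 99)
  t2 <- run_simulation(cfg, seed = 99)
  expect_identical(t1$positions, t2$positions)
  expect_identical(t1$headings, t2$headings)
  t3 <- run_simulation(cfg, seed = 100)
  expect_false(identical(t1$positions, t3$positions))
})

test_that("swarm_step agrees with the composition of the per-agent operations", {
  set.seed(72)
  p <- model_params(plasticity = TRUE)
  st <- rand_scene(n = 6, params = p)
  seed_state <- .Random.seed
  new <- swarm_step(st, p, dt = 0.01)

  # oracle: replay the same noise draws through the documented per-agent ops
  .Random.seed <<- seed_state
  n <- 6
  z0 <- matrix(rnorm(n * p$L, sd = sqrt(p$sigma2_z)), n, p$L)
  z1 <- matrix(rnorm(n * p$L, sd = sqrt(p$sigma2_zprime)), n, p$L)
  for (i in seq_len(n)) {
    mem <- assign_sectors(st, i, p)
    xh <- true_hidden_state(st, i, mem)
    fr <- list(y = cbind(ifelse(xh$mask, xh$x0, 0) + z0[i, ],
                         ifelse(xh$mask, xh$x1, 0) + z1[i, ]),
               mask = xh$mask, y_target = NULL)
    fr$y[!xh$mask, ] <- 0
    b2 <- belief_step(st$beliefs[[i]], fr, p, dt = 0.01,
                      lambda_z = st$lambda_z[i])
    pe <- prediction_errors(st$beliefs[[i]], fr, p,
                            lambda_z = st$lambda_z[i])
    sv <- sector_vectors(st, i, mem)
    h2 <- apply_heading_update(st$headings[i, ], heading_derivative(pe, sv),
                               p$kappa_a, 0.01)
    lam2 <- plasticity_step(st$beliefs[[i]], fr, p, st$lambda_z[i], 0.01)
    expect_equal(unclass(new$beliefs[[i]]), unclass(b2), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(new$headings[i, ], h2, tolerance = 1e-12)
    expect_equal(new$lambda_z[i], lam2, tolerance = 1e-12)
    expect_equal(new$positions[i, ], st$positions[i, ] + 0.01 * h2,
                 tolerance = 1e-12)
  }
})

test_that("two noiseless agents settle near the preferred distance", {
  p <- model_params(sigma2_z = 0, sigma2_zprime = 0)
  fx <- make_fixture("pair_at_eta")
  st <- make_swarm(fx$positions * 2, fx$headings, p) # start 2 eta apart
  es <- swarminf:::.pack_state(st, p)
  rec <- swarminf:::.simulate_engine(es, p, 0.01, 3000)
  d_end <- sqrt(sum((rec$state$pos[1, ] - rec$state$pos[2, ])^2))
  expect_lt(abs(d_end - p$eta), 0.1 * p$eta)
  # stationary: spacing no longer changes appreciably over the last 5 s
  ds <- sqrt(rowSums((rec$positions[, 1, ] - rec$positions[, 2, ])^2))
  expect_lt(max(abs(ds[2501:3001] - d_end)), 0.02)
})

test_that("run_simulation records the requested number of steps and metadata", {
  cfg <- run_config(n_agents = 5, duration_s = 0.25)
  traj <- run_simulation(cfg, seed = 3)
  expect_s3_class(traj, "swarm_trajectory")
  expect_length(traj$time, 26) # initial state + 25 steps
  expect_equal(dim(traj$positions), c(26, 5, 2))
  expect_equal(traj$seed, 3)
  expect_identical(traj$config$n_agents, 5L)

  cfg0 <- run_config(n_agents = 4, duration_s = 0)
  traj0 <- run_simulation(cfg0, seed = 1)
  expect_length(traj0$time, 1) # only the initial state
})

test_that("heading rows stay unit after every step", {
  set.seed(73)
  p <- model_params()
  st <- rand_scene(n = 10, params = p)
  for (k in 1:30) {
    st <- swarm_step(st, p, dt = 0.01)
    expect_lt(max(abs(sqrt(rowSums(st$headings^2)) - 1)), 1e-9)
  }
})

test_that("compiled engine reproduces the reference R engine", {
  # informed agents + plasticity + stimulus all active at once
  p <- model_params(plasticity = TRUE)
  set.seed(75)
  st <- init_swarm(12, p, informed = c(rep(TRUE, 4), rep(FALSE, 8)),
                   target = c(6, -2))
  es <- swarminf:::.pack_state(st, p)
  stim <- build_stimulus(3, t_on = 0.5, target_agents = c(1L, 5L))
  # 150 steps: long enough to exercise stimulus on/off phases and target
  # inference, short enough that chaotic amplification of last-bit float
  # differences stays far below the tolerance
  set.seed(123)
  a <- swarminf:::.simulate_engine(es, p, 0.01, 150, stimulus = stim,
                                   engine = "r")
  set.seed(123)
  b <- swarminf:::.simulate_engine(es, p, 0.01, 150, stimulus = stim,
                                   engine = "cpp")
  expect_equal(max(abs(b$positions - a$positions)), 0, tolerance = 1e-12)
  expect_equal(max(abs(b$headings - a$headings)), 0, tolerance = 1e-12)
  expect_equal(max(abs(b$lambda_z - a$lambda_z)), 0, tolerance = 1e-12)
  expect_equal(max(abs(b$state$mut - a$state$mut)), 0, tolerance = 1e-12)
})

test_that("zero-noise trajectories are equivariant under rotation and translation", {
  p <- model_params(sigma2_z = 0, sigma2_zprime = 0)
  set.seed(74)
  st <- rand_scene(n = 6, params = p)
  es <- swarminf:::.pack_state(st, p)
  rec <- swarminf:::.simulate_engine(es, p, 0.01, 100)

  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  shift <- c(3.2, -1.4)
  st2 <- st
  st2$positions <- sweep(st$positions %*% t(R), 2, shift, `+`)
  st2$headings <- st$headings %*% t(R)
  es2 <- swarminf:::.pack_state(st2, p)
  rec2 <- swarminf:::.simulate_engine(es2, p, 0.01, 100)

  back <- sweep(rec2$state$pos, 2, shift) %*% R
  expect_lt(max(abs(back - rec$state$pos)), 1e-8)
  expect_lt(max(abs(rec2$state$head %*% R - rec$state$head)), 1e-8)
})
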
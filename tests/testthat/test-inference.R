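test_that("prediction errors vanish at the fixed point and recompose from shift/drift", {
  p <- model_params()
  b <- make_belief(p)
  frame <- list(y = cbind(rep(p$eta, p$L), rep(0, p$L)),
                mask = rep(TRUE, p$L), y_target = NULL)
  pe <- prediction_errors(b, frame, p)
  expect_equal(pe$eps_z, matrix(0, p$L, 2))
  expect_equal(pe$eps_w, matrix(0, p$L, 3), ignore_attr = TRUE)
  expect_equal(pe$xi_z_prime, rep(0, p$L))

  set.seed(50)
  for (rep in 1:20) {
    p <- rand_params()
    b <- rand_belief(p, informed = TRUE)
    fr <- rand_frame(p, informed = TRUE)
    pe <- prediction_errors(b, fr, p)
    # composition oracle for the model error
    expect_equal(pe$eps_w, gen_shift(unclass(b)) - gen_drift(b, p),
                 ignore_attr = TRUE)
    # masked sectors contribute nothing
    expect_true(all(pe$eps_z[seq_len(p$L), ][!fr$mask, ] == 0))
    expect_true(all(pe$xi_z_prime[!fr$mask] == 0))
  }
})

test_that("first-order errors carry the 2 Gamma lambda^2 precision weight", {
  p <- model_params(Gamma_z = 1, lambda_z = 1)
  b <- make_belief(p)
  fr <- list(y = cbind(b[, 1], b[, 2] + 0.5), mask = rep(TRUE, p$L),
             y_target = NULL)
  pe <- prediction_errors(b, fr, p)
  expect_equal(pe$xi_z_prime, rep(1.0, p$L)) # 2 * 1 * 1 * 0.5
})

test_that("free energy: zero-error value, quadratic scaling, masked exclusion", {
  p <- model_params()
  b <- make_belief(p)
  fr0 <- list(y = cbind(b[, 1], b[, 2]), mask = rep(TRUE, p$L),
              y_target = NULL)
  Pw <- p$Gamma_w * temporal_precision(p$lambda_w, 3)
  const <- -0.5 * (sum(log(p$Gamma_z) + log(2 * p$Gamma_z * p$lambda_z^2)) +
                     p$L * determinant(Pw)$modulus[1])
  expect_equal(free_energy(b, fr0, p), const)

  # masking a sector removes exactly its quadratic + log-det contribution
  fr1 <- fr0
  fr1$y[1, ] <- c(9, 9)     # large error in sector 1 ...
  fr1$mask[1] <- FALSE      # ... but masked out
  ldw <- determinant(p$Gamma_w * temporal_precision(p$lambda_w, 3))$modulus[1]
  m_const <- -0.5 * (sum((log(p$Gamma_z) +
                            log(2 * p$Gamma_z * p$lambda_z^2))[-1]) +
                       p$L * ldw)
  expect_equal(free_energy(b, fr1, p), m_const, ignore_attr = TRUE)
})

test_that("doubling sensory errors quadruples the sensory quadratic term", {
  p <- model_params()
  b <- make_belief(p)
  base <- list(y = cbind(b[, 1], b[, 2]), mask = rep(TRUE, p$L),
               y_target = NULL)
  f0 <- free_energy(b, base, p)
  f1 <- base; f1$y <- base$y + 0.3
  f2 <- base; f2$y <- base$y + 0.6
  expect_equal(free_energy(b, f2, p) - f0,
               4 * (free_energy(b, f1, p) - f0), tolerance = 1e-10)
})

test_that("analytic belief gradient matches central finite differences", {
  set.seed(51)
  worst <- 0
  for (rep in 1:100) {
    p <- rand_params()
    informed <- rep %% 2 == 0
    b <- rand_belief(p, informed = informed)
    fr <- rand_frame(p, informed = informed)
    gr <- belief_gradient(b, fr, p)
    num <- fd_grad(function(v) {
      bb <- b; bb[] <- v
      free_energy(bb, fr, p)
    }, as.vector(b))
    denom <- pmax(abs(num), 1e-3)
    worst <- max(worst, max(abs(as.vector(gr) - num) / denom))
  }
  expect_lt(worst, 1e-6)
})

test_that("belief step is stationary at the fixed point and tracks a static source", {
  p <- model_params()
  b <- make_belief(p)
  fr <- list(y = cbind(b[, 1], b[, 2]), mask = rep(TRUE, p$L),
             y_target = NULL)
  expect_equal(belief_step(b, fr, p, dt = 0.01), b, ignore_attr = TRUE)

  # single-latent system observing a constant c: mu converges between c and
  # eta (precision-weighted compromise); oracle is the linear fixed point
  p1 <- model_params(L = 1L, sector_width = 240)
  c_obs <- 2.5
  fr1 <- list(y = matrix(c(c_obs, 0), 1), mask = TRUE, y_target = NULL)
  b1 <- make_belief(p1)
  for (k in 1:4000) b1 <- belief_step(b1, fr1, p1, dt = 0.005)
  expect_gt(b1[1, 1], p1$eta)
  expect_lt(b1[1, 1], c_obs)
  # analytic stationary point: gradient of F w.r.t. mu vanishes
  gr <- belief_gradient(b1, fr1, p1)
  expect_lt(max(abs(gr - gen_shift(unclass(b1)) / p1$kappa_mu)), 1e-6)
})

test_that("one belief step equals a dense-matrix predictive-coding oracle", {
  set.seed(52)
  for (rep in 1:10) {
    p <- rand_params()
    b <- rand_belief(p)
    fr <- rand_frame(p, all_observed = TRUE)
    dt <- 0.01
    # oracle: build full block matrices explicitly and do the update densely
    L <- p$L
    Pz <- generalized_precision(p$Gamma_z, p$lambda_z, 2L)
    Pw <- generalized_precision(rep(p$Gamma_w, L), p$lambda_w, 3L)
    mu_flat <- as.vector(t(b))                  # channel-major, order fastest
    y_flat <- as.vector(t(fr$y))
    sel <- kronecker(diag(L), cbind(diag(2), c(0, 0)))
    D <- kronecker(diag(L), rbind(c(0, 1, 0), c(0, 0, 1), c(0, 0, 0)))
    J <- kronecker(diag(L), -p$alpha * diag(3))
    eps_z <- y_flat - sel %*% mu_flat
    f_flat <- as.vector(t(gen_drift(b, p)))
    eps_w <- D %*% mu_flat - f_flat
    grad <- -t(sel) %*% Pz %*% eps_z + t(D - J) %*% Pw %*% eps_w
    mu_new <- mu_flat + dt * (D %*% mu_flat - p$kappa_mu * grad)
    got <- belief_step(b, fr, p, dt)
    expect_equal(as.vector(t(got)), as.vector(mu_new), tolerance = 1e-12)
  }
})

test_that("identity-precision single-latent 2-order case is plain predictive coding", {
  # with unit precisions the gradient reduces to -(sensory error) + (model
  # error terms); check the update moves mu toward y and toward the drift
  # alpha = 0 is invalid (no attracting point); a tiny alpha approximates it
  p <- model_params(L = 1L, sector_width = 240, Gamma_z = 1,
                    lambda_z = sqrt(0.5), Gamma_w = 1, lambda_w = sqrt(0.5),
                    alpha = 1e-9, eta = 1)
  b <- make_belief(p); b[1, ] <- c(0, 0, 0)
  fr <- list(y = matrix(c(1, 0), 1), mask = TRUE, y_target = NULL)
  gr <- belief_gradient(b, fr, p)
  # order 0: -(y - mu) * pi0 = -1; model term negligible at alpha ~ 0
  expect_equal(gr[1, 1], -1, tolerance = 1e-6)
})

test_that("lambda gradient matches finite differences and has the right signs", {
  set.seed(53)
  worst <- 0
  for (rep in 1:100) {
    p <- rand_params()
    informed <- rep %% 3 == 0
    b <- rand_belief(p, informed = informed)
    fr <- rand_frame(p, informed = informed)
    lam <- runif(1, 0.3, 3)
    g <- lambda_gradient(b, fr, p, lambda_z = lam)
    num <- fd_grad(function(v) free_energy(b, fr, p, lambda_z = v), lam)
    worst <- max(worst, abs(g - num) / max(abs(num), 1e-3))
  }
  expect_lt(worst, 1e-6)

  # zero errors: log-det dominates, lambda increases
  p <- model_params(plasticity = TRUE)
  b <- make_belief(p)
  fr <- list(y = cbind(b[, 1], b[, 2]), mask = rep(TRUE, p$L),
             y_target = NULL)
  expect_lt(lambda_gradient(b, fr, p), 0)
  expect_gt(plasticity_step(b, fr, p, p$lambda_z, dt = 0.01), p$lambda_z)

  # very large first-order errors: lambda decreases
  fr_big <- fr; fr_big$y[, 2] <- fr_big$y[, 2] + 10
  expect_gt(lambda_gradient(b, fr_big, p), 0)
  expect_lt(plasticity_step(b, fr_big, p, p$lambda_z, dt = 0.01), p$lambda_z)

  # kappa_theta = 0 freezes lambda
  p0 <- model_params(kappa_theta = 0, plasticity = TRUE)
  expect_equal(plasticity_step(b, fr_big, p0, 1.3, dt = 0.01), 1.3)
})

test_that("learned lambda stays inside the clamp bounds for any input sequence", {
  set.seed(54)
  p <- model_params(plasticity = TRUE, kappa_theta = 50) # deliberately huge
  lam <- p$lambda_z
  b <- make_belief(p)
  for (k in 1:200) {
    fr <- rand_frame(p, all_observed = TRUE)
    fr$y[, 2] <- fr$y[, 2] + sample(c(0, 50), 1) # bursts of huge errors
    lam <- plasticity_step(b, fr, p, lam, dt = 0.05)
    expect_gte(lam, p$lambda_min)
    expect_lte(lam, p$lambda_max)
  }
})
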
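space <- build_model_space()

test_that("free energy is exact for a conjugate linear-Gaussian model", {
  set.seed(10)
  n <- 40; p <- 3
  X <- matrix(rnorm(n * p), n, p)
  sigma <- 0.4
  Sigma0 <- diag(0.5^2, p)
  beta <- c(0.3, -0.2, 0.5)
  y <- as.numeric(X %*% beta) + rnorm(n, 0, sigma)
  # conjugate posterior
  Pi0 <- solve(Sigma0)
  H <- crossprod(X) / sigma^2 + Pi0
  Sp <- solve(H)
  mup <- as.numeric(Sp %*% (crossprod(X, y) / sigma^2))
  loglik <- sum(dnorm(y, as.numeric(X %*% mup), sigma, log = TRUE))
  F_laplace <- free_energy(loglik, mup, Sp, rep(0, p), Sigma0)
  F_exact <- lm_log_evidence(y, X, Sigma0, sigma)
  expect_lt(abs(F_laplace - F_exact), 1e-3)
  # posterior = prior with perfect fit: complexity term vanishes
  expect_equal(free_energy(loglik, rep(0, p), Sigma0, rep(0, p), Sigma0),
               loglik)
  # a parameter the data do not constrain leaves F unchanged
  X2 <- cbind(X, 0)
  Sigma0_2 <- diag(0.5^2, p + 1)
  H2 <- crossprod(X2) / sigma^2 + solve(Sigma0_2)
  Sp2 <- solve(H2)
  mup2 <- as.numeric(Sp2 %*% (crossprod(X2, y) / sigma^2))
  loglik2 <- sum(dnorm(y, as.numeric(X2 %*% mup2), sigma, log = TRUE))
  F2 <- free_energy(loglik2, mup2, Sp2, rep(0, p + 1), Sigma0_2)
  expect_lt(abs(F2 - F_laplace), 1e-8)
  expect_error(free_energy(0, c(0, 0), diag(c(1, -1)), c(0, 0), diag(2)),
               "positive definite")
})

test_that("exceedance probabilities match the Beta-comparison quadrature", {
  # symmetric case
  phi <- exceedance_probabilities(c(1, 1), n_draws = 2e5, seed = 1)
  expect_lt(abs(phi[1] - 0.5), 0.01)
  # K = 2: P(r1 > r2) = P(Beta(a1, a2) > 1/2), by numeric integration
  a <- c(8, 2)
  quad <- integrate(function(r) dbeta(r, a[1], a[2]), 0.5, 1)$value
  phi2 <- exceedance_probabilities(a, n_draws = 1e6, seed = 2)
  expect_lt(abs(phi2[1] - quad), 3 / sqrt(1e6) + 0.002)
  expect_lt(abs(sum(phi2) - 1), 1e-12)
  # partition property for larger K
  phi7 <- exceedance_probabilities(c(3, 1, 2, 5, 1, 1, 2),
                                   n_draws = 1e5, seed = 3)
  expect_lt(abs(sum(phi7) - 1), 1e-12)
  expect_error(exceedance_probabilities(c(1, -1)), "positive")
})

test_that("random-effects BMS behaves at its symmetric and decisive limits", {
  # identical evidence: uniform alpha and exceedance
  Fm <- matrix(3.14, 6, 4)
  bms <- rfx_bms(Fm, seed = 1, n_draws = 2e5)
  expect_equal(unname(bms$alpha), rep(1 + 6 / 4, 4))
  expect_true(all(abs(bms$exceedance - 0.25) < 0.01))
  # one model better by 10 nats for every subject: decisive exceedance
  Fm2 <- matrix(0, 8, 3)
  Fm2[, 2] <- 10
  bms2 <- rfx_bms(Fm2, seed = 2, n_draws = 2e5)
  expect_gt(bms2$exceedance[2], 0.99)
  expect_equal(which.max(bms2$alpha), 2L)
  # responsibilities reduce to near-certain subject-level assignments
  expect_true(all(bms2$g[, 2] > 0.99))
  expect_error(rfx_bms(Fm2, alpha0 = 0), "positive")
  expect_error(rfx_bms(matrix(c(1, Inf), 1, 2)), "finite")
})

test_that("model fits are deterministic and honour their preconditions", {
  mod <- space$Diamond
  p <- default_group_params(mod)
  sched <- generate_schedule(6, schedule_config(), seed = 14)
  inputs <- build_dcm_inputs(sched, dt = 0.02, duration = 100)
  b <- simulate_bold(mod, p, hemo_params(), inputs, TR = 2,
                     noise_sd = 0.01, seed = 15)
  f1 <- fit_model(mod, b, inputs, control = fit_control(max_iter = 4))
  f2 <- fit_model(mod, b, inputs, control = fit_control(max_iter = 4))
  expect_identical(f1$mu, f2$mu)
  expect_identical(f1$F, f2$F)
  # iteration cap 0 returns the prior as posterior
  f0 <- fit_model(mod, b, inputs, control = fit_control(max_iter = 0))
  expect_equal(unname(f0$mu), prior_spec(mod)$prior_mean)
  expect_equal(unname(diag(f0$Sigma)), prior_spec(mod)$prior_var)
  # region-count mismatch
  b3 <- b
  b3$Y <- b$Y[, 1:3]
  expect_error(fit_model(mod, b3, inputs), "regions")
})

test_that("fits recover generating parameters from near-noiseless data", {
  mod <- space$Stork3
  p <- default_group_params(mod)
  sched <- generate_schedule(10, schedule_config(), seed = 16)
  inputs <- build_dcm_inputs(sched, dt = 0.02, duration = 160)
  b <- simulate_bold(mod, p, hemo_params(), inputs, TR = 2,
                     noise_sd = 1e-5, seed = 17)
  fit <- fit_model(mod, b, inputs, control = fit_control(max_iter = 40))
  truth <- pack_params(p, mod, fit$priors)
  expect_lt(max(abs(fit$mu - truth)), 0.05)
  # the generating motif out-scores structurally different rivals
  f_diamond <- fit_model(space$Diamond, b, inputs,
                         control = fit_control(max_iter = 40))
  f_legs1 <- fit_model(space$Legs1, b, inputs,
                       control = fit_control(max_iter = 40))
  expect_gt(fit$F, f_diamond$F)
  expect_gt(fit$F, f_legs1$F)
})

test_that("BMS stays undecided on pure-noise data", {
  models <- space[c("Diamond", "Legs1", "Stork3")]
  sched <- generate_schedule(6, schedule_config(), seed = 18)
  inputs <- build_dcm_inputs(sched, dt = 0.02, duration = 100)
  set.seed(19)
  Fm <- t(vapply(1:4, function(s) {
    Y <- matrix(rnorm(50 * 4, 0, 0.02), 50, 4)
    b <- structure(list(Y = Y, TR = 2, model = "noise", seed = s,
                        noise_sd = 0.02, dt = 0.02),
                   class = "bold_series")
    vapply(models, function(m)
      fit_model(m, b, inputs, control = fit_control(max_iter = 8))$F,
      0)
  }, numeric(3)))
  bms <- rfx_bms(Fm, seed = 20, n_draws = 2e5)
  expect_lt(max(bms$exceedance), 0.9)
  expect_lt(max(abs(bms$alpha - bms$alpha0 - 4 / 3)), 1.2)
})

test_that("credible intervals expose the Laplace posterior", {
  mod <- space$Diamond
  p <- default_group_params(mod)
  sched <- generate_schedule(5, schedule_config(), seed = 21)
  inputs <- build_dcm_inputs(sched, dt = 0.02, duration = 80)
  b <- simulate_bold(mod, p, hemo_params(), inputs, TR = 2,
                     noise_sd = 0.01, seed = 22)
  fit <- fit_model(mod, b, inputs, control = fit_control(max_iter = 6))
  ci <- credible_intervals(fit)
  expect_equal(nrow(ci), length(fit$mu))
  expect_true(all(ci$upper >= ci$lower))
  expect_equal(ci$upper - ci$mean, qnorm(0.95) * ci$sd)
})
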
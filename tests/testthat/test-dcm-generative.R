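space <- build_model_space()

test_that("the model space contains the seven named motifs", {
  expect_equal(names(space),
               c("Diamond", "Fork", "Legs1", "Legs2",
                 "Stork1", "Stork2", "Stork3"))
  for (m in space) {
    expect_equal(m$nodes, c("IPL", "rPFC", "DLPFC", "SFG"))
    # common base: driving input to IPL, modulated forward routes,
    # backward DLPFC -> IPL, self-connections
    expect_true(m$C_mask["IPL", "stim"])
    expect_true(m$A_mask["rPFC", "IPL"])
    expect_true(m$A_mask["DLPFC", "IPL"])
    expect_true(m$A_mask["IPL", "DLPFC"])
    expect_true(m$B_masks$regular["rPFC", "IPL"])
    expect_true(m$B_masks$different["DLPFC", "IPL"])
    expect_true(all(diag(m$A_mask)))
    n_gates <- sum(vapply(m$D_masks, sum, 0))
    if (m$class == "nonlinear") expect_gt(n_gates, 0)
    else expect_equal(n_gates, 0)
  }
  # motif-specific wiring
  expect_true(space$Diamond$A_mask["SFG", "rPFC"] &&
                space$Diamond$A_mask["SFG", "DLPFC"])
  expect_true(space$Fork$A_mask["SFG", "IPL"])
  expect_true(space$Fork$B_masks$regular["SFG", "IPL"] &&
                space$Fork$B_masks$different["SFG", "IPL"])
  expect_true(space$Legs1$B_masks$regular["SFG", "DLPFC"])
  expect_true(space$Legs2$B_masks$different["SFG", "rPFC"])
  expect_true(space$Stork1$D_masks$rPFC["SFG", "DLPFC"])
  expect_true(space$Stork2$D_masks$DLPFC["SFG", "rPFC"])
  expect_true(space$Stork3$D_masks$rPFC["SFG", "DLPFC"] &&
                space$Stork3$D_masks$DLPFC["SFG", "rPFC"])
})

test_that("neural drift matches its definition", {
  mod <- space$Stork3
  p <- default_group_params(mod)
  # rest is a fixed point
  expect_equal(neural_drift(rep(0, 4), rep(0, 3), p, mod), rep(0, 4))
  # with all gates zeroed the drift equals the bilinear form exactly
  p0 <- p
  for (k in seq_along(p0$D)) p0$D[[k]][] <- 0
  x <- c(0.3, -0.1, 0.2, 0.05); u <- c(1, 0, 1)
  M <- effective_A(p0) + u[1] * p0$B[[1]] + u[2] * p0$B[[2]] +
    u[3] * p0$B[[3]]
  expect_equal(neural_drift(x, u, p0, mod),
               as.numeric(M %*% x + p0$C %*% u))
  expect_error(neural_drift(rep(0, 3), rep(0, 3), p, mod), "dimension")
})

test_that("a hand-built two-node gate matches the symbolic expansion", {
  toy <- make_2node_model()
  A <- matrix(0, 2, 2); A[2, 1] <- 0.4
  D <- list(R1 = matrix(0, 2, 2), R2 = matrix(0, 2, 2))
  D$R2[2, 1] <- 0.6
  p <- make_dcm_params(toy, A = A, C = matrix(c(1, 0), 2, 1), D = D,
                       theta_self = c(0, 0))
  x <- c(0.5, -0.2); u <- 0.7
  # dx1 = -0.5 x1 + c u ; dx2 = (a21 + d x2) x1 - 0.5 x2
  expect_equal(neural_drift(x, u, p, toy),
               c(-0.5 * x[1] + 1 * u,
                 (0.4 + 0.6 * x[2]) * x[1] - 0.5 * x[2]))
})

test_that("balloon hemodynamics rest at the fixed point with exact constants", {
  hp <- hemo_params(E0 = 0.4)
  rest <- hemodynamics_step(c(0, 1, 1, 1), 0, hp)
  expect_equal(rest$dh, rep(0, 4))
  expect_equal(rest$bold, 0)
  k <- bold_constants(0.4)
  expect_equal(unname(k["k1"]), 2.8)
  expect_equal(unname(k["k2"]), 2)
  expect_equal(unname(k["k3"]), 0.6)
  expect_error(hemodynamics_step(c(0, 1, -1, 1), 0, hp), "non-positive")
})

test_that("stability check reads the rest-state Jacobian", {
  mod <- space$Diamond
  p <- make_dcm_params(mod, theta_self = rep(0, 4))
  st <- stability_check(p, mod)
  expect_true(st$pass)
  expect_equal(st$margin, 0.5)
  # the Jacobian at rest is exactly A: gating terms vanish at x = 0
  expect_equal(effective_A(p), diag(-0.5, 4),
               ignore_attr = TRUE)
  bad <- p
  bad$A["rPFC", "IPL"] <- 3; bad$A["IPL", "rPFC"] <- 3
  expect_false(stability_check(bad, mod)$pass)
})

test_that("compiled integration matches the plain-R reference evaluations", {
  mod <- space$Stork3
  p <- default_group_params(mod)
  sched <- generate_schedule(2, schedule_config(), seed = 4)
  inputs <- build_dcm_inputs(sched, dt = 0.02, duration = 24)
  cpp <- simulate_bold(mod, p, hemo_params(), inputs, TR = 2)
  ref <- r_reference_bold(p, hemo_params(), inputs, TR = 2)
  expect_lt(max(abs(unname(cpp$Y) - ref)), 1e-10)
})

test_that("RK4 sampling agrees with a ten-fold finer reference grid", {
  mod <- space$Stork3
  p <- default_group_params(mod)
  sched <- generate_schedule(4, schedule_config(), seed = 4)
  inputs <- build_dcm_inputs(sched, dt = 0.02, duration = 60)
  coarse <- simulate_bold(mod, p, hemo_params(), inputs, TR = 2)
  fine <- simulate_bold(mod, p, hemo_params(), refine_inputs(inputs, 10),
                        TR = 2)
  expect_lt(max(abs(coarse$Y - fine$Y)), 1e-6)
})

test_that("simulation is deterministic, flat at rest, seeded under noise", {
  mod <- space$Diamond
  p <- default_group_params(mod)
  sched <- generate_schedule(2, schedule_config(), seed = 4)
  inputs <- build_dcm_inputs(sched, dt = 0.02, duration = 30)
  b1 <- simulate_bold(mod, p, hemo_params(), inputs, TR = 2)
  b2 <- simulate_bold(mod, p, hemo_params(), inputs, TR = 2)
  expect_identical(b1$Y, b2$Y)
  zero_inputs <- inputs
  zero_inputs$U[] <- 0
  flat <- simulate_bold(mod, p, hemo_params(), zero_inputs, TR = 2)
  expect_equal(max(abs(flat$Y)), 0)
  n1 <- simulate_bold(mod, p, hemo_params(), inputs, TR = 2,
                      noise_sd = 0.01, seed = 5)
  n2 <- simulate_bold(mod, p, hemo_params(), inputs, TR = 2,
                      noise_sd = 0.01, seed = 5)
  expect_identical(n1$Y, n2$Y)
  expect_gt(max(abs(n1$Y - b1$Y)), 0)
  expect_error(simulate_bold(mod, p, hemo_params(), inputs, TR = 1.33),
               "integer multiple")
})

test_that("a brief neural impulse yields a delayed positive BOLD transient", {
  mod <- space$Diamond
  p <- default_group_params(mod)
  inputs <- structure(list(dt = 0.02,
                           U = cbind(stim = rep(c(1, 0), c(25, 1475)),
                                     regular = 0, different = 0),
                           duration = 30), class = "dcm_inputs")
  b <- simulate_bold(mod, p, hemo_params(), inputs, TR = 0.5)
  ipl <- b$Y[, "IPL"]
  expect_gt(max(ipl), 0)
  peak_t <- which.max(ipl) * 0.5
  expect_gt(peak_t, 3)   # hemodynamic lag of several seconds
  expect_lt(peak_t, 10)
  expect_lt(abs(ipl[length(ipl)]), max(ipl) * 0.35)  # returns to baseline
})

test_that("every Stork reduces to its bilinear skeleton when gates are zero", {
  # Stork3 shares Diamond's A/B/C masks; zeroing its gates must reproduce
  # the Diamond series sample for sample
  pd <- default_group_params(space$Diamond)
  p3 <- default_group_params(space$Stork3)
  for (k in seq_along(p3$D)) p3$D[[k]][] <- 0
  sched <- generate_schedule(3, schedule_config(), seed = 6)
  inputs <- build_dcm_inputs(sched, dt = 0.02, duration = 40)
  bd <- simulate_bold(space$Diamond, pd, hemo_params(), inputs, TR = 2)
  b3 <- simulate_bold(space$Stork3, p3, hemo_params(), inputs, TR = 2)
  expect_equal(unname(b3$Y), unname(bd$Y))
})

test_that("gating makes the SFG response depend on rPFC drive", {
  mod <- space$Stork3
  base <- default_group_params(mod)
  boosted <- base
  boosted$A["rPFC", "IPL"] <- base$A["rPFC", "IPL"] + 0.4
  sched <- generate_schedule(3, schedule_config(), seed = 6)
  inputs <- build_dcm_inputs(sched, dt = 0.02, duration = 40)
  sfg_gap <- function(p) {
    on <- simulate_bold(mod, p, hemo_params(), inputs, TR = 2)$Y[, "SFG"]
    p0 <- p
    for (k in seq_along(p0$D)) p0$D[[k]][] <- 0
    off <- simulate_bold(mod, p0, hemo_params(), inputs, TR = 2)$Y[, "SFG"]
    max(abs(on - off))
  }
  # stronger rPFC activity amplifies the gated (interaction) component
  expect_gt(sfg_gap(boosted), sfg_gap(base) * 1.1)
})

test_that("the neural response is first-order linear in the drive", {
  mod <- space$Diamond
  p1 <- default_group_params(mod)
  p1$C[] <- p1$C * 0.01
  p2 <- p1
  p2$C[] <- p1$C * 2
  sched <- generate_schedule(2, schedule_config(), seed = 6)
  inputs <- build_dcm_inputs(sched, dt = 0.02, duration = 30)
  b1 <- simulate_bold(mod, p1, hemo_params(), inputs, TR = 2)
  b2 <- simulate_bold(mod, p2, hemo_params(), inputs, TR = 2)
  expect_lt(max(abs(b2$Y - 2 * b1$Y)), 0.02 * max(abs(b1$Y)))
})

test_that("unstable parameter sets raise simulation errors", {
  mod <- space$Diamond
  p <- default_group_params(mod)
  p$A["rPFC", "IPL"] <- 4; p$A["IPL", "rPFC"] <- 4
  sched <- generate_schedule(2, schedule_config(), seed = 4)
  inputs <- build_dcm_inputs(sched, dt = 0.02, duration = 30)
  expect_error(simulate_bold(mod, p, hemo_params(), inputs, TR = 2),
               "unstable")
})
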
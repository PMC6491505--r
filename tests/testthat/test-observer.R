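test_that("percept encoding combines internal and stimulus noise", {
  p0 <- observer_params(perceptual_sd = 0, bias = 0)
  set.seed(1)
  pct <- encode_percept(30, 0, p0)
  expect_equal(pct$value, 30)
  expect_equal(pct$known_sd, 0)
  p1 <- observer_params(perceptual_sd = 3, stim_noise_coupling = 1)
  set.seed(1)
  expect_equal(encode_percept(30, 4, p1)$known_sd, 5)  # Pythagorean sum
  # bias shifts the mean of the sampled values
  pb <- observer_params(perceptual_sd = 1, bias = 2)
  set.seed(2)
  draws <- replicate(4000, encode_percept(30, 0, pb)$value)
  expect_lt(abs(mean(draws) - 32), 4 * 1 / sqrt(4000))
  expect_error(encode_percept(30, -1, p1), ">= 0")
})

test_that("stimulus roughness maps to a frequency SD via the cycle count", {
  expect_equal(stimulus_noise_hz(34, 0), 0)
  s <- stimulus_noise_hz(40, 0.08, duration_ms = 512)
  expect_equal(s, 0.08 * 40 / sqrt(40 * 0.512))
})

test_that("faster-slower decisions follow the sign of the difference", {
  pp <- function(v, s = 1) structure(list(value = v, known_sd = s),
                                     class = "percept")
  expect_equal(decide_faster(pp(30), pp(33)), "yes")
  expect_equal(decide_faster(pp(33), pp(30)), "no")
  # accuracy matches the closed form Phi(df / sqrt(s1^2 + s2^2))
  set.seed(3)
  s1 <- 1.5; s2 <- 1; df <- 1
  n <- 20000
  v1 <- rnorm(n, 30, s1); v2 <- rnorm(n, 30 + df, s2)
  acc <- mean(v2 > v1)
  expect_lt(abs(acc - pnorm(df / sqrt(s1^2 + s2^2))), 0.012)
})

test_that("same-different decisions respect the boundary conventions", {
  pp <- function(v, s) structure(list(value = v, known_sd = s),
                                 class = "percept")
  pw <- observer_params(criterion = 1.5)
  # |z| exactly at the criterion resolves to "same" (7.5 / 5 = 1.5)
  expect_equal(decide_different(pp(30, 3), pp(37.5, 4), pw), "no")
  expect_equal(decide_different(pp(30, 3), pp(38, 4), pw), "yes")
  # zero known SD: any nonzero difference is "different", none is "same"
  expect_equal(decide_different(pp(30, 0), pp(30, 0), pw), "no")
  expect_equal(decide_different(pp(30, 0), pp(31, 0), pw), "yes")
  # larger known SD at a fixed percept difference gives fewer "yes"
  rw <- observer_params(criterion = 2, rule = "raw_difference")
  expect_equal(decide_different(pp(30, 1), pp(32.5, 1), rw), "yes")
  expect_equal(decide_different(pp(30, 1), pp(31.5, 1), rw), "no")
  z_narrow <- decide_different(pp(30, 0.5), pp(32.5, 0.5), pw)
  z_wide <- decide_different(pp(30, 3), pp(32.5, 3), pw)
  expect_equal(z_narrow, "yes")
  expect_equal(z_wide, "no")
})

test_that("d-prime matches inverse-normal arithmetic and edge correction", {
  expect_equal(dprime(0.5, 0.5), 0)
  expect_lt(abs(dprime(0.841, 0.159) - 2), 0.01)
  expect_error(dprime(1, 0), "trial count")
  d_edge <- dprime(1, 0, n_signal = 50)
  expect_true(is.finite(d_edge))
  expect_equal(d_edge, qnorm(1 - 1 / 100) - qnorm(1 / 100))
  # invariant to criterion shifts along the same ROC
  d_true <- 1.2
  for (c in c(-0.5, 0, 0.8))
    expect_equal(dprime(pnorm(d_true - c), pnorm(-c)), d_true)
})

test_that("simulated sessions are complete, labelled and reproducible", {
  sched <- generate_schedule(40, schedule_config(), seed = 5)
  pars <- observer_params()
  t1 <- simulate_session(sched, pars, seed = 8)
  t2 <- simulate_session(sched, pars, seed = 8)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 40)
  expect_false(anyNA(t1$choice))
  expect_false(anyNA(t1$correct))
  expect_true(all(t1$choice %in% c("yes", "no")))
  bad <- sched
  bad$noise[3] <- "weird"
  expect_error(simulate_session(bad, pars), "row")
  expect_error(simulate_session(sched[0, ], pars), "no trials")
})

test_that("precision weighting produces the noise-by-difference crossover", {
  cfg <- schedule_config(delta = 2)
  sched <- generate_schedule(2000, cfg, seed = 21)
  pw <- simulate_session(sched, observer_params(), seed = 22)
  acc_pw <- cell_accuracies(pw)
  expect_gt(acc_pw$cell_accuracy[["same_noisy"]],
            acc_pw$cell_accuracy[["same_regular"]])
  expect_gt(acc_pw$cell_accuracy[["different_regular"]],
            acc_pw$cell_accuracy[["different_noisy"]])
  expect_gt(acc_pw$interaction, 0)
  # the raw-difference reader of the same stimuli shows no same-trial
  # noise benefit (the shared jitter sequence cancels in the difference)
  rw <- simulate_session(sched,
                         observer_params(rule = "raw_difference",
                                         criterion = 1.5 * sqrt(2)),
                         seed = 22)
  acc_rw <- cell_accuracies(rw)
  expect_lt(acc_rw$cell_accuracy[["same_noisy"]] -
              acc_rw$cell_accuracy[["same_regular"]], 0.06)
  expect_lt(acc_rw$interaction, acc_pw$interaction)
})

test_that("stimulus noise lowers both hit and false-alarm rates", {
  # mechanism behind the crossover: under precision weighting, noise
  # shifts both response rates toward "same"
  cfg_reg <- schedule_config(delta = 2, noise_fraction = 1e-9)
  cfg_noisy <- schedule_config(delta = 2, noise_fraction = 0.16)
  s_reg <- generate_schedule(1200, cfg_reg, seed = 31)
  s_noisy <- generate_schedule(1200, cfg_noisy, seed = 31)
  pars <- observer_params()
  a_reg <- cell_accuracies(simulate_session(s_reg, pars, seed = 32))
  a_noisy <- cell_accuracies(simulate_session(s_noisy, pars, seed = 32))
  expect_lt(a_noisy$hit_rate, a_reg$hit_rate)
  expect_lt(a_noisy$false_alarm_rate, a_reg$false_alarm_rate)
})

test_that("accuracy tables require every noise-by-difference cell", {
  sched <- generate_schedule(60, schedule_config(), seed = 2)
  tt <- simulate_session(sched, observer_params(), seed = 3)
  expect_error(cell_accuracies(tt[tt$noise == "regular", ]),
               "empty cell")
  path <- tempfile(fileext = ".csv")
  write_accuracy_csv(cell_accuracies(tt), path)
  expect_true("interaction" %in% read.csv(path)$measure)
})
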
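test_that("lambda stepping matches the exponential closed form", {
  a <- attenuation_params(k_d = 0.32, n = 1.29, lambda0 = 1.93, k_f = 0)
  st <- attenuation_state(a)
  expect_equal(st$lam, 1.93)  # initialized at lambda0
  # constant v = 10 mm/s, F = 0: lambda(t) = lambda0 * exp(-k_d * 10^n * t)
  dt <- 1e-3
  for (k in 1:500) st <- lambda_update(st, a, v = 10, F = 0, dt = dt)
  closed <- 1.93 * exp(-0.32 * 10^1.29 * 0.5)
  expect_lt(abs(st$lam - closed) / closed, 1e-10)
  # at rest lambda is unchanged (no rebuilding)
  st2 <- lambda_update(st, a, v = 0, F = 100, dt = 1)
  expect_identical(st2$lam, st$lam)
  expect_error(lambda_update(st, a, v = -1, F = 0, dt = dt), ">= 0")
  # force modulation slows the breakdown
  af <- attenuation_params(k_d = 0.32, n = 1.29, lambda0 = 1.93, k_f = 0.01)
  s_low <- lambda_update(attenuation_state(af), af, v = 10, F = 0, dt = 1)
  s_high <- lambda_update(attenuation_state(af), af, v = 10, F = 50, dt = 1)
  expect_gt(s_high$lam, s_low$lam)
  # a custom modulation law is honored by the reference stepper
  ae <- attenuation_params(k_d = 0.32, n = 1.29, lambda0 = 1.93, k_f = 0.01,
                           force_modulation = function(F) exp(0.01 * max(F, 0)))
  s_exp <- lambda_update(attenuation_state(ae), ae, v = 10, F = 50, dt = 1)
  expect_equal(s_exp$lam,
               1.93 * exp(-0.32 * 10^1.29 / exp(0.5)), tolerance = 1e-12)
})

test_that("clipping and per-process gains follow the stated formulas", {
  a <- attenuation_params(0.3, 1.3, 1.93, 0.001,
                          gamma = c(0, 0, 0.510, 0.990, 0.740, 0.860, 1.000))
  expect_equal(effective_lambda(attenuation_state(a, lam = 1.93)), 1)
  expect_equal(effective_lambda(attenuation_state(a, lam = 0.4)), 0.4)
  expect_equal(effective_lambda(attenuation_state(a, lam = 1)), 1)
  # beta_i = 1 - gamma_i * (1 - lam_eff), checked against scalar arithmetic
  b <- beta_gains(a, 0.5)
  expect_equal(b, 1 - c(0, 0, 0.510, 0.990, 0.740, 0.860, 1.000) * 0.5)
  expect_true(all(b >= 0.5 & b <= 1))
  expect_equal(min(b), 0.5)  # some gamma_i = 1, so min beta = lam_eff
  expect_equal(beta_gains(a, 1), rep(1, 7))
  a0 <- attenuation_params(0.3, 1.3, 2, gamma = rep(0, 7))
  expect_equal(beta_gains(a0, 0.2), rep(1, 7))
  expect_error(beta_gains(a, 1.2), "\\[0, 1\\]")
  expect_error(attenuation_params(0.3, 1.3, 0.9), "lambda0")
  expect_error(attenuation_params(-0.1, 1.3, 2), "k_d")
  expect_error(attenuation_params(0.3, 1.3, 2, gamma = rep(2, 7)), "gamma")
})

test_that("reset restores lambda0 and rest holds it there", {
  a <- load_fixture("qlv_anlv", "m3SR")$attenuation
  st <- attenuation_state(a)
  for (k in 1:100) st <- lambda_update(st, a, v = 50, F = 0, dt = 1e-3)
  expect_lt(st$lam, 1)
  st <- reset_state(st, a)
  expect_equal(st$lam, a$lambda0)
  for (k in 1:100) st <- lambda_update(st, a, v = 0, F = 0, dt = 0.45)
  expect_equal(st$lam, a$lambda0)  # 45 s of rest: no rebuilding modeled
})

test_that("lambda trajectories are non-increasing between resets and frozen at rest", {
  m <- load_fixture("qlv_anlv", "m4LR")
  s <- make_step(0.5, rise_time = 0.025, hold_duration = 1)
  dbl <- concat_protocols(list(s, s), isi = 2, reset_before_second = TRUE)
  sim <- simulate(m, protocol = dbl)
  jump <- which(diff(sim$lam) > 1e-12)
  # the only increase is the reset, back to exactly lambda0
  expect_length(jump, 1)
  expect_equal(sim$lam[jump + 1], m$attenuation$lambda0)
  expect_equal(sim$t[jump + 1], dbl$resets, tolerance = 1e-9)
  # during holds (v = 0) lambda and the gains are constant, so each
  # attenuated process decays exactly exponentially
  hold <- sim$t > 0.5 & sim$t < 1.0
  expect_equal(diff(range(sim$lam[hold])), 0)
  x5 <- sim$F_processes[hold, 5] * sim$beta[hold, 5]
  ratios <- x5[-1] / x5[-length(x5)]
  expect_lt(diff(range(ratios)), 1e-10)
  expect_equal(ratios[1], exp(-sim$dt / DEFAULT_TAU[5]), tolerance = 1e-12)
})

test_that("after a reset at 45 s ISI the second step replays an independent run", {
  # lambda0 = 3 and a gentle 25 ms rise keep lambda above 1 throughout a
  # single 0.5 mm step, so the attenuated model stays in the unattenuated
  # regime and the second step must reproduce a fresh single-step run on
  # top of the first step's residual relaxation
  m <- load_fixture("qlv_anlv", "m3SR")
  s1 <- make_step(0.5, rise_time = 0.025, hold_duration = 1,
                  start_length = 0)
  s2 <- make_step(0.5, rise_time = 0.025, hold_duration = 3,
                  start_length = 0)
  dbl <- concat_protocols(list(s1, s2), isi = 45, reset_before_second = TRUE)
  sim_d <- simulate(m, protocol = dbl)
  expect_true(all(sim_d$lam >= 1))  # unattenuated regime throughout

  onset <- dbl$resets
  # independent second-step run, starting from the first step's plateau
  run2 <- simulate(m, protocol = make_step(0.5, rise_time = 0.025,
                                           hold_duration = 3,
                                           start_length = 0.5))
  # extended first-step run covering the whole sequence
  run1 <- simulate(m, protocol = make_step(
    0.5, rise_time = 0.025, start_length = 0,
    hold_duration = dbl$t[length(dbl$t)] - 0.025))
  seg <- sim_d$t >= onset - 1e-9
  k0 <- which(seg)[1]
  idx2 <- seq_len(sum(seg))
  resid1 <- run1$F_total[k0 + idx2 - 1] - lt_force(m$lt, 0.5)
  expect_lt(max(abs(sim_d$F_total[seg] -
                    (run2$F_total[idx2] + resid1))), 1e-9)
})
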
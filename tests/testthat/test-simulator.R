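test_that("a held muscle sits on its length-tension curve", {
  m <- synthetic_base_qlv()
  p <- make_ramp(1, 0, start_length = 3, hold_duration = 1)  # pure hold
  s <- simulate(m, protocol = p)
  expect_equal(s$F_total, rep(lt_force(m$lt, 3), length(s$t)))
  # steady-state force is the static curve
  expect_equal(steady_state_force(m, 0), m$lt$c0)
  L <- seq(0, 8, by = 0.5)
  expect_true(all(diff(steady_state_force(m, L)) >= 0))
  # after a step, a hold of 10 * max(tau) relaxes to within 1% of the
  # step's peak dynamic force
  p2 <- make_step(0.5, rise_time = 0.025, hold_duration = 10 * max(m$tau),
                  start_length = 2, dt = 0.005)
  s2 <- simulate(m, protocol = p2)
  stat <- lt_force(m$lt, 2.5)
  peak_dyn <- max(s2$F_total) - stat
  expect_lt(abs(s2$F_total[length(s2$t)] - stat), 0.01 * peak_dyn)
})

test_that("the decomposition identity holds at every sample", {
  for (m in list(synthetic_base_aqlv(), load_fixture("qlv_anlv", "m4LR"))) {
    s <- simulate(m, protocol = make_saccadic(3, 130, hold_duration = 2))
    recomposed <- s$F_elastic + rowSums(s$beta * s$F_processes) + s$F_viscous
    expect_lt(max(abs(s$F_total - recomposed)), 1e-10)
    if (!inherits(m, "anlv_model")) {
      expect_true(all(s$beta == 1))
    }
  }
})

test_that("linear-limit step and ramp responses match their closed forms", {
  m <- linear_qlv()
  # ideal step: rise time far below min(tau); the velocity impulse is
  # centered at rise/2, so the closed form is shifted by that centroid
  rise <- 5e-4; dt <- 1e-4
  p <- make_step(0.4, rise_time = rise, hold_duration = 3, dt = dt)
  s <- simulate(m, protocol = p)
  post <- s$t >= 2 * rise
  cf <- step_dyn_closed_form(m, 0.4, s$t[post], t_c = rise / 2)
  dyn <- s$F_total[post] - lt_force(m$lt, s$L[post])
  expect_lt(max(abs(dyn - cf) / cf), 0.005)
  # constant-speed ramp: F_dyn(t) = sum alpha g_i c1 v tau_i (1 - e^(-t/tau_i))
  pr <- make_ramp(5, 4, hold_duration = 0)
  sr <- simulate(m, protocol = pr)
  el <- sr$t <= 0.8
  cf_r <- ramp_dyn_closed_form(m, 5, sr$t[el])
  dyn_r <- sr$F_total[el] - lt_force(m$lt, sr$L[el])
  expect_lt(max(abs(dyn_r - cf_r)[-1] / cf_r[-1]), 0.005)
})

test_that("attenuation with k_d = 0 reduces bit-identically to the base model", {
  base <- synthetic_base_qlv()
  off <- anlv_model(base, attenuation_params(k_d = 0, n = 1.3, lambda0 = 2,
                                             gamma = rep(1, 7)))
  p <- make_saccadic(4, 160, hold_duration = 2)
  expect_identical(simulate(off, protocol = p)$F_total,
                   simulate(base, protocol = p)$F_total)
  # likewise when lambda0 is large enough that lambda never reaches 1
  tall <- anlv_model(base, attenuation_params(k_d = 0.01, n = 1, lambda0 = 4,
                                              gamma = rep(1, 7)))
  s <- simulate(tall, protocol = make_step(0.5, hold_duration = 1))
  expect_true(all(s$lam > 1))
  expect_identical(s$F_total,
                   simulate(base, protocol = make_step(0.5, hold_duration = 1))$F_total)
})

test_that("superposition holds in the linear limit and is broken by attenuation", {
  m <- linear_qlv()
  s_short <- make_step(0.5, hold_duration = 0.5)
  s_long <- make_step(0.5, hold_duration = 2)
  for (isi in c(0.1, 1)) {
    dbl <- concat_protocols(list(s_short, s_long), isi = isi)
    f_d <- simulate(m, protocol = dbl)$F_total - lt_force(m$lt, dbl$L)
    s_one <- simulate(m, protocol = make_step(
      0.5, hold_duration = dbl$t[length(dbl$t)] - 0.005))
    one <- s_one$F_total - lt_force(m$lt, s_one$L)
    onset_k <- round((0.505 + isi) / dbl$dt) + 1
    two <- simulate(m, protocol = s_long)$F_total - lt_force(m$lt, s_long$L)
    shifted <- c(rep(0, onset_k), two[-1])  # second step contributes 0 at onset
    expect_lt(max(abs(f_d - (one + shifted))), 1e-8)
  }
  # the attenuated model must violate superposition at short ISI: this is
  # the structural failure of convolution models the attenuation encodes
  att <- load_fixture("qlv_anlv", "m4LR")$attenuation
  ma <- anlv_model(m, att)
  sac <- make_saccadic(1.6, 100, hold_duration = 2)
  dbl <- concat_protocols(list(make_saccadic(1.6, 100, hold_duration = 0.5),
                               sac), isi = 0.1)
  f_d <- simulate(ma, protocol = dbl)$F_total - lt_force(m$lt, dbl$L)
  s_one <- simulate(ma, protocol = make_saccadic(
    1.6, 100, hold_duration = dbl$t[length(dbl$t)] - dbl$phases$end[1]))
  one <- s_one$F_total - lt_force(m$lt, s_one$L)
  onset_k <- which(abs(dbl$t - (dbl$phases$end[1] + 0.5 + 0.1)) < 1e-9)
  two <- simulate(ma, protocol = sac)$F_total - lt_force(m$lt, sac$L)
  shifted <- c(rep(0, onset_k), two[-1])
  expect_gt(max(abs(f_d - (one + shifted))), 0.3)
})

test_that("refining the integration grid barely changes the force", {
  m <- load_fixture("qlv_anlv", "m4LR")
  p <- make_ramp(160, 8, hold_duration = 1.5)  # fastest protocol
  s1 <- simulate(m, protocol = p)
  s2 <- simulate(m, protocol = p, dt = p$dt / 2)
  common <- seq(1, length(s2$t), by = 2)
  expect_equal(s2$t[common], s1$t, tolerance = 1e-9)
  expect_lt(max(abs(s2$F_total[common] - s1$F_total)) / max(abs(s1$F_total)),
            0.001)
})

test_that("inconsistent protocols are refused with a report", {
  p <- make_saccadic(2, 100, hold_duration = 0.5)
  bad <- p
  bad$v <- bad$v * 1.01
  expect_error(simulate(synthetic_base_qlv(), protocol = bad),
               "inconsistent protocol")
  # but an explicit opt-out allows simulating them
  s <- simulate(synthetic_base_qlv(), protocol = bad,
                check_consistency = FALSE)
  expect_true(is.numeric(s$F_total))
})
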
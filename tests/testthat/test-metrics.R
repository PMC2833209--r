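test_that("dynamic force subtracts the static curve", {
  m <- synthetic_base_qlv()
  hold <- make_ramp(1, 0, start_length = 4, hold_duration = 1)
  s <- simulate(m, protocol = hold)
  expect_equal(dynamic_force(s, m$lt, 0.5), 0)
  # constructed trace sitting a constant delta above the static curve
  tr <- measured_trace(t = seq(0, 1, by = 0.01),
                       F = rep(lt_force(m$lt, 2) + 1.25, 101), t_end = 0,
                       L = rep(2, 101))
  expect_equal(dynamic_force(tr, m$lt, 0.7), 1.25)
  expect_error(dynamic_force(tr, m$lt, 2), "outside")
  # end of a linear-limit ramp matches the closed form
  lin <- linear_qlv()
  p <- make_ramp(5, 4, hold_duration = 0.5)
  s2 <- simulate(lin, protocol = p)
  # evaluated inside the constant-speed phase, where the update is exact
  expect_equal(dynamic_force(s2, lin$lt, 0.75),
               ramp_dyn_closed_form(lin, 5, 0.75), tolerance = 1e-6)
})

test_that("viscoelastic ratio behaves as a model-overestimation index", {
  m <- load_fixture("qlv_anlv", "m4LR")
  base <- m$base
  p <- make_saccadic(3, 130, start_length = 3, hold_duration = 1)
  s_model <- simulate(base, protocol = p)
  expect_equal(viscoelastic_ratio(s_model, s_model, base$lt), 1)
  # a "data" trace exactly on the static curve gives 0
  t_end_model <- max(p$phases$end[p$phases$label == "elongation"])
  flat <- measured_trace(s_model$t, rep(lt_force(base$lt, 6), length(s_model$t)),
                         t_end_model, L = s_model$L)
  expect_equal(viscoelastic_ratio(flat, s_model, base$lt), 0)
  # invariant to adding a common constant to both traces and to c0
  s_att <- simulate(m, protocol = p)
  r <- viscoelastic_ratio(s_att, s_model, base$lt)
  lt_up <- length_tension(base$lt$c0 + 5, base$lt$c1, base$lt$c2, base$lt$c3)
  bump <- function(s, d) { s2 <- s; s2$F_total <- s2$F_total + d; s2 }
  expect_equal(viscoelastic_ratio(bump(s_att, 5), bump(s_model, 5), lt_up), r,
               tolerance = 1e-9)
  # attenuated model as "data" against its own base: ratio < 1, and it
  # decreases with saccade amplitude (amplitudes 1..3 mm, common final length)
  ratios <- vapply(list(c(1, 60), c(2, 100), c(3, 130)), function(ap) {
    pp <- make_saccadic(ap[1], ap[2], start_length = 6 - ap[1],
                        hold_duration = 0.5)
    viscoelastic_ratio(simulate(m, protocol = pp),
                       simulate(base, protocol = pp), base$lt)
  }, numeric(1))
  expect_true(all(ratios < 1))
  expect_true(all(diff(ratios) < 0))
  # undefined when the model's viscoelastic force is below the floor
  still <- simulate(base, protocol = make_ramp(1, 0, start_length = 2,
                                               hold_duration = 0.5))
  still$protocol$phases$label <- "elongation"  # degenerate: no motion at all
  expect_error(viscoelastic_ratio(still, still, base$lt), "floor")
})

test_that("cross-over detection matches the analytic crossing of two exponentials", {
  t <- seq(0, 8, by = 0.001)
  a <- 3; b <- 2
  fam <- trace_family(
    fast = measured_trace(t, a * exp(-t / 1), t_end = 0),
    slow = measured_trace(t, b * exp(-t / 10), t_end = 0),
    check = FALSE)
  cx <- detect_crossover(fam, t_probe = 5)
  expect_true(cx$crossover)
  t_star <- log(a / b) / (1 - 0.1)
  expect_equal(cx$pairs$first_crossing_s, t_star, tolerance = 0.001 / t_star)
  # identical traces: no cross-over, no crossing time
  fam_id <- trace_family(x = measured_trace(t, exp(-t), 0),
                         y = measured_trace(t, exp(-t), 0), check = FALSE)
  cx_id <- detect_crossover(fam_id)
  expect_false(cx_id$crossover)
  expect_true(is.na(cx_id$pairs$first_crossing_s))
  # permutation invariance of the family order
  fam_rev <- trace_family(
    slow = measured_trace(t, b * exp(-t / 10), t_end = 0),
    fast = measured_trace(t, a * exp(-t / 1), t_end = 0),
    check = FALSE)
  cx_rev <- detect_crossover(fam_rev, t_probe = 5)
  expect_equal(cx_rev$crossover, cx$crossover)
  expect_equal(cx_rev$pairs$first_crossing_s, cx$pairs$first_crossing_s)
})

test_that("convergence time finds when a family's relaxations collapse", {
  t <- seq(0, 5, by = 0.01)
  fam_id <- trace_family(x = measured_trace(t, exp(-t), 0),
                         y = measured_trace(t, exp(-t), 0), check = FALSE)
  expect_equal(convergence_time(fam_id, tol = 0.01), 0)
  # constant offset of twice the tolerance: never reached
  fam_off <- trace_family(x = measured_trace(t, exp(-t), 0),
                          y = measured_trace(t, exp(-t) + 0.02, 0),
                          check = FALSE)
  expect_identical(convergence_time(fam_off, tol = 0.01), Inf)
  # two decaying exponentials converge when their difference drops below tol
  fam_2 <- trace_family(x = measured_trace(t, 2 * exp(-t), 0),
                        y = measured_trace(t, exp(-t), 0), check = FALSE)
  expect_equal(convergence_time(fam_2, tol = 0.1), log(1 / 0.1),
               tolerance = 0.02)
})

test_that("trace families require a common final length", {
  m <- synthetic_base_qlv()
  s6 <- simulate(m, protocol = make_saccadic(2, 100, start_length = 4,
                                             hold_duration = 0.5))
  s5 <- simulate(m, protocol = make_saccadic(2, 100, start_length = 3,
                                             hold_duration = 0.5))
  expect_error(trace_family(s6, s5), "final length")
  expect_s3_class(trace_family(s6, s6), "trace_family")
})
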
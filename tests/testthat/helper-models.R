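# Shared fixtures, built in code.

# Linear-limit QLV: linear length-tension, no viscosity. In this limit the
# purely viscoelastic response has closed forms for steps and ramps, and
# obeys superposition.
linear_qlv <- function(c0 = 1, c1 = 2, g = c(0.25, 0.25, 0.25, 0.3, 0.35, 0.5, 1.4),
                       alpha = 0.5, tau = DEFAULT_TAU) {
  qlv_model(length_tension(c0 = c0, c1 = c1), g = g, alpha = alpha,
            tau = tau, viscosity = NULL)
}

# closed-form dynamic force of the linear-limit QLV under a constant-speed
# ramp started at t = 0: sum_i alpha g_i c1 v tau_i (1 - exp(-t / tau_i))
ramp_dyn_closed_form <- function(model, v, t) {
  k <- model$alpha * model$g * model$lt$c1
  vapply(t, function(tt) sum(k * v * model$tau * (1 - exp(-tt / model$tau))),
         numeric(1))
}

# closed-form post-step decay for an ideal step of amplitude dL whose
# velocity impulse is centered at t_c: sum_i alpha g_i c1 dL exp(-(t-t_c)/tau_i)
step_dyn_closed_form <- function(model, dL, t, t_c = 0) {
  k <- model$alpha * model$g * model$lt$c1
  vapply(t, function(tt) sum(k * dL * exp(-(tt - t_c) / model$tau)),
         numeric(1))
}

# viscoelastic part of a simulation (gains applied)
sim_visco <- function(s) rowSums(s$beta * s$F_processes)

# ramp family over the full range with a common final length
ramp_family_sims <- function(model, speeds = c(1, 10, 80, 160), range = 8,
                             hold = 2.5, dt = 0.001) {
  sims <- lapply(speeds, function(sp)
    simulate(model, protocol = make_ramp(sp, range, hold_duration = hold,
                                         dt = dt)))
  trace_family(sims, labels = paste0("v", speeds))
}

# saccadic family: amplitudes 1/2/3 mm at main-sequence-like speeds, all
# ending at 6 mm of elongation
saccade_family_sims <- function(model, hold = 3, dt = 0.001) {
  amps <- c(1, 2, 3); speeds <- c(60, 100, 130)
  sims <- lapply(seq_along(amps), function(i)
    simulate(model, protocol = make_saccadic(
      amps[i], speeds[i], start_length = 6 - amps[i],
      hold_duration = hold, dt = dt)))
  trace_family(sims, labels = paste0("a", amps))
}

# zero-noise spec (synthetic recordings identical to the clean simulation)
zero_noise <- function(seed = 11L) noise_spec(0, 2, 0, 0.3, 0, seed = seed)

# conditions of the parameter-recovery benchmark: reduced battery (ramps +
# saccades), 2 ms sampling, 12 s holds so the relaxation windows of the
# slow processes are informative
recovery_battery_options <- function() {
  battery_options(
    ramp_speeds = c(1, 10, 80, 160), ramp_range = 8,
    saccade_amps = c(1, 2, 3), saccade_speeds = c(60, 100, 130),
    saccade_starts = 0, dt = 0.002, hold = 12,
    include = c("ramps", "saccades"))
}
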
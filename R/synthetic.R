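# Synthetic "recordings": ground-truth model force plus heartbeat-like and
# respiration-like periodic artifacts plus white measurement noise. The in
# vivo preparation the models describe suffers from both artifacts (they
# are removed post hoc before analysis); here only their existence is
# emulated, so that end-to-end tests exercise realistic-looking inputs
# without any measured data.

#' Noise specification for synthetic recordings
#'
#' Additive, state-independent noise: two sinusoidal artifacts (heartbeat-
#' and respiration-like, with phases drawn from the seeded generator) plus
#' Gaussian white noise. Defaults are plausible for an anesthetized
#' macaque preparation with small residual instrumentation noise; no
#' quantitative noise levels are published, so all are configurable.
#'
#' @param heartbeat_amp,heartbeat_freq heartbeat artifact amplitude (gf)
#'   and frequency (Hz).
#' @param resp_amp,resp_freq respiration artifact amplitude (gf) and
#'   frequency (Hz).
#' @param white_sd white-noise standard deviation, gf.
#' @param seed integer seed; identical seed gives an identical realization.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(heartbeat_amp = 0.1, heartbeat_freq = 2,
                       resp_amp = 0.2, resp_freq = 0.3,
                       white_sd = 0.02, seed = 1L) {
  if (heartbeat_amp < 0 || resp_amp < 0 || white_sd < 0)
    stop("noise amplitudes must be >= 0")
  if (heartbeat_freq <= 0 || resp_freq <= 0)
    stop("noise frequencies must be > 0")
  structure(list(heartbeat_amp = heartbeat_amp, heartbeat_freq = heartbeat_freq,
                 resp_amp = resp_amp, resp_freq = resp_freq,
                 white_sd = white_sd, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Generate a synthetic noisy recording
#'
#' Simulates `model` along `protocol` and adds the noise components of
#' `noise`. The same seed always yields the same realization; with all
#' noise amplitudes zero the recording equals the simulation exactly.
#'
#' @param model an `eom_model`.
#' @param protocol an `eom_protocol`.
#' @param noise a [noise_spec()].
#' @param ... passed to [simulate.eom_model()].
#' @return An object of class `eom_recording`: the protocol, the clean
#'   simulation (`clean`), the noisy force trace (`force`, gf), and the
#'   generating model and noise spec (ground truth travels with the data).
#' @export
generate_recording <- function(model, protocol, noise = noise_spec(), ...) {
  stopifnot(inherits(model, "eom_model"), inherits(protocol, "eom_protocol"),
            inherits(noise, "noise_spec"))
  clean <- simulate(model, protocol = protocol, ...)
  n <- length(clean$t)
  noisy <- with_local_seed(noise$seed, {
    ph <- runif(2, 0, 2 * pi)
    clean$F_total +
      noise$heartbeat_amp * sin(2 * pi * noise$heartbeat_freq * clean$t + ph[1]) +
      noise$resp_amp * sin(2 * pi * noise$resp_freq * clean$t + ph[2]) +
      (if (noise$white_sd > 0) rnorm(n, 0, noise$white_sd) else numeric(n))
  })
  structure(list(protocol = protocol, t = clean$t, L = clean$L,
                 force = noisy, clean = clean,
                 truth = model, noise = noise),
            class = "eom_recording")
}

#' @export
print.eom_recording <- function(x, ...) {
  cat(sprintf("Synthetic recording: %d samples, force %.4g..%.4g gf (%s)\n",
              length(x$t), min(x$force), max(x$force), x$clean$model_kind))
  invisible(x)
}

#' Battery options
#'
#' Composition of the standard protocol battery: constant-speed ramps over
#' the working range, saccade-like elongations paired amplitude/peak-speed
#' along a fixed main-sequence-like table from several start lengths, and
#' double steps / double saccades at the standard inter-stimulus intervals
#' (with the attenuation reset marked at the 45 s ISI, emulating the reset
#' applied there).
#'
#' @param ramp_speeds ramp speeds, mm/s.
#' @param ramp_range elongation covered by each ramp, mm.
#' @param saccade_amps,saccade_speeds paired amplitude (mm) / peak speed
#'   (mm/s) table.
#' @param saccade_starts start elongations for each saccadic amplitude, mm.
#' @param isis inter-stimulus intervals for the double elongations, s.
#' @param reset_isi ISIs at or above this get a reset mark, s.
#' @param dt sample interval, s.
#' @param hold post-elongation hold, s.
#' @param include which protocol groups to generate.
#' @export
battery_options <- function(ramp_speeds = c(0.1, 1, 10, 80, 160),
                            ramp_range = 8,
                            saccade_amps = c(1, 2, 3, 4),
                            saccade_speeds = c(60, 100, 130, 160),
                            saccade_starts = c(0, 2),
                            isis = c(0.01, 0.1, 1, 45),
                            reset_isi = 45,
                            dt = 0.001, hold = 3,
                            include = c("ramps", "saccades", "double_steps",
                                        "double_saccades")) {
  stopifnot(length(saccade_amps) == length(saccade_speeds))
  list(ramp_speeds = ramp_speeds, ramp_range = ramp_range,
       saccade_amps = saccade_amps, saccade_speeds = saccade_speeds,
       saccade_starts = saccade_starts, isis = isis, reset_isi = reset_isi,
       dt = dt, hold = hold, include = include)
}

#' Generate a synthetic battery of recordings
#'
#' Assembles the full protocol battery described by `options` and generates
#' one synthetic recording per protocol, all from the same ground-truth
#' model. Every generated protocol is length/velocity consistent by
#' construction.
#'
#' @param model ground-truth `eom_model`.
#' @param noise a [noise_spec()]; each item gets a distinct sub-seed derived
#'   from it.
#' @param options a [battery_options()] list.
#' @return An object of class `eom_battery`: a list of `eom_recording`s
#'   with a manifest of names and kinds; the generating model and noise
#'   spec are stored alongside.
#' @export
generate_battery <- function(model, noise = noise_spec(),
                             options = battery_options()) {
  o <- options
  protos <- list(); kinds <- character(0)
  if ("ramps" %in% o$include) {
    for (sp in o$ramp_speeds) {
      protos[[sprintf("ramp_%g", sp)]] <-
        make_ramp(sp, o$ramp_range, 0, hold_duration = o$hold, dt = o$dt)
      kinds <- c(kinds, "ramp")
    }
  }
  if ("saccades" %in% o$include) {
    for (i in seq_along(o$saccade_amps)) {
      for (s0 in o$saccade_starts) {
        amp <- o$saccade_amps[i]
        protos[[sprintf("saccade_%gmm_from_%gmm", amp, s0)]] <-
          make_saccadic(amp, o$saccade_speeds[i], start_length = s0,
                        hold_duration = o$hold, dt = o$dt)
        kinds <- c(kinds, "saccade")
      }
    }
  }
  if ("double_steps" %in% o$include) {
    for (isi in o$isis) {
      s <- make_step(0.5, rise_time = 0.005, hold_duration = min(o$hold, 1),
                     start_length = 0, dt = o$dt)
      s2 <- make_step(0.5, rise_time = 0.005, hold_duration = o$hold,
                      start_length = 0, dt = o$dt)
      protos[[sprintf("double_step_isi_%g", isi)]] <-
        concat_protocols(list(s, s2), isi = isi,
                         reset_before_second = isi >= o$reset_isi)
      kinds <- c(kinds, "double_step")
    }
  }
  if ("double_saccades" %in% o$include) {
    for (isi in o$isis) {
      s <- make_saccadic(1.6, 100, start_length = 0,
                         hold_duration = min(o$hold, 1), dt = o$dt)
      s2 <- make_saccadic(1.6, 100, start_length = 0,
                          hold_duration = o$hold, dt = o$dt)
      protos[[sprintf("double_saccade_isi_%g", isi)]] <-
        concat_protocols(list(s, s2), isi = isi,
                         reset_before_second = isi >= o$reset_isi)
      kinds <- c(kinds, "double_saccade")
    }
  }
  items <- vector("list", length(protos))
  names(items) <- names(protos)
  for (i in seq_along(protos)) {
    ns <- noise
    ns$seed <- noise$seed + i  # distinct realization per item
    items[[i]] <- generate_recording(model, protos[[i]], ns)
  }
  structure(list(items = items,
                 manifest = data.frame(name = names(protos), kind = kinds,
                                       stringsAsFactors = FALSE),
                 truth = model, noise = noise, options = o),
            class = "eom_battery")
}

#' @export
print.eom_battery <- function(x, ...) {
  cat(sprintf("Synthetic battery: %d recordings (%s ground truth)\n",
              length(x$items), x$truth$kind))
  print(table(x$manifest$kind))
  invisible(x)
}
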
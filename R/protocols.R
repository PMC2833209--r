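# Elongation protocols: sampled length/velocity trajectories with phase
# annotations. Coordinates: L is elongation in mm relative to the shortest
# (slack reference) length, so L = 0 at the bottom of the ~8 mm working
# range; v = dL/dt in mm/s. Only lengthening is represented (v >= 0).

cumtrapz <- function(t, y) {
  n <- length(y)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(t)))
}

trapz <- function(t, y) {
  n <- length(y)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(t))
}

new_protocol <- function(t, L, v, phases, resets = numeric(0), dt = NULL,
                         rel_tol = 0.002) {
  stopifnot(length(t) == length(L), length(t) == length(v))
  if (is.null(dt)) dt <- (t[length(t)] - t[1]) / (length(t) - 1)
  dts <- diff(t)
  if (any(dts <= 0) || max(abs(dts - dt)) > 1e-12 + 1e-9 * dt)
    stop("time grid must be strictly increasing with constant dt")
  if (any(v < -1e-12))
    stop("negative elongation velocity: only lengthening is modeled")
  v[v < 0] <- 0
  # length/velocity consistency (guards against the kind of artifact that a
  # small mismatch between integrated speed and measured length produces)
  resid <- max(abs(cumtrapz(t, v) - (L - L[1])))
  denom <- max(max(L) - min(L), 1e-9)
  if (resid / denom > rel_tol)
    stop(sprintf(
      "length/velocity inconsistency: max |integral(v) - dL| is %.3g%% of range (tolerance %.3g%%)",
      100 * resid / denom, 100 * rel_tol))
  if (nrow(phases) > 0 &&
      (min(phases$start) < t[1] - 1e-9 || max(phases$end) > t[length(t)] + 1e-9))
    stop("phase marks must lie within the protocol time span")
  structure(
    list(t = t, L = L, v = v, dt = dt,
         phases = phases, resets = resets, start_length = L[1]),
    class = "eom_protocol")
}

phase_df <- function(start = numeric(0), end = numeric(0), label = character(0)) {
  data.frame(start = start, end = end, label = label,
             stringsAsFactors = FALSE)
}

grid_n <- function(duration, dt) max(0L, as.integer(round(duration / dt)))

# rescale v so its trapezoidal integral equals the commanded amplitude
# exactly, then define L as the cumulative trapezoidal integral of v; the
# generated protocol is then self-consistent to machine precision.
finish_protocol <- function(v, dt, amplitude, start_length, phases,
                            resets = numeric(0)) {
  t <- (seq_along(v) - 1) * dt
  if (amplitude > 0) {
    I <- trapz(t, v)
    if (I <= 0) stop("degenerate velocity profile")
    v <- v * (amplitude / I)
  } else {
    v <- rep(0, length(v))
  }
  L <- start_length + cumtrapz(t, v)
  new_protocol(t, L, v, phases, resets, dt = dt)
}

#' Quick-step elongation protocol
#'
#' A smooth monotone rise of `amplitude` mm over `rise_time` seconds
#' (half-sinusoid velocity profile by default, so velocity is bounded and
#' continuous), followed by a constant-length hold. Used to emulate the
#' quick-step (0.5 mm) elongations from which base-model parameters are
#' classically identified.
#'
#' @param amplitude elongation amplitude, mm (>= 0).
#' @param rise_time duration of the rise, s.
#' @param hold_duration duration of the post-step hold, s.
#' @param start_length initial elongation, mm.
#' @param dt sample interval, s; must satisfy `dt <= rise_time / 4`.
#' @return An object of class `eom_protocol`.
#' @export
#' @examples
#' p <- make_step(0.5, rise_time = 0.005, hold_duration = 1)
#' max(p$L) - min(p$L) # 0.5
make_step <- function(amplitude, rise_time = 0.005, hold_duration = 1,
                      start_length = 0, dt = 0.001) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (rise_time <= 0 || dt <= 0) stop("rise_time and dt must be positive")
  if (dt > rise_time / 4) stop("dt must not exceed rise_time / 4")
  n_rise <- max(4L, grid_n(rise_time, dt))
  Tr <- n_rise * dt
  n_hold <- grid_n(hold_duration, dt)
  t_rise <- (0:n_rise) * dt
  v <- c(amplitude * pi / (2 * Tr) * sin(pi * t_rise / Tr), rep(0, n_hold))
  phases <- if (amplitude > 0) {
    phase_df(c(0, Tr), c(Tr, (n_rise + n_hold) * dt), c("elongation", "hold"))
  } else {
    phase_df(0, (n_rise + n_hold) * dt, "hold")
  }
  finish_protocol(v, dt, amplitude, start_length, phases)
}

#' Saccade-like elongation protocol
#'
#' Half-sinusoid velocity profile `v(t) = peak_speed * sin(pi t / T)` on
#' `[0, T]` with `T = pi * amplitude / (2 * peak_speed)`, so that the
#' integral of the velocity equals the amplitude; the length is then held
#' constant. This mimics the elongation imposed on the antagonist muscle
#' during a saccadic eye movement.
#'
#' @param amplitude elongation amplitude, mm (> 0).
#' @param peak_speed peak elongation speed, mm/s (> 0).
#' @param start_length initial elongation, mm.
#' @param hold_duration duration of the post-elongation hold, s.
#' @param dt sample interval, s.
#' @return An object of class `eom_protocol`.
#' @export
#' @examples
#' p <- make_saccadic(4, 160, hold_duration = 2)
make_saccadic <- function(amplitude, peak_speed, start_length = 0,
                          hold_duration = 1, dt = 0.001) {
  if (amplitude <= 0 || peak_speed <= 0)
    stop("amplitude and peak_speed must be positive")
  if (dt <= 0) stop("dt must be positive")
  Tn <- pi * amplitude / (2 * peak_speed)
  if (Tn < 4 * dt)
    stop(sprintf(
      "elongation duration %.4g s is under-resolved at dt = %.4g s (need T >= 4 dt)",
      Tn, dt))
  n_el <- grid_n(Tn, dt)
  Tg <- n_el * dt
  n_hold <- grid_n(hold_duration, dt)
  t_el <- (0:n_el) * dt
  v <- c(peak_speed * sin(pi * t_el / Tg), rep(0, n_hold))
  phases <- phase_df(c(0, Tg), c(Tg, (n_el + n_hold) * dt),
                     c("elongation", "hold"))
  finish_protocol(v, dt, amplitude, start_length, phases)
}

#' Constant-speed ramp protocol
#'
#' Constant elongation speed until `total_range` is covered, then a hold.
#' The elongation phase lasts `total_range / speed` seconds; the velocity
#' sample at the stop transition is halved so that the trapezoidal integral
#' of the sampled velocity is exact.
#'
#' @param speed elongation speed, mm/s (> 0).
#' @param total_range total elongation covered, mm (>= 0).
#' @param start_length initial elongation, mm.
#' @param hold_duration duration of the post-ramp hold, s.
#' @param dt sample interval, s.
#' @return An object of class `eom_protocol`.
#' @export
#' @examples
#' p <- make_ramp(160, 8, hold_duration = 1)
#' subset(p$phases, label == "elongation") # 50 ms elongation phase
make_ramp <- function(speed, total_range, start_length = 0,
                      hold_duration = 1, dt = 0.001) {
  if (speed <= 0) stop("speed must be positive")
  if (total_range < 0) stop("total_range must be >= 0")
  if (dt <= 0) stop("dt must be positive")
  n_hold <- grid_n(hold_duration, dt)
  if (total_range == 0) {
    v <- rep(0, n_hold + 1)
    return(finish_protocol(v, dt, 0, start_length,
                           phase_df(0, n_hold * dt, "hold")))
  }
  n_el <- max(1L, grid_n(total_range / speed, dt))
  # v = speed at samples 0..n_el-1, speed/2 at the stop sample, 0 after:
  # the trapezoidal integral is then exactly speed * n_el * dt
  v <- c(rep(speed, n_el), speed / 2, rep(0, n_hold))
  phases <- phase_df(c(0, n_el * dt), c(n_el * dt, (n_el + n_hold) * dt),
                     c("elongation", "hold"))
  finish_protocol(v, dt, total_range, start_length, phases)
}

#' Concatenate elongation protocols with an inter-stimulus interval
#'
#' Joins protocols with an `isi`-long constant-length hold between them.
#' Each subsequent protocol is re-based so that length is continuous at the
#' junction. If `reset_before_second` is `TRUE`, a reset mark is placed at
#' the onset of each appended protocol: during an ANLV simulation the
#' structural parameter is restored to its initial value there (emulating
#' the reset applied before the second elongation of a 45 s ISI sequence).
#'
#' @param protocols a list of `eom_protocol` objects sharing the same `dt`.
#' @param isi inter-stimulus interval, s (>= 0).
#' @param reset_before_second place an attenuation reset mark at the onset
#'   of each appended protocol.
#' @return An object of class `eom_protocol`.
#' @export
concat_protocols <- function(protocols, isi = 0, reset_before_second = FALSE) {
  stopifnot(length(protocols) >= 1, isi >= 0)
  lapply(protocols, function(p) stopifnot(inherits(p, "eom_protocol")))
  dt <- protocols[[1]]$dt
  for (p in protocols)
    if (abs(p$dt - dt) > 1e-12)
      stop("all protocols must share the same sample interval dt")
  out <- protocols[[1]]
  t <- out$t; L <- out$L; v <- out$v
  phases <- out$phases; resets <- out$resets
  for (p in protocols[-1]) {
    t_end <- t[length(t)]
    n_isi <- grid_n(isi, dt)
    if (n_isi > 0) {
      t <- c(t, t_end + (1:n_isi) * dt)
      L <- c(L, rep(L[length(L)], n_isi))
      v <- c(v, rep(0, n_isi))
      phases <- rbind(phases, phase_df(t_end, t_end + n_isi * dt, "isi"))
    }
    onset <- t[length(t)]
    # drop the duplicated junction sample (p starts at rest, v = 0)
    t <- c(t, onset + p$t[-1])
    L <- c(L, p$L[-1] - p$L[1] + L[length(L)])
    v <- c(v, p$v[-1])
    ph <- p$phases; ph$start <- ph$start + onset; ph$end <- ph$end + onset
    phases <- rbind(phases, ph)
    resets <- c(resets, p$resets + onset)
    if (reset_before_second) resets <- c(resets, onset)
  }
  t <- (seq_along(t) - 1) * dt   # regularize accumulated rounding
  new_protocol(t, L, v, phases, sort(unique(resets)), dt = dt)
}

#' Check length/velocity consistency of a protocol
#'
#' Compares the trapezoidal integral of the elongation speed with the change
#' in length. Small mismatches between the two (of the kind present when the
#' speed and length channels are recorded independently) are known to
#' produce spurious relaxation cross-over in base-model simulations, so the
#' simulator refuses inconsistent protocols.
#'
#' @param p an `eom_protocol`.
#' @param rel_tol tolerated discrepancy as a fraction of the elongation range.
#' @return A list with the maximum relative `discrepancy`, a logical `pass`,
#'   and `rescaled`, a copy of the protocol whose velocity has been scaled so
#'   that its integral matches the length change exactly.
#' @export
validate_consistency <- function(p, rel_tol = 0.002) {
  stopifnot(inherits(p, "eom_protocol"))
  dL <- p$L - p$L[1]
  I <- cumtrapz(p$t, p$v)
  denom <- max(max(p$L) - min(p$L), 1e-9)
  discrepancy <- max(abs(I - dL)) / denom
  total <- I[length(I)]
  v2 <- if (total > 0) p$v * (dL[length(dL)] / total) else p$v
  L2 <- p$L[1] + cumtrapz(p$t, v2)
  rescaled <- structure(
    list(t = p$t, L = L2, v = v2, dt = p$dt, phases = p$phases,
         resets = p$resets, start_length = p$L[1]),
    class = "eom_protocol")
  list(discrepancy = discrepancy, pass = discrepancy <= rel_tol,
       rescaled = rescaled)
}

#' @export
print.eom_protocol <- function(x, ...) {
  dur <- x$t[length(x$t)] - x$t[1]
  cat(sprintf(
    "Elongation protocol: %d samples, dt = %g s, duration %.4g s\n",
    length(x$t), x$dt, dur))
  cat(sprintf("  elongation %.4g -> %.4g mm, peak speed %.4g mm/s\n",
              x$L[1], x$L[length(x$L)], max(x$v)))
  if (nrow(x$phases)) {
    cat("  phases:\n")
    for (i in seq_len(nrow(x$phases)))
      cat(sprintf("    %-10s [%.4g, %.4g] s\n", x$phases$label[i],
                  x$phases$start[i], x$phases$end[i]))
  }
  if (length(x$resets))
    cat("  attenuation resets at:", paste(signif(x$resets, 6), collapse = ", "),
        "s\n")
  invisible(x)
}

#' @export
as.data.frame.eom_protocol <- function(x, ...) {
  data.frame(time_s = x$t, length_mm = x$L, velocity_mm_s = x$v)
}

#' @export
plot.eom_protocol <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$t, x$L, type = "l", xlab = "time (s)", ylab = "elongation (mm)", ...)
  plot(x$t, x$v, type = "l", xlab = "time (s)", ylab = "speed (mm/s)", ...)
  invisible(x)
}
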
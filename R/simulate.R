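# State-space integration of a model along an elongation protocol.
#
# Seven first-order states (one per relaxation process) are advanced with
# the exact exponential update for a drive varying linearly between its
# sampled values (exact for constant-drive segments and holds, second
# order for smooth drives); the structural parameter, when present, is
# advanced with its own exact exponential update with speed and total
# force frozen over the step. This is O(N) and requires no stored history.
# The inner loop is compiled (src/sim_core.cpp).

#' Simulate a passive-muscle model along an elongation protocol
#'
#' @param object a `qlv_model`, `aqlv_model` or `anlv_model`.
#' @param nsim,seed unused (the models are deterministic); present for
#'   compatibility with the [stats::simulate()] generic.
#' @param protocol an `eom_protocol`.
#' @param dt integration step, s. Defaults to the protocol's sample
#'   interval; may also be an integer refinement of it (protocol length and
#'   speed are then linearly interpolated onto the finer grid).
#' @param initial_states optional list with elements `x` (seven process
#'   forces, gf) and `lam` (structural parameter) used to chain
#'   simulations; defaults to zero states (muscle equilibrated at the start
#'   length) and `lambda0`.
#' @param check_consistency refuse protocols whose integrated speed does
#'   not match their length change to within 0.2% of the range (such
#'   inconsistencies are known to create spurious relaxation cross-over).
#' @param ... unused.
#' @return An object of class `eom_sim`: time grid `t` (s), `L` (mm), `v`
#'   (mm/s), total force `F_total` (gf) and its decomposition `F_elastic`,
#'   `F_processes` (N x 7 pre-gain process forces), `beta` (N x 7 gain
#'   traces), `F_viscous`, and the structural-parameter trace `lam`. For
#'   base models `beta` is identically 1. At every sample
#'   `F_total = F_elastic + rowSums(beta * F_processes) + F_viscous`.
#' @export
simulate.eom_model <- function(object, nsim = 1, seed = NULL, protocol,
                               dt = NULL, initial_states = NULL,
                               check_consistency = TRUE, ...) {
  stopifnot(inherits(protocol, "eom_protocol"))
  if (check_consistency) {
    vc <- validate_consistency(protocol)
    if (!vc$pass)
      stop(sprintf(
        "inconsistent protocol: integral of speed deviates from length change by %.3g%% of range; rescale the velocity first",
        100 * vc$discrepancy))
  }
  p_dt <- protocol$dt
  if (is.null(dt)) dt <- p_dt
  refine <- p_dt / dt
  if (abs(refine - round(refine)) > 1e-9 || refine < 1)
    stop("dt must equal the protocol dt or divide it an integer number of times")
  refine <- as.integer(round(refine))
  if (refine > 1L) {
    t <- seq(protocol$t[1], protocol$t[length(protocol$t)], by = dt)
    L <- approx(protocol$t, protocol$L, xout = t)$y
    v <- approx(protocol$t, protocol$v, xout = t)$y
  } else {
    t <- protocol$t; L <- protocol$L; v <- protocol$v
  }

  base <- if (inherits(object, "anlv_model")) object$base else object
  attenuate <- inherits(object, "anlv_model")
  atp <- if (attenuate) object$attenuation else NULL

  drv <- drive_matrix(base, L, v)
  F_elastic <- lt_force(base$lt, L)
  F_viscous <- if (isTRUE(base$no_viscosity)) rep(0, length(L)) else
    viscous_force(base$viscosity, L, v)

  x0 <- rep(0, 7); lam0 <- if (attenuate) atp$lambda0 else 1
  if (!is.null(initial_states)) {
    if (!is.null(initial_states$x)) x0 <- as.numeric(initial_states$x)
    if (!is.null(initial_states$lam)) lam0 <- initial_states$lam
  }
  reset_idx <- if (length(protocol$resets))
    as.integer(round((protocol$resets - t[1]) / dt)) + 1L else integer(0)

  core <- sim_core(drv, base$tau, F_elastic + F_viscous, v, dt,
                   attenuate,
                   if (attenuate) atp$gamma else rep(0, 7),
                   if (attenuate) atp$k_d else 0,
                   if (attenuate) atp$n else 1,
                   if (attenuate) atp$lambda0 else 1,
                   if (attenuate) atp$k_f else 0,
                   reset_idx, x0, lam0)

  lam_eff <- pmin(core$lam, 1)
  beta <- if (attenuate) {
    1 - outer(1 - lam_eff, atp$gamma)
  } else {
    matrix(1, nrow = length(t), ncol = 7)
  }
  structure(
    list(t = t, L = L, v = v, dt = dt,
         F_total = core$F_total, F_elastic = F_elastic,
         F_processes = core$x, beta = beta, F_viscous = F_viscous,
         lam = core$lam,
         model_kind = object$kind, protocol = protocol),
    class = "eom_sim")
}

#' Equilibrium (steady-state) force at a fixed length
#'
#' The force exerted by the muscle when a length is maintained for a very
#' long time: all relaxation processes have decayed and the viscous force
#' vanishes, leaving the static length-tension force.
#'
#' @param model an `eom_model`.
#' @param L elongation, mm (vectorized).
#' @export
steady_state_force <- function(model, L) {
  stopifnot(inherits(model, "eom_model"))
  lt_force(model$lt, L)
}

#' @export
print.eom_sim <- function(x, ...) {
  cat(sprintf("%s simulation: %d samples, dt = %g s\n",
              x$model_kind, length(x$t), x$dt))
  cat(sprintf("  force %.4g -> %.4g gf (peak %.4g gf)\n",
              x$F_total[1], x$F_total[length(x$F_total)], max(x$F_total)))
  if (!is.null(x$lam))
    cat(sprintf("  lambda: %.4g -> %.4g\n", x$lam[1], x$lam[length(x$lam)]))
  invisible(x)
}

#' @export
as.data.frame.eom_sim <- function(x, ...) {
  data.frame(
    time_s = x$t, length_mm = x$L, velocity_mm_s = x$v,
    force_gf = x$F_total, f_elastic_gf = x$F_elastic,
    f_visco_gf = rowSums(x$beta * x$F_processes),
    f_viscous_gf = x$F_viscous, lambda = x$lam)
}

#' @export
plot.eom_sim <- function(x, what = c("force", "decomposition", "lambda"), ...) {
  what <- match.arg(what)
  if (what == "force") {
    plot(x$t, x$F_total, type = "l", xlab = "time (s)", ylab = "force (gf)", ...)
  } else if (what == "decomposition") {
    visco <- rowSums(x$beta * x$F_processes)
    plot(x$t, x$F_total, type = "l", xlab = "time (s)", ylab = "force (gf)",
         ylim = range(0, x$F_total), ...)
    graphics::lines(x$t, x$F_elastic, lty = 2)
    graphics::lines(x$t, visco, lty = 3)
    graphics::lines(x$t, x$F_viscous, lty = 4)
    graphics::legend("topright", c("total", "elastic", "viscoelastic", "viscous"),
                     lty = 1:4, bty = "n")
  } else {
    plot(x$t, x$lam, type = "l", xlab = "time (s)", ylab = "lambda", ...)
    graphics::abline(h = 1, lty = 2)
  }
  invisible(x)
}

# end time of the last elongation phase of the protocol behind a simulation
elongation_end <- function(sim) {
  ph <- sim$protocol$phases
  el <- ph[ph$label == "elongation", , drop = FALSE]
  if (nrow(el) == 0) stop("protocol has no elongation phase")
  max(el$end)
}
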
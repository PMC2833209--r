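# The ANLV attenuation extension.
#
# A thixotropy-style structural parameter lambda (1 = fully built-up
# microstructure, 0 = fully broken down) decays under imposed elongation:
#
#   d(lambda)/dt = -k_d * v^n / (1 + k_f * F) * lambda
#
# No rebuilding is modeled (at rest lambda is constant); the classical
# build-up term is left as a documented hook only. lambda is initialized at
# lambda0 >= 1 and clipped at 1 where it enters the gains, so that small
# elongations (~0.5 mm, the quick-step regime the base models were
# identified on) produce no attenuation. Each viscoelastic process i gets
# its own output gain
#
#   beta_i = 1 - gamma_i * (1 - min(lambda, 1)),  gamma_i in [0, 1],
#
# so gamma_i = 1 means the process is attenuated down to lambda (lambda is
# the maximum attenuation, i.e. the lowest gain, across processes) and
# gamma_i = 0 leaves the process untouched. The gains scale each process's
# force prediction (stiffness and viscosity together), so the process time
# constants are unchanged and hold-phase decay remains exactly exponential.

#' Attenuation parameters of the ANLV model
#'
#' @param k_d breakdown rate coefficient, (mm/s)^(-n)/s scaling (>= 0).
#' @param n breakdown speed exponent, dimensionless (> 0).
#' @param lambda0 initial structural parameter, dimensionless (>= 1).
#' @param k_f force-modulation coefficient, 1/gf (>= 0): the breakdown rate
#'   is divided by `1 + k_f * F`, so attenuation builds up more slowly when
#'   the total muscle force is high.
#' @param gamma seven per-process scaling factors in `[0, 1]`.
#' @param force_modulation optional function `f(F)` returning the factor
#'   that divides the breakdown rate; defaults to `1 + k_f * F`. Supplying
#'   a different law only affects simulation paths that go through the R
#'   reference stepper ([lambda_update()]); the compiled integrator always
#'   uses the default law.
#' @return An object of class `attenuation_params`. Its conventional DOF
#'   count is 10: `k_d`, `n`, `lambda0`, `k_f` plus six for the bounded
#'   `gamma` factors (see [dof()]).
#' @export
attenuation_params <- function(k_d, n, lambda0, k_f = 0,
                               gamma = rep(1, 7), force_modulation = NULL) {
  if (k_d < 0) stop("k_d must be >= 0")
  if (n <= 0) stop("n must be > 0")
  if (lambda0 < 1) stop("lambda0 must be >= 1")
  if (k_f < 0) stop("k_f must be >= 0")
  if (length(gamma) != 7 || any(gamma < 0) || any(gamma > 1))
    stop("gamma must be seven factors in [0, 1]")
  structure(list(k_d = k_d, n = n, lambda0 = lambda0, k_f = k_f,
                 gamma = as.numeric(gamma),
                 force_modulation = force_modulation),
            class = "attenuation_params")
}

#' @export
dof.attenuation_params <- function(x, ...) 10L

#' ANLV model: a base model plus attenuation
#'
#' Wraps a QLV or AQLV base model with [attenuation_params()]. The total
#' force is `lt_force(L) + sum_i beta_i * x_i + eta(L) * v`: neither the
#' asymptotic length-tension force nor the pure viscous force is attenuated.
#'
#' @param base a `qlv_model` or `aqlv_model`.
#' @param attenuation an `attenuation_params` object.
#' @return An object of class `c("anlv_model", "eom_model")`.
#' @export
anlv_model <- function(base, attenuation) {
  stopifnot(inherits(base, "eom_model"), !inherits(base, "anlv_model"),
            inherits(attenuation, "attenuation_params"))
  structure(list(kind = paste0("ANLV/", base$kind), base = base,
                 attenuation = attenuation,
                 lt = base$lt, tau = base$tau, viscosity = base$viscosity),
            class = c("anlv_model", "eom_model"))
}

#' @export
dof.anlv_model <- function(x, ...) dof(x$base) + dof(x$attenuation)

#' @export
print.anlv_model <- function(x, ...) {
  a <- x$attenuation
  cat(sprintf("%s passive-muscle model (%d DOF)\n", x$kind, dof(x)))
  cat(sprintf("  attenuation: k_d=%.4g, n=%.4g, lambda0=%.4g, k_f=%.4g 1/gf\n",
              a$k_d, a$n, a$lambda0, a$k_f))
  cat("  gamma:", paste(signif(a$gamma, 3), collapse = ", "), "\n")
  cat("  base model:\n")
  print(x$base)
  invisible(x)
}

#' Attenuation state
#'
#' Holds the current value of the structural parameter lambda. Created with
#' `lambda = lambda0`; lambda never increases except at an explicit
#' [reset_state()].
#'
#' @param params an `attenuation_params` object.
#' @param lam initial lambda (defaults to `lambda0`).
#' @return An object of class `attenuation_state`.
#' @export
attenuation_state <- function(params, lam = params$lambda0) {
  stopifnot(inherits(params, "attenuation_params"), lam > 0)
  structure(list(lam = lam), class = "attenuation_state")
}

#' One breakdown step of the structural parameter
#'
#' Advances lambda over one step of size `dt` using the exact-in-lambda
#' exponential update `lambda <- lambda * exp(-a * dt)` with instantaneous
#' rate `a = k_d * v^n / (1 + k_f * F)` (`v` and `F` frozen over the step).
#' At rest (`v = 0`) lambda is unchanged: no rebuilding is modeled. This is
#' the scalar R reference for the compiled integrator; a custom
#' `force_modulation` law in `params` is honored here.
#'
#' @param state an `attenuation_state`.
#' @param params an `attenuation_params`.
#' @param v elongation speed over the step, mm/s (>= 0).
#' @param F total muscle force at the start of the step, gf.
#' @param dt step size, s (> 0).
#' @return The updated `attenuation_state`.
#' @export
lambda_update <- function(state, params, v, F, dt) {
  stopifnot(inherits(state, "attenuation_state"),
            inherits(params, "attenuation_params"), dt > 0)
  if (v < 0) stop("v must be >= 0 (only lengthening is modeled)")
  if (v == 0) return(state)
  mod <- if (is.null(params$force_modulation)) {
    1 + params$k_f * max(F, 0)
  } else {
    params$force_modulation(F)
  }
  a <- params$k_d * v^params$n / mod
  state$lam <- state$lam * exp(-a * dt)
  state
}

#' Clipped structural parameter
#'
#' `min(lambda, 1)`: the value actually used for attenuation, so that the
#' initial excess `lambda0 - 1` acts as a breakdown reserve during which no
#' attenuation occurs.
#'
#' @param state an `attenuation_state`.
#' @export
effective_lambda <- function(state) {
  stopifnot(inherits(state, "attenuation_state"))
  min(state$lam, 1)
}

#' Per-process gains
#'
#' `beta_i = 1 - gamma_i * (1 - lam_eff)`. Each gain lies in
#' `[lam_eff, 1]`; `gamma_i = 1` gives `beta_i = lam_eff` (maximum
#' attenuation) and `gamma_i = 0` gives `beta_i = 1` (process untouched).
#'
#' @param params an `attenuation_params`.
#' @param lam_eff clipped structural parameter in `[0, 1]`.
#' @return Numeric vector of seven gains.
#' @export
beta_gains <- function(params, lam_eff) {
  stopifnot(inherits(params, "attenuation_params"))
  if (lam_eff < 0 || lam_eff > 1) stop("lam_eff must be in [0, 1]")
  1 - params$gamma * (1 - lam_eff)
}

#' Reset the structural parameter
#'
#' Restores lambda to its initial value `lambda0` (applied, e.g., before the
#' second elongation of a 45 s ISI sequence).
#'
#' @param state an `attenuation_state`.
#' @param params an `attenuation_params`.
#' @export
reset_state <- function(state, params) {
  stopifnot(inherits(state, "attenuation_state"),
            inherits(params, "attenuation_params"))
  state$lam <- params$lambda0
  state
}
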
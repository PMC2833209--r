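# QLV and AQLV constitutive laws.
#
# Both models share the same structure: a static length-tension force, a
# purely viscoelastic force carried by seven first-order relaxation
# processes, and a pure viscous force (length-dependent viscosity times
# elongation speed). They differ only in how each process is driven:
#   QLV : drive_i = alpha * g_i * lt_slope(L) * v     (8 DOF: g_1..g_7, alpha)
#   AQLV: drive_i = k_i(L) * v, k_i piecewise linear  (4 DOF per process)
# Units package-wide: mm, mm/s, s, gf (see GF_TO_N).

#' Static length-tension relationship
#'
#' Parametric form `F(L) = c0 + c1 * L + c2 * (exp(c3 * L) - 1)`: essentially
#' linear at small elongations, with accelerating stiffness toward the end
#' of the working range. It estimates the force exerted by the muscle when a
#' length is maintained for a very long time (equilibrium force).
#'
#' @param c0 offset force at the slack reference length, gf.
#' @param c1 linear stiffness, gf/mm (>= 0).
#' @param c2 exponential amplitude, gf.
#' @param c3 exponential rate, 1/mm. `c2 * c3` must be >= 0 so that the
#'   curve is non-decreasing over the working range.
#' @return An object of class `length_tension`.
#' @export
length_tension <- function(c0 = 0, c1 = 1, c2 = 0, c3 = 0) {
  if (c1 < 0) stop("c1 must be >= 0")
  if (c2 * c3 < 0) stop("c2 * c3 must be >= 0 (force non-decreasing)")
  structure(list(c0 = c0, c1 = c1, c2 = c2, c3 = c3),
            class = "length_tension")
}

#' @describeIn length_tension evaluate the static force at elongation `L` (mm).
#' @param lt a `length_tension` object.
#' @param L elongation, mm (vectorized).
#' @export
lt_force <- function(lt, L) {
  stopifnot(inherits(lt, "length_tension"))
  lt$c0 + lt$c1 * L + lt$c2 * (exp(lt$c3 * L) - 1)
}

#' @describeIn length_tension analytic slope `c1 + c2 * c3 * exp(c3 * L)`,
#'   gf/mm.
#' @export
lt_slope <- function(lt, L) {
  stopifnot(inherits(lt, "length_tension"))
  lt$c1 + lt$c2 * lt$c3 * exp(lt$c3 * L)
}

#' Length-dependent viscosity law
#'
#' Quadratic polynomial `eta(L) = w0 + w1 * L + w2 * L^2` (gf s / mm),
#' clipped at zero; the pure viscous force is `eta(L) * v`.
#'
#' @param w0,w1,w2 polynomial coefficients.
#' @return An object of class `viscosity_law`.
#' @export
viscosity_law <- function(w0 = 0, w1 = 0, w2 = 0) {
  structure(list(w0 = w0, w1 = w1, w2 = w2), class = "viscosity_law")
}

eta_of_L <- function(law, L) {
  pmax(law$w0 + law$w1 * L + law$w2 * L^2, 0)
}

#' @describeIn viscosity_law pure viscous force `eta(L) * v`, gf.
#' @param law a `viscosity_law`.
#' @param L elongation, mm.
#' @param v elongation speed, mm/s.
#' @export
viscous_force <- function(law, L, v) {
  stopifnot(inherits(law, "viscosity_law"))
  eta_of_L(law, L) * v
}

#' Quasi-linear viscoelastic (QLV) muscle model
#'
#' Total force = static length-tension force + sum of seven relaxation
#' processes + pure viscous force. Process `i` is driven by
#' `alpha * g_i * lt_slope(L) * v`, so the purely viscoelastic response is
#' proportional to the slope of the static length-tension curve. The seven
#' time constants are fixed (not fitted); the free parameters are the 4
#' length-tension coefficients, the 7 moduli `g_i` plus `alpha`, and the 3
#' viscosity coefficients: 15 DOF in total.
#'
#' @param lt a `length_tension` object.
#' @param g seven non-negative dimensionless moduli.
#' @param alpha scale of the instantaneous elastic response, dimensionless.
#' @param tau seven strictly increasing time constants, s.
#' @param viscosity a `viscosity_law`.
#' @return An object of class `c("qlv_model", "eom_model")`.
#' @export
qlv_model <- function(lt, g, alpha = 1, tau = DEFAULT_TAU,
                      viscosity = viscosity_law()) {
  no_visc <- is.null(viscosity)
  if (no_visc) viscosity <- viscosity_law()
  stopifnot(inherits(lt, "length_tension"), inherits(viscosity, "viscosity_law"))
  if (length(g) != 7) stop("g must have exactly 7 moduli")
  if (any(g < 0)) stop("moduli g must be >= 0")
  check_tau(tau)
  structure(list(kind = "QLV", lt = lt, g = as.numeric(g),
                 alpha = alpha, tau = as.numeric(tau), viscosity = viscosity,
                 no_viscosity = no_visc),
            class = c("qlv_model", "eom_model"))
}

#' Adaptive QLV (AQLV) muscle model
#'
#' Same structure as [qlv_model()], except that each relaxation process has
#' its own length-dependent stiffness `k_i(L)`, represented as a
#' piecewise-linear function through 4 knots (constant extrapolation beyond
#' them). This decouples the post-elongation decay from a single elastic
#' law. DOF: 4 (length-tension) + 7 x 4 (stiffness knots) + 3 (viscosity)
#' = 35.
#'
#' @param lt a `length_tension` object.
#' @param knot_lengths increasing vector of 4 knot elongations, mm, shared
#'   by all processes, or a 7 x 4 matrix (one row per process).
#' @param knot_stiffness 7 x 4 matrix of non-negative stiffness values
#'   `k_i` at the knots, gf/mm.
#' @param tau seven strictly increasing time constants, s.
#' @param viscosity a `viscosity_law`.
#' @return An object of class `c("aqlv_model", "eom_model")`.
#' @export
aqlv_model <- function(lt, knot_lengths, knot_stiffness, tau = DEFAULT_TAU,
                       viscosity = viscosity_law()) {
  no_visc <- is.null(viscosity)
  if (no_visc) viscosity <- viscosity_law()
  stopifnot(inherits(lt, "length_tension"), inherits(viscosity, "viscosity_law"))
  if (is.null(dim(knot_lengths)))
    knot_lengths <- matrix(knot_lengths, nrow = 7, ncol = 4, byrow = TRUE)
  knot_stiffness <- as.matrix(knot_stiffness)
  if (!all(dim(knot_lengths) == c(7, 4)) || !all(dim(knot_stiffness) == c(7, 4)))
    stop("need 4 stiffness knots for each of the 7 processes")
  if (any(apply(knot_lengths, 1, function(z) any(diff(z) <= 0))))
    stop("knot lengths must be strictly increasing")
  if (any(knot_stiffness < 0)) stop("knot stiffness must be >= 0")
  check_tau(tau)
  structure(list(kind = "AQLV", lt = lt, knot_lengths = knot_lengths,
                 knot_stiffness = knot_stiffness, tau = as.numeric(tau),
                 viscosity = viscosity, no_viscosity = no_visc),
            class = c("aqlv_model", "eom_model"))
}

check_tau <- function(tau) {
  if (length(tau) != 7) stop("tau must have exactly 7 time constants")
  if (any(tau <= 0) || any(diff(tau) <= 0))
    stop("tau must be positive and strictly increasing")
  invisible(tau)
}

#' Per-process drive
#'
#' The input feeding process `i`'s first-order relaxation state:
#' `alpha * g_i * lt_slope(L) * v` for the QLV model, `k_i(L) * v` for the
#' AQLV model. Returned in gf/s.
#'
#' @param model a `qlv_model` or `aqlv_model` (for an `anlv_model` the base
#'   model's drive is used: attenuation acts on the output, not the drive).
#' @param i process index in 1..7.
#' @param L elongation, mm (vectorized).
#' @param v elongation speed, mm/s (vectorized).
#' @export
process_drive <- function(model, i, L, v) {
  if (inherits(model, "anlv_model")) model <- model$base
  stopifnot(inherits(model, "eom_model"))
  if (length(i) != 1 || i < 1 || i > 7) stop("process index i must be in 1..7")
  stiffness_at(model, i, L) * v
}

stiffness_at <- function(model, i, L) {
  if (model$kind == "QLV") {
    model$alpha * model$g[i] * lt_slope(model$lt, L)
  } else {
    approx(model$knot_lengths[i, ], model$knot_stiffness[i, ],
           xout = L, rule = 2)$y
  }
}

# N x 7 matrix of process drives along a trajectory
drive_matrix <- function(model, L, v) {
  vapply(1:7, function(i) stiffness_at(model, i, L) * v,
         numeric(length(L)))
}

#' Degrees of freedom exposed to the fitter
#'
#' Counts the free parameters of a model object: 15 for QLV (4 length-
#' tension + 8 spectrum + 3 viscosity), 35 for AQLV (4 + 28 + 3), and for
#' an ANLV model the base-model count plus 10 for the attenuation extension
#' (breakdown rate and exponent, initial structural parameter, force
#' modulation, and the per-process scaling factors, which under their
#' boundedness convention contribute six). An ablation flag on the viscous
#' term removes its 3 DOF.
#'
#' @param x a model or parameter object.
#' @param ... unused.
#' @export
dof <- function(x, ...) UseMethod("dof")

#' @export
dof.qlv_model <- function(x, ...) if (isTRUE(x$no_viscosity)) 12L else 15L

#' @export
dof.aqlv_model <- function(x, ...) if (isTRUE(x$no_viscosity)) 32L else 35L

#' @export
print.eom_model <- function(x, ...) {
  cat(sprintf("%s passive-muscle model (%d DOF)\n", x$kind, dof(x)))
  cat(sprintf("  length-tension: c0=%.4g gf, c1=%.4g gf/mm, c2=%.4g gf, c3=%.4g 1/mm\n",
              x$lt$c0, x$lt$c1, x$lt$c2, x$lt$c3))
  cat("  tau (s):", paste(signif(x$tau, 4), collapse = ", "), "\n")
  if (x$kind == "QLV")
    cat("  g:", paste(signif(x$g, 3), collapse = ", "),
        sprintf(" alpha = %.4g\n", x$alpha))
  v <- x$viscosity
  cat(sprintf("  viscosity: eta(L) = %.4g + %.4g L + %.4g L^2 gf s/mm\n",
              v$w0, v$w1, v$w2))
  invisible(x)
}
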
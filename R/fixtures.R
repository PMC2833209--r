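# Packaged parameter fixtures.
#
# The attenuation parameters below are transcriptions of the published
# fitted values for four muscles (SR = superior rectus, LR = lateral
# rectus, of monkeys m2-m4), one set for the ANLV built on the QLV base and
# one for the ANLV built on the AQLV base. The base-model parameters for
# those muscles were published elsewhere and are NOT transcribed here: the
# base models attached to these fixtures are SYNTHETIC, chosen to be
# representative of passive extraocular muscle (see the methods vignette),
# and are labeled as such in their provenance.

.atten_tables <- list(
  qlv_anlv = list(
    m2SR = list(k_d = 0.200, n = 1.490, lambda0 = 3.000, k_f = 0.001,
                gamma = c(0.980, 0.110, 0.810, 0.210, 0.860, 0.300, 0.370)),
    m3LR = list(k_d = 0.240, n = 1.410, lambda0 = 2.060, k_f = 0.001,
                gamma = c(0.000, 0.000, 0.020, 0.680, 0.850, 0.240, 0.660)),
    m3SR = list(k_d = 0.310, n = 1.450, lambda0 = 3.000, k_f = 0.001,
                gamma = c(0.000, 0.000, 0.000, 0.580, 0.630, 0.470, 0.760)),
    m4LR = list(k_d = 0.320, n = 1.290, lambda0 = 1.930, k_f = 0.001,
                gamma = c(0.000, 0.000, 0.180, 0.730, 0.530, 0.580, 0.830))),
  aqlv_anlv = list(
    m2SR = list(k_d = 0.270, n = 1.260, lambda0 = 1.620, k_f = 0.001,
                gamma = c(0.270, 0.040, 0.740, 0.800, 0.860, 0.990, 0.880)),
    m3LR = list(k_d = 0.280, n = 1.210, lambda0 = 1.410, k_f = 0.001,
                gamma = c(0.000, 0.000, 0.420, 0.990, 0.670, 0.950, 0.980)),
    m3SR = list(k_d = 0.600, n = 1.070, lambda0 = 1.510, k_f = 0.001,
                gamma = c(0.200, 0.000, 0.420, 0.850, 1.000, 0.960, 0.880)),
    m4LR = list(k_d = 0.450, n = 1.180, lambda0 = 1.640, k_f = 0.006,
                gamma = c(0.000, 0.000, 0.510, 0.990, 0.740, 0.860, 1.000))))

#' Synthetic QLV base model for passive extraocular muscle
#'
#' A representative (synthetic, not transcribed) QLV parameter set for a
#' monkey extraocular muscle over its ~8 mm elongation range: a
#' length-tension curve that is essentially linear up to ~3 mm with
#' accelerating stiffness beyond (about 23 gf at 8 mm), a relaxation
#' spectrum that puts most of its weight on the slow processes (the dynamic
#' force after a quick step takes seconds to decay, and even a 0.1 mm/s
#' stretch develops a considerable dynamic force), and a small viscosity.
#'
#' @param tau seven process time constants, s.
#' @return A `qlv_model`.
#' @export
synthetic_base_qlv <- function(tau = DEFAULT_TAU) {
  qlv_model(
    lt = length_tension(c0 = 1.5, c1 = 1.0, c2 = 0.25, c3 = 0.5),
    g = c(0.25, 0.25, 0.25, 0.30, 0.35, 0.50, 1.40),
    alpha = 0.5,
    tau = tau,
    viscosity = viscosity_law(w0 = 0.01, w1 = 0.002, w2 = 0))
}

#' Synthetic AQLV base model
#'
#' AQLV counterpart of [synthetic_base_qlv()]: each process's stiffness
#' profile is built by sampling the QLV stiffness law
#' `alpha * g_i * lt_slope(L)` at four knots spanning the working range,
#' with piecewise-linear interpolation between them.
#'
#' @param tau seven process time constants, s.
#' @param knots four knot elongations, mm.
#' @return An `aqlv_model`.
#' @export
synthetic_base_aqlv <- function(tau = DEFAULT_TAU, knots = c(0, 8/3, 16/3, 8)) {
  q <- synthetic_base_qlv(tau)
  ks <- t(vapply(1:7, function(i) q$alpha * q$g[i] * lt_slope(q$lt, knots),
                 numeric(length(knots))))
  aqlv_model(lt = q$lt, knot_lengths = knots, knot_stiffness = ks,
             tau = tau, viscosity = q$viscosity)
}

#' Load a packaged ANLV parameter fixture
#'
#' Returns an `anlv_model` combining the published attenuation parameters
#' for one of the four fitted muscles with the corresponding synthetic base
#' model. `kind` selects whether the attenuation set is the one fitted on
#' top of the QLV or of the AQLV base.
#'
#' @param kind `"qlv_anlv"` or `"aqlv_anlv"`.
#' @param muscle one of `"m2SR"`, `"m3LR"`, `"m3SR"`, `"m4LR"`.
#' @return An `anlv_model` with a `provenance` attribute.
#' @export
#' @examples
#' m <- load_fixture("qlv_anlv", "m4LR")
#' m$attenuation$k_d # 0.32
load_fixture <- function(kind = c("qlv_anlv", "aqlv_anlv"),
                         muscle = c("m2SR", "m3LR", "m3SR", "m4LR")) {
  kind <- match.arg(kind)
  if (!is.character(muscle) || length(muscle) != 1 ||
      !muscle %in% names(.atten_tables[[kind]]))
    stop(sprintf("unknown muscle '%s'; available: %s",
                 as.character(muscle)[1],
                 paste(names(.atten_tables[[kind]]), collapse = ", ")))
  a <- .atten_tables[[kind]][[muscle]]
  base <- if (kind == "qlv_anlv") synthetic_base_qlv() else synthetic_base_aqlv()
  m <- anlv_model(base, attenuation_params(a$k_d, a$n, a$lambda0, a$k_f,
                                           a$gamma))
  attr(m, "provenance") <- sprintf(
    "attenuation: published fit, muscle %s (%s); base model: synthetic fixture",
    muscle, kind)
  m
}
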
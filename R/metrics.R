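# Phenomenological diagnostics: dynamic force, the data/model viscoelastic
# ratio, relaxation cross-over, and relaxation-convergence time. These are
# the quantities in which the failure of the classical models (and the
# behavior of the attenuated model) is visible: after an elongation the
# muscle force quickly becomes a function of the final length alone, traces
# from different elongations converge within ~100 ms and can cross over,
# while unattenuated models keep the end-of-elongation ordering throughout
# the decay.

trace_t <- function(tr) tr$t
trace_F <- function(tr) if (!is.null(tr$F_total)) tr$F_total else tr$F
trace_L <- function(tr) tr$L

trace_at <- function(tr, time, what = c("F", "L")) {
  what <- match.arg(what)
  t <- trace_t(tr)
  if (time < t[1] - 1e-12 || time > t[length(t)] + 1e-12)
    stop(sprintf("time %.4g s is outside the trace record [%.4g, %.4g]",
                 time, t[1], t[length(t)]))
  y <- if (what == "F") trace_F(tr) else trace_L(tr)
  approx(t, y, xout = time, rule = 2)$y
}

trace_end_time <- function(tr) {
  if (inherits(tr, "eom_sim")) elongation_end(tr) else {
    if (is.null(tr$t_end)) stop("trace has no end-of-elongation time")
    tr$t_end
  }
}

#' Measured (or externally supplied) force trace
#'
#' Light container for a force record that did not come from [simulate()]:
#' a time grid, a force trace, optionally a length trace, and the
#' end-of-elongation time used for alignment.
#'
#' @param t time grid, s (uniform).
#' @param F force, gf.
#' @param t_end end-of-elongation time, s.
#' @param L optional elongation trace, mm.
#' @export
measured_trace <- function(t, F, t_end, L = NULL) {
  stopifnot(length(t) == length(F), t_end >= t[1], t_end <= t[length(t)])
  structure(list(t = t, F = F, L = L, t_end = t_end), class = "eom_trace")
}

#' Family of traces sharing a final length
#'
#' Groups traces (simulations or measured records) that end at a common
#' final length, aligned at each trace's own end-of-elongation time, for
#' cross-over and convergence diagnostics.
#'
#' @param ... `eom_sim` or `eom_trace` objects (or a single list of them).
#' @param labels optional labels.
#' @param check require all final lengths to agree within 1% of the spanned
#'   range.
#' @return An object of class `trace_family`.
#' @export
trace_family <- function(..., labels = NULL, check = TRUE) {
  traces <- list(...)
  if (length(traces) == 1 && is.list(traces[[1]]) &&
      !inherits(traces[[1]], c("eom_sim", "eom_trace")))
    traces <- traces[[1]]
  if (is.null(labels)) labels <- names(traces)
  if (is.null(labels) || any(labels == ""))
    labels <- paste0("trace", seq_along(traces))
  names(traces) <- labels
  Lend <- vapply(traces, function(tr) {
    L <- trace_L(tr)
    if (is.null(L)) NA_real_ else L[length(L)]
  }, numeric(1))
  if (check && !anyNA(Lend)) {
    Lall <- unlist(lapply(traces, trace_L))
    rng <- max(Lall) - min(Lall)
    if (rng > 0 && (max(Lend) - min(Lend)) > 0.01 * rng)
      stop("traces do not share a common final length (within 1% of range)")
  }
  structure(list(traces = traces,
                 t_end = vapply(traces, trace_end_time, numeric(1))),
            class = "trace_family")
}

#' Dynamic force
#'
#' The difference between the force in a trace and the static force at the
#' same length: `F(t) - lt_force(L(t))`. This is the part of the force
#' carried by the relaxation processes and the viscosity.
#'
#' @param trace an `eom_sim` or `eom_trace` with a length channel.
#' @param lt a `length_tension` object.
#' @param at_time time at which to evaluate, s (must lie within the trace).
#' @export
dynamic_force <- function(trace, lt, at_time) {
  L <- trace_at(trace, at_time, "L")
  trace_at(trace, at_time, "F") - lt_force(lt, L)
}

#' Data/model viscoelastic ratio
#'
#' Ratio between the purely viscoelastic force in a measured (or
#' "data-playing") trace and that predicted by a model at the end of the
#' elongation: `[F_data(t_end) - lt(L_end)] / [F_model(t_end) - lt(L_end)]`.
#' A ratio of 1 means the model captures the end-of-elongation force
#' exactly; ratios below 1 quantify how much the model overestimates it.
#' By construction the ratio is invariant to adding a common constant to
#' both traces and to the length-tension offset.
#'
#' @param data_trace,model_trace traces sharing the elongation end time and
#'   final length.
#' @param lt a `length_tension` object.
#' @param floor smallest admissible model viscoelastic force, gf; below it
#'   the ratio is undefined and an error is raised.
#' @export
viscoelastic_ratio <- function(data_trace, model_trace, lt, floor = 1e-6) {
  t_end <- trace_end_time(model_trace)
  L_end <- trace_at(model_trace, t_end, "L")
  stat <- lt_force(lt, L_end)
  den <- trace_at(model_trace, t_end, "F") - stat
  if (den < floor)
    stop(sprintf(
      "model viscoelastic force %.3g gf at end of elongation is below the floor (%.3g gf); ratio undefined",
      den, floor))
  (trace_at(data_trace, t_end, "F") - stat) / den
}

# matrix of post-elongation forces on a common relative-time grid
aligned_relaxation <- function(family) {
  trs <- family$traces
  dt <- vapply(trs, function(tr) {
    t <- trace_t(tr); (t[length(t)] - t[1]) / (length(t) - 1)
  }, numeric(1))
  if (max(dt) - min(dt) > 1e-9) stop("traces must share the sample interval")
  dt <- dt[1]
  horizon <- min(vapply(seq_along(trs), function(i) {
    t <- trace_t(trs[[i]]); t[length(t)] - family$t_end[i]
  }, numeric(1)))
  if (horizon < 0) stop("a trace ends before its elongation does")
  s <- seq(0, horizon, by = dt)
  Fm <- vapply(seq_along(trs), function(i) {
    approx(trace_t(trs[[i]]), trace_F(trs[[i]]),
           xout = family$t_end[i] + s, rule = 2)$y
  }, numeric(length(s)))
  colnames(Fm) <- names(trs)
  list(s = s, F = Fm)
}

#' Detect relaxation cross-over in a trace family
#'
#' Compares the ranking of forces at the end of the elongation with the
#' ranking `t_probe` seconds later, and reports per-pair first crossing
#' times. A cross-over means that a trace with the higher force at the end
#' of its elongation has the lower force later in the decay.
#'
#' @param family a [trace_family()] with at least two traces.
#' @param t_probe probe delay after the end of the elongation, s.
#' @return A list with `crossover` (logical), the two rankings, and a data
#'   frame of pairwise first crossing times (`NA` when a pair never
#'   crosses). The result does not depend on the order of the family.
#' @export
detect_crossover <- function(family, t_probe = 1) {
  stopifnot(inherits(family, "trace_family"), length(family$traces) >= 2)
  al <- aligned_relaxation(family)
  if (t_probe > al$s[length(al$s)])
    stop("t_probe exceeds the common post-elongation record")
  F0 <- al$F[1, ]
  Fp <- al$F[which.min(abs(al$s - t_probe)), ]
  nm <- colnames(al$F)
  pairs <- t(utils::combn(length(nm), 2))
  first_cross <- apply(pairs, 1, function(ij) {
    d <- al$F[, ij[1]] - al$F[, ij[2]]
    s0 <- sign(d[1])
    if (s0 == 0) return(NA_real_)
    k <- which(sign(d) == -s0)
    if (length(k) == 0) return(NA_real_)
    k <- k[1]
    # linear interpolation of the crossing between samples k-1 and k
    al$s[k - 1] + (al$s[k] - al$s[k - 1]) * d[k - 1] / (d[k - 1] - d[k])
  })
  rank_end <- rank(-F0); rank_probe <- rank(-Fp)
  list(crossover = !all(rank_end == rank_probe),
       rank_end = setNames(rank_end, nm),
       rank_probe = setNames(rank_probe, nm),
       pairs = data.frame(a = nm[pairs[, 1]], b = nm[pairs[, 2]],
                          first_crossing_s = first_cross,
                          stringsAsFactors = FALSE))
}

#' Relaxation convergence time of a trace family
#'
#' First post-elongation time at which the maximum pairwise force
#' difference across the family falls below `tol` and stays below it for
#' the rest of the common record. Returns `Inf` ("not reached") if the
#' family never converges within the record.
#'
#' @param family a [trace_family()] with at least two traces.
#' @param tol convergence tolerance, gf.
#' @return Time after the end of the elongation, s (0 if the traces already
#'   agree at the end of the elongation), or `Inf`.
#' @export
convergence_time <- function(family, tol) {
  stopifnot(inherits(family, "trace_family"), length(family$traces) >= 2,
            tol > 0)
  al <- aligned_relaxation(family)
  spread <- apply(al$F, 1, function(z) max(z) - min(z))
  below <- rev(cumprod(rev(spread < tol))) > 0  # below tol from here on
  if (!any(below)) return(Inf)
  al$s[which(below)[1]]
}
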
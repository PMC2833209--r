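# Plain-text interchange: trace/protocol CSVs and YAML parameter configs.
# Traces are small (<= ~1e5 samples), so diffable CSV is preferred over any
# binary format. Numbers are written with 17 significant digits so that a
# write/read round trip reproduces the values to machine precision.

fmt_num_df <- function(df) {
  df[] <- lapply(df, function(col)
    if (is.numeric(col)) sprintf("%.17g", col) else col)
  df
}

#' Write a trace or protocol to CSV
#'
#' Columns `time_s,length_mm,velocity_mm_s` for a protocol; a simulation or
#' recording adds `force_gf` (and, for simulations, the force decomposition
#' and the lambda trace). For an `eom_protocol`, phase marks and reset
#' marks are written to a YAML sidecar `<path>.meta.yaml`.
#'
#' @param x an `eom_protocol`, `eom_sim`, `eom_recording`, or data frame.
#' @param path output CSV path.
#' @export
write_trace <- function(x, path) {
  if (inherits(x, "eom_recording")) {
    df <- data.frame(time_s = x$t, length_mm = x$L,
                     velocity_mm_s = x$protocol$v, force_gf = x$force)
  } else if (inherits(x, c("eom_sim", "eom_protocol"))) {
    df <- as.data.frame(x)
  } else {
    df <- as.data.frame(x)
  }
  write.csv(fmt_num_df(df), path, row.names = FALSE, quote = FALSE)
  if (inherits(x, "eom_protocol")) {
    meta <- list(phases = lapply(seq_len(nrow(x$phases)), function(i)
      list(start = x$phases$start[i], end = x$phases$end[i],
           label = x$phases$label[i])),
      resets = as.list(x$resets))
    yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  }
  invisible(path)
}

read_trace_df <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (length(names(df)) < length(required) ||
      !identical(names(df)[seq_along(required)], required)) {
    missing <- setdiff(required, names(df))
    if (length(missing))
      stop("missing required column(s): ", paste(missing, collapse = ", "))
    stop("required columns present but reordered; expected ",
         paste(required, collapse = ","))
  }
  for (col in names(df)) {
    if (!is.numeric(df[[col]]))
      stop(sprintf("non-numeric value in column '%s' (first bad row: %d)",
                   col, which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]))
    if (anyNA(df[[col]]))
      stop(sprintf("missing/non-numeric value in column '%s' at row %d",
                   col, which(is.na(df[[col]]))[1]))
  }
  df
}

# check grid uniformity and snap to the exact uniform grid; jitter beyond
# 1% of dt is rejected rather than silently regularized
snap_grid <- function(t) {
  n <- length(t)
  if (n < 2) stop("trace needs at least 2 samples")
  dt <- (t[n] - t[1]) / (n - 1)
  if (dt <= 0) stop("time must be strictly increasing")
  dev <- max(abs(diff(t) - dt))
  if (dev > 0.01 * dt)
    stop(sprintf(
      "non-uniform time grid: sample-interval deviation %.3g s exceeds 1%% of dt = %.3g s",
      dev, dt))
  list(t = t[1] + (0:(n - 1)) * dt, dt = dt)
}

#' Read a trace CSV
#'
#' Validates the dialect written by [write_trace()]: required columns in
#' order, numeric cells, uniform time grid (jitter above 1% of the sample
#' interval is rejected).
#'
#' @param path CSV path.
#' @return A data frame with the snapped uniform time grid.
#' @export
read_trace <- function(path) {
  df <- read_trace_df(path, c("time_s", "length_mm", "velocity_mm_s"))
  df$time_s <- snap_grid(df$time_s)$t
  df
}

#' Read an elongation protocol from CSV
#'
#' Reads `time_s,length_mm,velocity_mm_s` plus, if present, the phase/reset
#' sidecar `<path>.meta.yaml` written by [write_trace()]. Without a
#' sidecar, phases are inferred from the velocity trace (contiguous runs of
#' `v > 0` become elongation phases).
#'
#' @param path CSV path.
#' @return An `eom_protocol`.
#' @export
read_protocol <- function(path) {
  df <- read_trace(path)
  meta_path <- paste0(path, ".meta.yaml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    phases <- do.call(rbind, lapply(meta$phases, function(p)
      phase_df(p$start, p$end, p$label)))
    if (is.null(phases)) phases <- phase_df()
    resets <- as.numeric(unlist(meta$resets))
  } else {
    moving <- df$velocity_mm_s > 1e-9
    r <- rle(moving)
    ends <- cumsum(r$lengths)
    starts <- c(1, head(ends, -1) + 1)
    phases <- phase_df(df$time_s[starts], df$time_s[ends],
                       ifelse(r$values, "elongation", "hold"))
    resets <- numeric(0)
  }
  new_protocol(df$time_s, df$length_mm, df$velocity_mm_s, phases, resets)
}

lt_to_list <- function(lt) lt[c("c0", "c1", "c2", "c3")]
visc_to_list <- function(v) v[c("w0", "w1", "w2")]

#' Write a model parameter config
#'
#' Structured YAML with blocks `kind`, `length_tension`, `tau`, `spectrum`
#' (QLV) or `stiffness_profiles` (AQLV), `viscosity`, an optional
#' `attenuation` block, a `units` declaration and a free-text `provenance`
#' note. Round-trips losslessly through [read_model_config()].
#'
#' @param model an `eom_model`.
#' @param path output path.
#' @param provenance note recorded in the file (e.g. which fixture the
#'   values transcribe, or that they are synthetic).
#' @export
write_model_config <- function(model, path, provenance = NULL) {
  stopifnot(inherits(model, "eom_model"))
  if (is.null(provenance))
    provenance <- attr(model, "provenance") %||% "unspecified"
  base <- if (inherits(model, "anlv_model")) model$base else model
  cfg <- list(kind = model$kind,
              units = list(length = "mm", speed = "mm/s", time = "s",
                           force = "gf"),
              provenance = provenance,
              length_tension = lt_to_list(base$lt),
              tau = as.list(base$tau))
  if (base$kind == "QLV") {
    cfg$spectrum <- list(g = as.list(base$g), alpha = base$alpha)
  } else {
    cfg$stiffness_profiles <- lapply(1:7, function(i)
      list(knot_lengths = as.list(base$knot_lengths[i, ]),
           knot_stiffness = as.list(base$knot_stiffness[i, ])))
  }
  cfg$viscosity <- visc_to_list(base$viscosity)
  if (inherits(model, "anlv_model")) {
    a <- model$attenuation
    cfg$attenuation <- list(k_d = a$k_d, n = a$n, lambda0 = a$lambda0,
                            k_f = a$k_f, gamma = as.list(a$gamma))
  }
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a model parameter config
#'
#' @param path YAML path written by [write_model_config()].
#' @return An `eom_model` (with a `provenance` attribute).
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  lt <- do.call(length_tension, cfg$length_tension)
  visc <- do.call(viscosity_law, cfg$viscosity)
  tau <- as.numeric(unlist(cfg$tau))
  base_kind <- sub("^ANLV/", "", cfg$kind)
  base <- if (base_kind == "QLV") {
    qlv_model(lt, g = as.numeric(unlist(cfg$spectrum$g)),
              alpha = cfg$spectrum$alpha, tau = tau, viscosity = visc)
  } else {
    kl <- t(vapply(cfg$stiffness_profiles,
                   function(p) as.numeric(unlist(p$knot_lengths)), numeric(4)))
    ks <- t(vapply(cfg$stiffness_profiles,
                   function(p) as.numeric(unlist(p$knot_stiffness)), numeric(4)))
    aqlv_model(lt, kl, ks, tau = tau, viscosity = visc)
  }
  out <- if (!is.null(cfg$attenuation)) {
    a <- cfg$attenuation
    anlv_model(base, attenuation_params(a$k_d, a$n, a$lambda0, a$k_f,
                                        as.numeric(unlist(a$gamma))))
  } else base
  attr(out, "provenance") <- cfg$provenance
  out
}
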
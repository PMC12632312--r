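#' Construct a diameter trace
#'
#' A `diameter_trace` holds one pressure-myography recording: inner vessel
#' diameter sampled uniformly (default 30 Hz, the frame rate of the video
#' edge-detection system) together with the inflow and outflow pressure
#' channels. Carrying the recorded pressures, rather than trusting the protocol
#' blindly, lets [segment_by_protocol()] cross-check that the file matches the
#' protocol it is analyzed against.
#'
#' @param time numeric vector, seconds from recording start, strictly
#'   increasing with constant spacing.
#' @param diameter numeric vector, inner diameter in micrometres (> 0).
#' @param pressure_in,pressure_out numeric vectors, cmH2O. `pressure_out`
#'   defaults to `pressure_in` (pressures are held equal during the protocol so
#'   there is no imposed gradient for forward flow).
#' @param sample_rate sampling rate in Hz; inferred from `time` when `NULL`.
#' @param vessel_id,condition labels attached to the recording.
#' @param is_passive logical; `TRUE` for a Ca2+-free (passive) recording used
#'   to measure maximal passive diameters.
#' @return A `diameter_trace`: data frame with columns `time`, `diameter`,
#'   `pressure_in`, `pressure_out` and attributes `sample_rate`, `vessel_id`,
#'   `condition`, `is_passive`.
#' @export
diameter_trace <- function(time, diameter, pressure_in,
                           pressure_out = pressure_in,
                           sample_rate = NULL,
                           vessel_id = "vessel", condition = "unknown",
                           is_passive = FALSE) {
  n <- length(time)
  if (n < 2) stop("a trace needs at least 2 samples", call. = FALSE)
  if (length(diameter) != n || length(pressure_in) != n || length(pressure_out) != n) {
    stop("all trace channels must have the same length", call. = FALSE)
  }
  dt <- diff(time)
  if (any(dt <= 0)) {
    stop("time must be strictly increasing (first violation at row ",
         which(dt <= 0)[1] + 1L, ")", call. = FALSE)
  }
  if (max(dt) - min(dt) > 1e-6) {
    stop("time is not uniformly sampled (spacing varies by more than 1e-6 s)",
         call. = FALSE)
  }
  if (any(!is.finite(diameter)) || any(diameter <= 0)) {
    stop("diameter must be positive everywhere (first violation at row ",
         which(!is.finite(diameter) | diameter <= 0)[1], ")", call. = FALSE)
  }
  sr <- if (is.null(sample_rate)) 1 / stats::median(dt) else sample_rate
  if (abs(1 / sr - stats::median(dt)) > 1e-6) {
    stop("stated sample_rate disagrees with time spacing", call. = FALSE)
  }
  out <- data.frame(time = as.numeric(time), diameter = as.numeric(diameter),
                    pressure_in = as.numeric(pressure_in),
                    pressure_out = as.numeric(pressure_out))
  attr(out, "sample_rate") <- sr
  attr(out, "vessel_id") <- as.character(vessel_id)
  attr(out, "condition") <- as.character(condition)
  attr(out, "is_passive") <- isTRUE(is_passive)
  class(out) <- c("diameter_trace", "data.frame")
  out
}

#' @export
print.diameter_trace <- function(x, ...) {
  cat(sprintf(
    "<diameter_trace '%s'> condition=%s%s, %d samples @ %g Hz (%.1f s)\n",
    attr(x, "vessel_id"), attr(x, "condition"),
    if (attr(x, "is_passive")) " [passive]" else "",
    nrow(x), attr(x, "sample_rate"), nrow(x) / attr(x, "sample_rate")))
  cat(sprintf("  diameter %.1f-%.1f um, pressure %g-%g cmH2O\n",
              min(x$diameter), max(x$diameter),
              min(x$pressure_in), max(x$pressure_in)))
  invisible(x)
}

.trace_columns <- c(time = "time_s", pressure_in = "pressure_in_cmH2O",
                    pressure_out = "pressure_out_cmH2O", diameter = "diameter_um")

#' Read a diameter trace from CSV
#'
#' Format: optional `#`-prefixed metadata lines (`# key: value` for
#' `vessel_id`, `condition`, `is_passive`, `sample_rate`), then a header row
#' naming the four required columns `time_s`, `pressure_in_cmH2O`,
#' `pressure_out_cmH2O`, `diameter_um`, then comma-separated data. Validation
#' (uniform sampling, positive diameter) is as in [diameter_trace()].
#'
#' @param path path to a trace CSV written by [write_trace()] or any file in
#'   the same dialect.
#' @return A validated `diameter_trace`.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta_idx <- meta_idx[meta_idx == seq_along(meta_idx)]  # leading block only
  meta <- list()
  for (ln in lines[meta_idx]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)\\s*$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  if (!length(body)) stop("trace file has no data", call. = FALSE)
  dat <- utils::read.csv(text = body, check.names = FALSE)
  missing_cols <- setdiff(unname(.trace_columns), names(dat))
  if (length(missing_cols)) {
    stop("trace file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  diameter_trace(
    time = dat[[.trace_columns[["time"]]]],
    diameter = dat[[.trace_columns[["diameter"]]]],
    pressure_in = dat[[.trace_columns[["pressure_in"]]]],
    pressure_out = dat[[.trace_columns[["pressure_out"]]]],
    sample_rate = if (!is.null(meta$sample_rate)) as.numeric(meta$sample_rate) else NULL,
    vessel_id = if (!is.null(meta$vessel_id)) meta$vessel_id else "vessel",
    condition = if (!is.null(meta$condition)) meta$condition else "unknown",
    is_passive = identical(tolower(meta$is_passive %||% "false"), "true")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a diameter trace to CSV
#'
#' Values are rendered at full double precision (`%.17g`) so that
#' `read_trace(write_trace(t))` reproduces `t` bit-exactly. Metadata
#' (vessel id, condition, passive flag, sample rate) is stored in leading
#' `#` comment lines.
#'
#' @param trace a `diameter_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (!inherits(trace, "diameter_trace")) stop("not a diameter_trace", call. = FALSE)
  num <- function(x) sprintf("%.17g", x)
  header <- c(
    sprintf("# vessel_id: %s", attr(trace, "vessel_id")),
    sprintf("# condition: %s", attr(trace, "condition")),
    sprintf("# is_passive: %s", if (attr(trace, "is_passive")) "true" else "false"),
    sprintf("# sample_rate: %.17g", attr(trace, "sample_rate")),
    paste(unname(.trace_columns[c("time", "pressure_in", "pressure_out", "diameter")]),
          collapse = ",")
  )
  rows <- paste(num(trace$time), num(trace$pressure_in),
                num(trace$pressure_out), num(trace$diameter), sep = ",")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Slice a trace into per-step analysis windows
#'
#' Steps are laid out consecutively from the start of the trace according to
#' the protocol durations. Each analysis window is the half-open interval
#' `[step start + settle, step end)`: the leading `settle` seconds of every
#' step are discarded so the post-step transient (the vessel re-equilibrating
#' after a pressure change) does not contaminate averages. The recorded
#' inflow-pressure channel is cross-checked against the protocol pressure in
#' every window.
#'
#' @param trace a `diameter_trace`.
#' @param protocol a `pressure_protocol`.
#' @param settle seconds discarded at the start of each step (default 20).
#' @param min_window minimum admissible window length in seconds (default 30).
#' @param pressure_tol tolerance (cmH2O) for the recorded-vs-protocol pressure
#'   cross-check (default 0.05).
#' @return A `step_windows` data frame: `step_index`, `pressure`,
#'   `start_time`, `end_time`, one row per protocol step, in order.
#' @export
segment_by_protocol <- function(trace, protocol, settle = 20,
                                min_window = 30, pressure_tol = 0.05) {
  stopifnot(inherits(trace, "diameter_trace"), inherits(protocol, "pressure_protocol"))
  if (settle < 0) stop("`settle` must be non-negative", call. = FALSE)
  t0 <- trace$time[1]
  sr <- attr(trace, "sample_rate")
  total <- protocol_duration(protocol)
  extent <- nrow(trace) / sr
  if (total > extent + 1 / sr + 1e-9) {
    stop(sprintf("trace (%.1f s) is shorter than the protocol (%.1f s)",
                 extent, total), call. = FALSE)
  }
  ends <- cumsum(protocol$duration)
  starts <- c(0, ends[-length(ends)])
  win_start <- t0 + starts + settle
  win_end <- t0 + ends
  if (any(win_end - win_start < min_window)) {
    bad <- which(win_end - win_start < min_window)[1]
    stop(sprintf("analysis window for step %d is shorter than min_window (%g s)",
                 bad, min_window), call. = FALSE)
  }
  for (i in seq_len(nrow(protocol))) {
    in_win <- trace$time >= win_start[i] & trace$time < win_end[i]
    p_rec <- stats::median(trace$pressure_in[in_win])
    if (abs(p_rec - protocol$pressure[i]) > pressure_tol) {
      stop(sprintf(
        "recorded pressure %.2f cmH2O at step %d does not match protocol pressure %.2f",
        p_rec, i, protocol$pressure[i]), call. = FALSE)
    }
  }
  out <- data.frame(step_index = seq_len(nrow(protocol)),
                    pressure = protocol$pressure,
                    start_time = win_start, end_time = win_end)
  class(out) <- c("step_windows", "data.frame")
  out
}
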
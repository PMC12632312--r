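#' Contractile-function parameters
#'
#' The five standard parameters characterizing lymphatic contractile function,
#' computed from end-diastolic diameter (EDD), end-systolic diameter (ESD) and
#' the maximal passive diameter DMAX at the same intraluminal pressure:
#'
#' * amplitude: `EDD - ESD` (um)
#' * normalized amplitude: `(EDD - ESD) / DMAX * 100` (% of DMAX)
#' * ejection fraction: `(EDD^2 - ESD^2) / EDD^2`, the fractional luminal
#'   area ejected per contraction, in `[0, 1)`
#' * tone: `(DMAX - EDD) / DMAX * 100` (%), how far the diastolic diameter
#'   sits below the fully relaxed passive diameter
#' * fractional pump flow: `EF * FREQ` (min^-1), an index of active pumping
#'
#' All are vectorized. `vessel_tone()` may legitimately be negative when noise
#' puts EDD slightly above DMAX; it warns rather than clips.
#'
#' @param edd end-diastolic diameter (um, > 0).
#' @param esd end-systolic diameter (um, 0 < esd <= edd).
#' @param dmax maximal passive diameter at the same pressure (um, > 0).
#' @param ef ejection fraction in `[0, 1)`.
#' @param freq contraction frequency (min^-1, >= 0).
#' @return Numeric vector of the requested parameter.
#' @name contractile_parameters
NULL

check_dia <- function(edd, esd) {
  if (any(!is.finite(edd)) || any(edd <= 0)) {
    stop("EDD must be positive", call. = FALSE)
  }
  if (any(!is.finite(esd)) || any(esd <= 0)) {
    stop("ESD must be positive", call. = FALSE)
  }
  if (any(esd > edd)) stop("ESD exceeds EDD", call. = FALSE)
}

#' @rdname contractile_parameters
#' @export
amplitude <- function(edd, esd) {
  check_dia(edd, esd)
  edd - esd
}

#' @rdname contractile_parameters
#' @export
normalized_amplitude <- function(edd, esd, dmax) {
  check_dia(edd, esd)
  if (any(!is.finite(dmax)) || any(dmax <= 0)) {
    stop("DMAX must be positive", call. = FALSE)
  }
  (edd - esd) / dmax * 100
}

#' @rdname contractile_parameters
#' @export
ejection_fraction <- function(edd, esd) {
  check_dia(edd, esd)
  1 - (esd / edd)^2
}

#' @rdname contractile_parameters
#' @export
vessel_tone <- function(dmax, edd) {
  if (any(!is.finite(dmax)) || any(dmax <= 0)) {
    stop("DMAX must be positive", call. = FALSE)
  }
  if (any(!is.finite(edd)) || any(edd <= 0)) {
    stop("EDD must be positive", call. = FALSE)
  }
  out <- (dmax - edd) / dmax * 100
  if (any(out < 0)) {
    warning("negative tone: EDD exceeds DMAX (not clipped)", call. = FALSE)
  }
  out
}

#' @rdname contractile_parameters
#' @export
fractional_pump_flow <- function(ef, freq) {
  if (any(!is.finite(ef)) || any(ef < 0) || any(ef >= 1)) {
    stop("EF must lie in [0, 1)", call. = FALSE)
  }
  if (any(!is.finite(freq)) || any(freq < 0)) {
    stop("FREQ must be non-negative", call. = FALSE)
  }
  ef * freq
}

#' Maximal passive diameters from a Ca2+-free recording
#'
#' After equilibration in Ca2+-free buffer the vessel has no active tone, so
#' the diameter at each pressure step is the maximal passive diameter DMAX(P).
#' The trace is segmented by the protocol and DMAX is the mean diameter over
#' each analysis window; windows at a repeated pressure are pooled.
#' If contractions are still detected in the supposedly passive trace, a
#' warning (not an error) is raised.
#'
#' @param passive_trace a `diameter_trace` with `is_passive = TRUE`.
#' @param protocol a `pressure_protocol`.
#' @param settle seconds discarded at each step start (default 20).
#' @param params detection parameters used for the residual-contraction check.
#' @return A `passive_diameters` data frame with columns `pressure`, `dmax`
#'   (one row per distinct pressure).
#' @export
passive_dmax <- function(passive_trace, protocol, settle = 20,
                         params = detection_params()) {
  stopifnot(inherits(passive_trace, "diameter_trace"))
  if (!attr(passive_trace, "is_passive")) {
    stop("trace is not flagged is_passive; refusing to treat an active ",
         "recording as a passive-diameter measurement", call. = FALSE)
  }
  windows <- segment_by_protocol(passive_trace, protocol, settle = settle)
  means <- numeric(nrow(windows))
  n_ev <- 0L
  for (i in seq_len(nrow(windows))) {
    sel <- passive_trace$time >= windows$start_time[i] &
      passive_trace$time < windows$end_time[i]
    means[i] <- mean(passive_trace$diameter[sel])
    n_ev <- n_ev + nrow(detect_contractions(passive_trace, windows[i, ], params))
  }
  if (n_ev > 0L) {
    warning(n_ev, " contraction(s) detected in a passive trace; ",
            "check the Ca2+-free equilibration", call. = FALSE)
  }
  agg <- stats::aggregate(list(dmax = means), list(pressure = windows$pressure), mean)
  agg <- agg[order(agg$pressure), , drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("passive_diameters", "data.frame")
  agg
}

dmax_lookup <- function(passive, pressure, tol = 1e-6) {
  i <- which(abs(passive$pressure - pressure) <= tol)
  if (!length(i)) {
    stop("no passive DMAX available for pressure ", pressure,
         " cmH2O; the passive table must cover every analyzed pressure",
         call. = FALSE)
  }
  passive$dmax[i[1]]
}

#' Summarize one pressure step
#'
#' Averages the detected contractions over the analysis window into one row of
#' contractile parameters. EDD and ESD are means over events; FREQ comes from
#' [step_frequency()]. Amplitude, normalized amplitude and ejection fraction
#' are computed from the step-mean EDD/ESD (`per_event = TRUE` instead
#' averages per-event values; the two orders differ slightly for EF). When no
#' contraction occurred (FREQ = 0) the amplitude-family parameters are omitted
#' (`NA`) — an amplitude is undefined without a contraction — while tone is
#' still reported, computed from the mean smoothed diameter of the window as a
#' stand-in for EDD, and FPF is 0.
#'
#' @param events a `contraction_events` data frame for this window.
#' @param window the corresponding `step_windows` row.
#' @param dmax DMAX (um) at this window's pressure, or a `passive_diameters`
#'   table to look it up in.
#' @param trace the `diameter_trace` (required to compute tone when no events
#'   were detected; optional otherwise).
#' @param params detection parameters (smoothing width for the no-event tone).
#' @param per_event logical; average per-event parameter values instead of
#'   computing parameters from mean diameters.
#' @return A one-row `step_summary` data frame: `pressure`, `n_events`, `edd`,
#'   `esd`, `freq`, `amp`, `norm_amp`, `ef`, `tone`, `fpf`.
#' @export
summarize_step <- function(events, window, dmax, trace = NULL,
                           params = detection_params(), per_event = FALSE) {
  pressure <- as.numeric(window$pressure)
  if (inherits(dmax, "data.frame")) dmax <- dmax_lookup(dmax, pressure)
  if (!is.finite(dmax) || dmax <= 0) stop("DMAX must be positive", call. = FALSE)
  n <- nrow(events)
  freq <- step_frequency(events, window)
  if (n == 0L) {
    if (is.null(trace)) {
      stop("a trace is required to compute tone for a step with no events",
           call. = FALSE)
    }
    sel <- trace$time >= as.numeric(window$start_time) &
      trace$time < as.numeric(window$end_time)
    sm <- moving_average(trace$diameter[sel],
                         round(params$smooth_window * attr(trace, "sample_rate")))
    edd <- mean(sm)
    out <- data.frame(pressure = pressure, n_events = 0L, edd = edd,
                      esd = NA_real_, freq = 0, amp = NA_real_,
                      norm_amp = NA_real_, ef = NA_real_,
                      tone = vessel_tone(dmax, edd), fpf = 0)
  } else {
    edd <- mean(events$edd)
    esd <- mean(events$esd)
    if (per_event) {
      amp <- mean(amplitude(events$edd, events$esd))
      namp <- mean(normalized_amplitude(events$edd, events$esd, dmax))
      ef <- mean(ejection_fraction(events$edd, events$esd))
    } else {
      amp <- amplitude(edd, esd)
      namp <- normalized_amplitude(edd, esd, dmax)
      ef <- ejection_fraction(edd, esd)
    }
    out <- data.frame(pressure = pressure, n_events = n, edd = edd, esd = esd,
                      freq = freq, amp = amp, norm_amp = namp, ef = ef,
                      tone = vessel_tone(dmax, edd),
                      fpf = fractional_pump_flow(ef, freq))
  }
  class(out) <- c("step_summary", "data.frame")
  out
}

#' Per-step contractile summary for a whole recording
#'
#' Segments the trace by the protocol, detects contractions in every window,
#' and stacks one [summarize_step()] row per step.
#'
#' @param trace an active `diameter_trace`.
#' @param protocol a `pressure_protocol`.
#' @param passive a `passive_diameters` table covering every protocol pressure.
#' @param settle seconds discarded at each step start (default 20).
#' @param params a [detection_params()] list.
#' @param per_event see [summarize_step()].
#' @return A `step_summary` data frame with one row per protocol step, plus
#'   `step_index` and `vessel_id` columns.
#' @export
summarize_trace <- function(trace, protocol, passive, settle = 20,
                            params = detection_params(), per_event = FALSE) {
  windows <- segment_by_protocol(trace, protocol, settle = settle)
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    ev <- detect_contractions(trace, w, params)
    s <- summarize_step(ev, w, passive, trace = trace, params = params,
                        per_event = per_event)
    s$step_index <- w$step_index
    s
  })
  out <- do.call(rbind, rows)
  out$vessel_id <- attr(trace, "vessel_id")
  class(out) <- c("step_summary", "data.frame")
  out
}
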
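#' Analysis windows implied by a protocol alone
#'
#' The same window arithmetic as [segment_by_protocol()] but derived purely
#' from the protocol (no trace, hence no recorded-pressure cross-check):
#' step `s` occupies `[start_s + settle, end_s)` with steps laid out
#' consecutively from `t0`.
#'
#' @param protocol a `pressure_protocol`.
#' @param settle seconds discarded at each step start.
#' @param t0 time of protocol start (s, default 0).
#' @return A `step_windows` data frame.
#' @export
protocol_windows <- function(protocol, settle = 20, t0 = 0) {
  stopifnot(inherits(protocol, "pressure_protocol"))
  ends <- cumsum(protocol$duration)
  starts <- c(0, ends[-length(ends)])
  out <- data.frame(step_index = seq_len(nrow(protocol)),
                    pressure = protocol$pressure,
                    start_time = t0 + starts + settle,
                    end_time = t0 + ends)
  class(out) <- c("step_windows", "data.frame")
  out
}

#' Full single-vessel analysis: segment, detect, summarize, fit
#'
#' Runs the complete per-vessel pipeline on one active recording: protocol
#' segmentation, contraction detection in every analysis window, per-step
#' contractile parameters against the passive DMAX table, and the F-P
#' chronotropy fit.
#'
#' @param trace an active `diameter_trace`.
#' @param passive a `passive_diameters` table (from [passive_dmax()]) or a
#'   passive `diameter_trace` to derive one from.
#' @param protocol a `pressure_protocol`.
#' @param settle seconds discarded at each step start (default 20).
#' @param params a [detection_params()] list.
#' @param ... passed to [summarize_trace()].
#' @return A list with `summary` (per-step `step_summary`) and `fit`
#'   (an `fp_fit`).
#' @export
analyze_vessel <- function(trace, passive, protocol = default_protocol(),
                           settle = 20, params = detection_params(), ...) {
  if (inherits(passive, "diameter_trace")) {
    passive <- passive_dmax(passive, protocol, settle = settle, params = params)
  }
  summary <- summarize_trace(trace, protocol, passive, settle = settle,
                             params = params, ...)
  list(summary = summary, fit = fit_fp(summary))
}

#' Per-vessel F-P slopes for a simulated cohort
#'
#' Simulates `n_vessels` recordings from a preset and runs the analysis to a
#' per-vessel chronotropy fit. `method = "trace"` exercises the full path
#' (30 Hz waveform synthesis, detection, per-step summary, fit);
#' `method = "events"` draws only the ground-truth gamma event times and feeds
#' them to [step_frequency()]/[fit_fp()] directly — statistically equivalent
#' for frequency-derived quantities and far cheaper, intended for large
#' replication studies.
#'
#' @param preset a `genotype_preset` or shipped preset name.
#' @param n_vessels cohort size.
#' @param seed integer seed driving the whole cohort.
#' @param protocol a `pressure_protocol`.
#' @param settle seconds discarded at each step start.
#' @param method `"trace"` (full pipeline) or `"events"` (event-level).
#' @param params detection parameters (trace method only).
#' @return Data frame with one row per vessel: `vessel_id`, `slope`,
#'   `intercept`, `r2`, `deltaF`.
#' @export
experiment_slopes <- function(preset, n_vessels, seed,
                              protocol = default_protocol(), settle = 20,
                              method = c("trace", "events"),
                              params = detection_params()) {
  method <- match.arg(method)
  preset <- get_preset(preset)
  if (method == "trace") {
    exp <- simulate_experiment(preset, n_vessels, seed, protocol = protocol)
    passive <- passive_dmax(exp$passive, protocol, settle = settle)
    fits <- lapply(exp$traces, function(tr) {
      analyze_vessel(tr, passive, protocol, settle = settle, params = params)$fit
    })
    ids <- vapply(exp$traces, attr, character(1), "vessel_id")
  } else {
    seeds <- withr::with_seed(seed,
                              sample.int(.Machine$integer.max - 1L, n_vessels + 1L))
    windows <- protocol_windows(protocol, settle = settle)
    fits <- lapply(seq_len(n_vessels), function(i) {
      ev <- simulate_events(preset, protocol, seed = seeds[i])
      freq <- vapply(seq_len(nrow(windows)), function(s) {
        w <- windows[s, ]
        nd <- ev$nadir_time[ev$step_index == s &
                              ev$nadir_time >= w$start_time &
                              ev$nadir_time < w$end_time]
        step_frequency(data.frame(nadir_time = nd), w)
      }, numeric(1))
      fit_fp(data.frame(pressure = windows$pressure, freq = freq))
    })
    ids <- sprintf("%s_v%02d", preset$name, seq_len(n_vessels))
  }
  data.frame(vessel_id = ids,
             slope = vapply(fits, `[[`, numeric(1), "slope"),
             intercept = vapply(fits, `[[`, numeric(1), "intercept"),
             r2 = vapply(fits, `[[`, numeric(1), "r2"),
             deltaF = vapply(fits, `[[`, numeric(1), "deltaF"))
}
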
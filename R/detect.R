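#' Detection parameters for spontaneous contractions
#'
#' @param smooth_window width (s) of the centred moving average applied to the
#'   diameter channel before extremum finding. Default 0.3 s (9 samples at
#'   30 Hz) — wide enough to suppress sensor noise, narrow relative to the
#'   ~1.5 s systolic phase so nadirs are not flattened.
#' @param min_amplitude minimum contraction amplitude in um. Default 5 um:
#'   small localized diameter oscillations below 5 um are treated as
#'   non-propulsive and excluded.
#' @param refractory minimum separation (s) between consecutive nadirs;
#'   candidates closer than this are merged, keeping the deeper nadir.
#' @param nadir_neighborhood half-width (s) of the raw-trace search window
#'   around a smoothed nadir from which the end-systolic diameter is taken.
#' @return A `detection_params` list.
#' @export
detection_params <- function(smooth_window = 0.3, min_amplitude = 5,
                             refractory = 1.0, nadir_neighborhood = 0.5) {
  vals <- c(smooth_window = smooth_window, min_amplitude = min_amplitude,
            refractory = refractory, nadir_neighborhood = nadir_neighborhood)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all detection parameters must be positive", call. = FALSE)
  }
  structure(as.list(vals), class = "detection_params")
}

# Centred moving average; the window shrinks symmetrically near the edges.
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  n <- length(x)
  h <- (k - 1L) %/% 2L
  if (h == 0L || n < 3L) return(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Indices of local minima (or maxima), middle of flat plateaus.
local_extrema <- function(x, minima = TRUE) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  nz <- which(d != 0)
  if (length(nz) < 2L) return(integer(0))
  s <- sign(d[nz])
  from <- if (minima) -1 else 1
  j <- which(s[-length(s)] == from & s[-1] == -from)
  as.integer(floor((nz[j] + 1L + nz[j + 1L]) / 2))
}

# Topographic prominence of minima of x at indices idx: height of the lower of
# the two enclosing maxima above the minimum, where each side is scanned until
# a sample lower than the minimum (or the signal edge) is met.
min_prominence <- function(x, idx) {
  n <- length(x)
  vapply(idx, function(i) {
    v <- x[i]
    left_high <- v
    j <- i - 1L
    while (j >= 1L && x[j] >= v) {
      if (x[j] > left_high) left_high <- x[j]
      j <- j - 1L
    }
    right_high <- v
    j <- i + 1L
    while (j <= n && x[j] >= v) {
      if (x[j] > right_high) right_high <- x[j]
      j <- j + 1L
    }
    min(left_high, right_high) - v
  }, numeric(1))
}

# Greedy merge of candidate nadirs closer than `refractory`, keeping the
# deeper one (prevents double-counting a noisy nadir).
merge_refractory <- function(times, depths, refractory) {
  keep <- integer(0)
  for (k in seq_along(times)) {
    if (length(keep) && times[k] - times[keep[length(keep)]] < refractory) {
      if (depths[k] < depths[keep[length(keep)]]) keep[length(keep)] <- k
    } else {
      keep <- c(keep, k)
    }
  }
  keep
}

#' Detect spontaneous contractions within a step window
#'
#' The diameter channel is smoothed with a centred moving average; candidate
#' nadirs are local minima of the smoothed trace with topographic prominence
#' of at least `min_amplitude`; candidates closer together than `refractory`
#' are merged keeping the deeper nadir. For each retained event the
#' end-systolic diameter (ESD) is the raw-trace minimum within
#' `+/- nadir_neighborhood` of the smoothed nadir, the onset is the last local
#' maximum of the smoothed trace preceding the nadir, and the end-diastolic
#' diameter (EDD) is the smoothed-trace maximum over the diastolic interval
#' from the previous event's nadir (or the window start) to the onset.
#'
#' A constant (degenerate) trace yields zero events, not an error; a window
#' outside the trace extent is an error.
#'
#' @param trace a `diameter_trace`.
#' @param window a single-row slice of [segment_by_protocol()] output (or any
#'   list with `start_time`, `end_time`, and optionally `pressure`,
#'   `step_index`).
#' @param params a [detection_params()] list.
#' @return A `contraction_events` data frame with columns `onset_time`,
#'   `nadir_time`, `edd`, `esd`, `amplitude`, sorted by `nadir_time`;
#'   attributes `pressure` and `step_index` copied from the window.
#' @export
detect_contractions <- function(trace, window, params = detection_params()) {
  stopifnot(inherits(trace, "diameter_trace"))
  w_start <- as.numeric(window$start_time)
  w_end <- as.numeric(window$end_time)
  sr <- attr(trace, "sample_rate")
  t_lo <- trace$time[1]
  t_hi <- trace$time[nrow(trace)] + 1 / sr
  if (w_start < t_lo - 1e-9 || w_end > t_hi + 1e-9 || w_end <= w_start) {
    stop("window [", w_start, ", ", w_end, ") lies outside the trace extent",
         call. = FALSE)
  }
  sel <- which(trace$time >= w_start & trace$time < w_end)
  tt <- trace$time[sel]
  raw <- trace$diameter[sel]
  k <- round(params$smooth_window * sr)
  if (length(sel) < max(k, 3)) {
    stop("window contains fewer samples than the smoothing width", call. = FALSE)
  }
  sm <- moving_average(raw, k)

  cand <- local_extrema(sm, minima = TRUE)
  empty <- data.frame(onset_time = numeric(0), nadir_time = numeric(0),
                      edd = numeric(0), esd = numeric(0), amplitude = numeric(0))
  finish <- function(ev) {
    ev <- ev[order(ev$nadir_time), , drop = FALSE]
    rownames(ev) <- NULL
    attr(ev, "pressure") <- if (!is.null(window$pressure)) as.numeric(window$pressure) else NA_real_
    attr(ev, "step_index") <- if (!is.null(window$step_index)) as.integer(window$step_index) else NA_integer_
    attr(ev, "window_start") <- w_start
    attr(ev, "window_end") <- w_end
    class(ev) <- c("contraction_events", "data.frame")
    ev
  }
  if (!length(cand)) return(finish(empty))
  prom <- min_prominence(sm, cand)
  cand <- cand[prom >= params$min_amplitude]
  if (!length(cand)) return(finish(empty))
  cand <- cand[merge_refractory(tt[cand], sm[cand], params$refractory)]

  maxima <- local_extrema(sm, minima = FALSE)
  nb <- round(params$nadir_neighborhood * sr)
  n_ev <- length(cand)
  onset_time <- nadir_time <- edd <- esd <- numeric(n_ev)
  for (e in seq_len(n_ev)) {
    i <- cand[e]
    lo <- max(1L, i - nb)
    hi <- min(length(raw), i + nb)
    j <- lo - 1L + which.min(raw[lo:hi])
    esd[e] <- raw[j]
    nadir_time[e] <- tt[j]
    prev_max <- maxima[maxima < i]
    onset_idx <- if (length(prev_max)) prev_max[length(prev_max)] else 1L
    dia_lo <- if (e > 1L) cand[e - 1L] else 1L
    edd[e] <- max(sm[dia_lo:onset_idx])
    onset_time[e] <- min(tt[onset_idx], nadir_time[e] - 1 / sr)
  }
  ev <- data.frame(onset_time = onset_time, nadir_time = nadir_time,
                   edd = edd, esd = esd, amplitude = edd - esd)
  ev <- ev[ev$amplitude >= params$min_amplitude, , drop = FALSE]
  # raw-nadir relocation can nudge times; re-assert the refractory contract
  if (nrow(ev) > 1L) {
    ev <- ev[order(ev$nadir_time), , drop = FALSE]
    ev <- ev[merge_refractory(ev$nadir_time, ev$esd, params$refractory), , drop = FALSE]
  }
  finish(ev)
}

#' Per-contraction (instantaneous) frequencies
#'
#' Contraction frequency computed on a contraction-by-contraction basis:
#' for events with nadirs at t_1 < ... < t_n, the i-th instantaneous frequency
#' is 60 / (t_i - t_(i-1)) per minute, giving n - 1 values.
#'
#' @param events a `contraction_events` data frame (sorted by nadir time).
#' @return Numeric vector of length `max(nrow(events) - 1, 0)`, in min^-1.
#' @export
instantaneous_frequencies <- function(events) {
  tn <- events$nadir_time
  if (is.null(tn)) stop("`events` must have a nadir_time column", call. = FALSE)
  if (length(tn) <= 1L) return(numeric(0))
  if (is.unsorted(tn, strictly = TRUE)) {
    stop("events must be sorted by nadir_time", call. = FALSE)
  }
  60 / diff(tn)
}

#' Average contraction frequency over a step window
#'
#' Zero events give frequency 0 (the zero-frequency case is meaningful and is
#' propagated, not dropped). A single event gives count/duration — one
#' contraction per window length. With two or more events the step frequency
#' is the arithmetic mean of the instantaneous frequencies.
#'
#' @param events a `contraction_events` data frame.
#' @param window window with `start_time` and `end_time` (s).
#' @return Frequency in min^-1.
#' @export
step_frequency <- function(events, window) {
  dur_min <- (as.numeric(window$end_time) - as.numeric(window$start_time)) / 60
  if (dur_min <= 0) stop("window duration must be positive", call. = FALSE)
  n <- nrow(events)
  if (n == 0L) return(0)
  if (n == 1L) return(1 / dur_min)
  mean(instantaneous_frequencies(events))
}
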
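#' Pressure grid used by genotype presets
#'
#' The seven distinct pressures of the default protocol, in ascending order.
#' @return Numeric vector `c(0.5, 1, 2, 3, 5, 8, 10)` (cmH2O).
#' @export
preset_pressures <- function() c(0.5, 1, 2, 3, 5, 8, 10)

#' Maximal passive diameter curve
#'
#' `DMAX(P) = d_lo + (d_hi - d_lo) * P / (P + p_half)`: a saturating
#' pressure-diameter relation rising from `d_lo` toward `d_hi` with
#' half-saturation pressure `p_half`.
#'
#' @param curve numeric vector `c(d_lo, d_hi, p_half)` (um, um, cmH2O).
#' @param pressure pressure(s) in cmH2O.
#' @return DMAX in um.
#' @export
dmax_curve_at <- function(curve, pressure) {
  curve <- as.numeric(curve)
  curve[1] + (curve[2] - curve[1]) * pressure / (pressure + curve[3])
}

#' Derive per-pressure mean frequencies from slope/deltaF anchors
#'
#' Constructs mean contraction frequencies on the preset pressure grid such
#' that (i) the OLS slope of frequency on pressure over {0.5, 1, 2, 3, 5}
#' equals `target_slope`, (ii) `f(5) - f(0.5)` equals `target_deltaF`,
#' (iii) `f(0.5)` and `f(10)` equal the supplied anchors, and (iv) the
#' sequence is monotone non-decreasing up to 5 cmH2O and plateaus at
#' `f(8) = f(10)` (frequency plateaus above 5 cmH2O). The three interior
#' frequencies are found by minimum-curvature interpolation: the sum of
#' squared second divided differences at P = 1, 2, 3 is minimized subject to
#' the slope constraint (an equality-constrained least-squares problem solved
#' via its KKT system). When the anchors are exactly linear-compatible
#' (`target_deltaF = 4.5 * target_slope`) the result is the exact line.
#'
#' @param target_slope F-P slope over 0.5-5 cmH2O (min^-1 cmH2O^-1).
#' @param target_deltaF `f(5) - f(0.5)` (min^-1).
#' @param f_lo frequency anchor at 0.5 cmH2O (min^-1).
#' @param f_hi frequency anchor at 10 cmH2O (min^-1).
#' @return Named numeric vector of mean frequencies on [preset_pressures()].
#' @export
derive_preset_frequencies <- function(target_slope, target_deltaF, f_lo, f_hi) {
  if (f_lo < 0 || f_hi < 0) {
    stop("infeasible: frequency anchors must be non-negative", call. = FALSE)
  }
  if (target_deltaF < 0) {
    stop("infeasible: target_deltaF must be non-negative for a ",
         "non-decreasing frequency profile", call. = FALSE)
  }
  f5 <- f_lo + target_deltaF
  if (f5 > f_hi + 1e-9) {
    stop("infeasible: f(5) = f(0.5) + deltaF exceeds the f(10) anchor, ",
         "violating the plateau constraint f(5) <= f(10)", call. = FALSE)
  }
  # minimize ||A x - b||^2 over x = (f(1), f(2), f(3)) s.t. c'x = b_c,
  # rows of A x - b = second divided differences at P = 1, 2, 3
  A <- rbind(c(-3, 1, 0), c(1, -2, 1), c(0, 1, -1.5))
  b <- c(-2 * f_lo, 0, -0.5 * f5)
  P_fit <- c(0.5, 1, 2, 3, 5)
  d <- P_fit - mean(P_fit)
  Sxx <- sum(d^2)
  cc <- d[2:4]
  b_c <- target_slope * Sxx - d[1] * f_lo - d[5] * f5
  K <- rbind(cbind(2 * crossprod(A), cc), c(cc, 0))
  sol <- solve(K, c(2 * crossprod(A, b), b_c))
  f <- c(f_lo, sol[1:3], f5, f_hi, f_hi)
  if (any(diff(f[1:5]) < -1e-9)) {
    stop("infeasible: the requested slope/deltaF combination requires a ",
         "non-monotone frequency profile over 0.5-5 cmH2O", call. = FALSE)
  }
  if (any(f < -1e-9)) {
    stop("infeasible: derived frequencies would be negative", call. = FALSE)
  }
  f <- pmax(f, 0)
  names(f) <- as.character(preset_pressures())
  f
}

#' Construct a genotype/treatment preset for the trace simulator
#'
#' A preset holds the generative parameters for one condition: mean
#' contraction frequency, mean amplitude and tone at each pressure of the
#' preset grid, the passive-diameter curve, the inter-contraction-interval
#' coefficient of variation, measurement noise, and the contraction waveform
#' timing (systolic descent duration, diastolic refill time constant).
#'
#' @param name condition label.
#' @param freq_by_pressure named numeric: mean frequency (min^-1) at each of
#'   [preset_pressures()]; typically from [derive_preset_frequencies()].
#' @param amp_by_pressure named numeric: mean contraction amplitude (um) at
#'   each grid pressure.
#' @param tone_by_pressure named numeric: tone (%, in `[0, 100)`) at each grid
#'   pressure; the diastolic diameter is `EDD(P) = (1 - tone/100) * DMAX(P)`.
#' @param dmax_curve `c(d_lo, d_hi, p_half)`, see [dmax_curve_at()].
#' @param interval_cv coefficient of variation of the gamma-distributed
#'   inter-contraction intervals (default 0.2, near-regular pacemaking).
#' @param noise_sd additive Gaussian measurement noise, um (default 0.6).
#' @param systole_s duration of the raised-cosine systolic descent, s.
#' @param refill_s time constant of the exponential diastolic refill, s.
#' @return A `genotype_preset` list.
#' @export
genotype_preset <- function(name, freq_by_pressure, amp_by_pressure,
                            tone_by_pressure,
                            dmax_curve = c(d_lo = 80, d_hi = 115, p_half = 2),
                            interval_cv = 0.2, noise_sd = 0.6,
                            systole_s = 1.5, refill_s = 2.5) {
  grid <- preset_pressures()
  getmap <- function(m, what) {
    if (length(m) == 1L) m <- rep(m, length(grid))
    if (length(m) != length(grid)) {
      stop("`", what, "` must give one value per grid pressure", call. = FALSE)
    }
    m <- as.numeric(m)
    names(m) <- as.character(grid)
    m
  }
  freq <- getmap(freq_by_pressure, "freq_by_pressure")
  amp <- getmap(amp_by_pressure, "amp_by_pressure")
  tone <- getmap(tone_by_pressure, "tone_by_pressure")
  if (any(freq < 0)) stop("frequencies must be >= 0", call. = FALSE)
  if (any(amp < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (any(tone < 0 | tone >= 100)) stop("tone must lie in [0, 100)", call. = FALSE)
  if (interval_cv <= 0 || noise_sd < 0 || systole_s <= 0 || refill_s <= 0) {
    stop("interval_cv, systole_s, refill_s must be positive; noise_sd >= 0",
         call. = FALSE)
  }
  edd <- (1 - tone / 100) * dmax_curve_at(dmax_curve, grid)
  if (any(edd - amp <= 0)) {
    stop("preset implies non-positive end-systolic diameter ",
         "(EDD(P) must exceed amplitude at every pressure)", call. = FALSE)
  }
  structure(list(name = name, freq_by_pressure = freq, amp_by_pressure = amp,
                 tone_by_pressure = tone, dmax_curve = as.numeric(dmax_curve),
                 interval_cv = interval_cv, noise_sd = noise_sd,
                 systole_s = systole_s, refill_s = refill_s),
            class = "genotype_preset")
}

#' @export
print.genotype_preset <- function(x, ...) {
  cat(sprintf("<genotype_preset '%s'>\n", x$name))
  print(rbind(`freq (min^-1)` = round(x$freq_by_pressure, 2),
              `amp (um)` = x$amp_by_pressure,
              `tone (%)` = x$tone_by_pressure))
  invisible(x)
}

preset_value_at <- function(map, pressure) {
  i <- which(abs(preset_pressures() - pressure) <= 1e-9)
  if (!length(i)) {
    stop("pressure ", pressure, " cmH2O is not on the preset grid", call. = FALSE)
  }
  unname(map[i])
}

#' Shipped genotype/treatment presets
#'
#' Seven presets whose frequency profiles are produced by
#' [derive_preset_frequencies()] from the condition-mean F-P slope anchors:
#' wild type (slope 2.8, deltaF 12.1, frequencies rising from 2 to 20 min^-1),
#' wild type + 1 uM Ani9 (ANO1 inhibitor; slope 0.3), smooth-muscle *Ano1*
#' knockout (slope 0.4, frequencies below 3 min^-1 at all pressures) and its
#' floxed control (slope 2.8), smooth-muscle *Itpr1* knockout (slope 0.6) and
#' its floxed control (slope 2.6), and global *Trpv4* knockout (slope 2.7).
#' For conditions whose deltaF is not anchored separately, the profile is the
#' exact line (`deltaF = 4.5 * slope`). Amplitude and tone profiles, and the
#' passive-diameter scale, are plausible invented defaults shared across
#' presets (amplitudes 35-50 um, tone 4-18%, DMAX 80-115 um); no analysis
#' target depends on them.
#'
#' @return Named list of `genotype_preset` objects.
#' @export
preset_registry <- function() {
  amp <- c(35, 40, 45, 50, 50, 45, 40)
  tone <- c(4, 6, 8, 10, 14, 16, 18)
  mk <- function(name, slope, deltaF, f_lo, f_hi) {
    genotype_preset(name, derive_preset_frequencies(slope, deltaF, f_lo, f_hi),
                    amp, tone)
  }
  list(
    WT         = mk("WT", 2.8, 12.1, 2, 20),
    WT_Ani9    = mk("WT_Ani9", 0.3, 4.5 * 0.3, 1, 2.5),
    Ano1_smKO  = mk("Ano1_smKO", 0.4, 4.5 * 0.4, 0.5, 2.5),
    Ano1_ff    = mk("Ano1_ff", 2.8, 4.5 * 2.8, 2, 20),
    Itpr1_smKO = mk("Itpr1_smKO", 0.6, 4.5 * 0.6, 1, 4),
    Itpr1_ff   = mk("Itpr1_ff", 2.6, 4.5 * 2.6, 2, 19),
    Trpv4_KO   = mk("Trpv4_KO", 2.7, 4.5 * 2.7, 2, 19.5)
  )
}

get_preset <- function(preset) {
  if (inherits(preset, "genotype_preset")) return(preset)
  reg <- preset_registry()
  if (is.character(preset) && preset %in% names(reg)) return(reg[[preset]])
  stop("unknown preset: ", preset, " (see names(preset_registry()))",
       call. = FALSE)
}

# Gamma renewal event (nadir) times on [0, duration), started at time 0.
draw_nadir_times <- function(freq, duration, cv) {
  if (freq <= 0) return(numeric(0))
  m <- 60 / freq
  shape <- 1 / cv^2
  times <- numeric(0)
  last <- 0
  repeat {
    n_draw <- ceiling((duration - last) / m + 6 * sqrt((duration - last) / m) + 10)
    iv <- stats::rgamma(n_draw, shape = shape, scale = m / shape)
    new <- last + cumsum(iv)
    times <- c(times, new)
    last <- times[length(times)]
    if (last >= duration) break
  }
  times[times < duration]
}

#' Simulate one active pressure-myography recording
#'
#' Generates a diameter trace following the protocol: within each step the
#' vessel sits at its diastolic diameter `EDD(P) = (1 - tone(P)/100) *
#' DMAX(P)`; contraction nadir times form a gamma renewal process with mean
#' interval `60 / f(P)` and coefficient of variation `interval_cv`
#' (no events where `f(P) = 0`); each contraction descends from EDD to
#' `ESD = EDD - amp(P)` along a raised cosine over `systole_s`, then refills
#' exponentially toward EDD with time constant `refill_s` (interrupted by the
#' next contraction). Pressure channels follow the protocol exactly with
#' inflow = outflow. Gaussian measurement noise of sd `noise_sd` is added
#' unless `noiseless`. Fixing `seed` makes the trace bit-reproducible.
#'
#' The ground-truth event table (step, pressure, onset/nadir times, EDD, ESD)
#' is attached as `attr(trace, "truth")`; the simulator never calls the
#' detection or fitting code.
#'
#' @param preset a `genotype_preset` or the name of a shipped preset.
#' @param protocol a `pressure_protocol` (default [default_protocol()]).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param vessel_id,condition labels; `condition` defaults to the preset name.
#' @param noiseless logical; omit measurement noise.
#' @param sample_rate Hz (default 30).
#' @return A `diameter_trace` with attribute `truth`.
#' @export
simulate_vessel <- function(preset, protocol = default_protocol(), seed = NULL,
                            vessel_id = "sim", condition = NULL,
                            noiseless = FALSE, sample_rate = 30) {
  preset <- get_preset(preset)
  run <- function() simulate_vessel_impl(preset, protocol, vessel_id,
                                         condition %||% preset$name,
                                         noiseless, sample_rate)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

simulate_vessel_impl <- function(preset, protocol, vessel_id, condition,
                                 noiseless, sr) {
  total <- protocol_duration(protocol)
  n_total <- round(total * sr)
  time <- (seq_len(n_total) - 1L) / sr
  diam <- numeric(n_total)
  pin <- numeric(n_total)
  ends <- cumsum(protocol$duration)
  starts <- c(0, ends[-length(ends)])
  truth <- vector("list", nrow(protocol))
  for (s in seq_len(nrow(protocol))) {
    P <- protocol$pressure[s]
    dur <- protocol$duration[s]
    i0 <- round(starts[s] * sr) + 1L
    i1 <- round(ends[s] * sr)
    idx <- i0:i1
    t_loc <- time[idx] - starts[s]
    edd <- (1 - preset_value_at(preset$tone_by_pressure, P) / 100) *
      dmax_curve_at(preset$dmax_curve, P)
    amp <- preset_value_at(preset$amp_by_pressure, P)
    esd <- edd - amp
    f <- preset_value_at(preset$freq_by_pressure, P)
    d <- rep(edd, length(idx))
    nadirs <- if (amp > 0) draw_nadir_times(f, dur, preset$interval_cv) else numeric(0)
    if (length(nadirs)) {
      onsets <- pmax(nadirs - preset$systole_s, c(0, nadirs[-length(nadirs)]))
      bounds <- c(onsets[-1], dur)  # refill runs until next onset or step end
      for (k in seq_along(nadirs)) {
        sys_sel <- t_loc >= onsets[k] & t_loc <= nadirs[k]
        d[sys_sel] <- edd - amp / 2 *
          (1 - cos(pi * (t_loc[sys_sel] - onsets[k]) / (nadirs[k] - onsets[k])))
        ref_sel <- t_loc > nadirs[k] & t_loc < bounds[k]
        d[ref_sel] <- esd + (edd - esd) *
          (1 - exp(-(t_loc[ref_sel] - nadirs[k]) / preset$refill_s))
      }
    }
    diam[idx] <- d
    pin[idx] <- P
    n_ev <- length(nadirs)
    truth[[s]] <- data.frame(
      step_index = rep(s, n_ev), pressure = rep(P, n_ev),
      onset_time = starts[s] + (if (n_ev) onsets else numeric(0)),
      nadir_time = starts[s] + nadirs,
      edd = rep(edd, n_ev), esd = rep(esd, n_ev))
  }
  if (!noiseless && preset$noise_sd > 0) {
    diam <- diam + stats::rnorm(n_total, 0, preset$noise_sd)
  }
  tr <- diameter_trace(time, diam, pin, pin, sample_rate = sr,
                       vessel_id = vessel_id, condition = condition,
                       is_passive = FALSE)
  attr(tr, "truth") <- do.call(rbind, truth)
  tr
}

#' Simulate a passive (Ca2+-free) recording
#'
#' With no active tone the vessel tracks its maximal passive diameter: the
#' trace is `DMAX(P)` per the preset's passive curve at each protocol step,
#' plus measurement noise, with no contractions and `is_passive = TRUE`.
#'
#' @inheritParams simulate_vessel
#' @return A passive `diameter_trace`.
#' @export
simulate_passive <- function(preset, protocol = default_protocol(), seed = NULL,
                             vessel_id = "sim_passive", condition = NULL,
                             noiseless = FALSE, sample_rate = 30) {
  preset <- get_preset(preset)
  run <- function() {
    total <- protocol_duration(protocol)
    n_total <- round(total * sample_rate)
    time <- (seq_len(n_total) - 1L) / sample_rate
    ends <- cumsum(protocol$duration)
    starts <- c(0, ends[-length(ends)])
    step_of <- findInterval(time, starts)
    P <- protocol$pressure[step_of]
    diam <- dmax_curve_at(preset$dmax_curve, P)
    if (!noiseless && preset$noise_sd > 0) {
      diam <- diam + stats::rnorm(n_total, 0, preset$noise_sd)
    }
    diameter_trace(time, diam, P, P, sample_rate = sample_rate,
                   vessel_id = vessel_id,
                   condition = condition %||% preset$name, is_passive = TRUE)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a cohort of vessels plus one passive recording
#'
#' Per-vessel seeds are drawn reproducibly from `seed`, so the whole
#' experiment is a deterministic function of (preset, protocol, n, seed).
#'
#' @inheritParams simulate_vessel
#' @param n_vessels number of active vessels to simulate.
#' @return A list with `traces` (list of `diameter_trace`) and `passive`
#'   (one passive `diameter_trace`).
#' @export
simulate_experiment <- function(preset, n_vessels, seed,
                                protocol = default_protocol(),
                                noiseless = FALSE, sample_rate = 30) {
  preset <- get_preset(preset)
  seeds <- withr::with_seed(seed,
                            sample.int(.Machine$integer.max - 1L, n_vessels + 1L))
  traces <- lapply(seq_len(n_vessels), function(i) {
    simulate_vessel(preset, protocol, seed = seeds[i],
                    vessel_id = sprintf("%s_v%02d", preset$name, i),
                    noiseless = noiseless, sample_rate = sample_rate)
  })
  passive <- simulate_passive(preset, protocol, seed = seeds[n_vessels + 1L],
                              vessel_id = sprintf("%s_passive", preset$name),
                              noiseless = noiseless, sample_rate = sample_rate)
  list(traces = traces, passive = passive)
}

#' Ground-truth contraction times without waveform synthesis
#'
#' Draws the gamma renewal event times for every protocol step — the same
#' stochastic layer that drives [simulate_vessel()] — without rendering the
#' 30 Hz diameter waveform. Useful for large statistical replication where
#' only event timing matters; the waveform + detection path is validated
#' separately to reproduce these times.
#'
#' @inheritParams simulate_vessel
#' @return Data frame `step_index`, `pressure`, `nadir_time` (s from recording
#'   start).
#' @export
simulate_events <- function(preset, protocol = default_protocol(), seed = NULL) {
  preset <- get_preset(preset)
  run <- function() {
    ends <- cumsum(protocol$duration)
    starts <- c(0, ends[-length(ends)])
    rows <- lapply(seq_len(nrow(protocol)), function(s) {
      f <- preset_value_at(preset$freq_by_pressure, protocol$pressure[s])
      nd <- draw_nadir_times(f, protocol$duration[s], preset$interval_cv)
      data.frame(step_index = rep(s, length(nd)),
                 pressure = rep(protocol$pressure[s], length(nd)),
                 nadir_time = starts[s] + nd)
    })
    do.call(rbind, rows)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
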
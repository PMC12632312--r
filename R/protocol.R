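#' Construct a pressure-step protocol
#'
#' A protocol is an ordered sequence of intraluminal pressure steps applied to
#' a cannulated vessel, with inflow and outflow pressure held equal (no imposed
#' axial gradient). Each step has a hold duration; the leading `settle` portion
#' of every step is excluded from analysis windows (see
#' [segment_by_protocol()]).
#'
#' @param pressures numeric vector of step pressures (cmH2O, all > 0).
#' @param durations numeric vector of step durations (s, all > 0); recycled if
#'   length 1.
#' @param name label for the protocol.
#' @return A `pressure_protocol`: a data frame with columns `pressure` and
#'   `duration`, one row per step, in application order.
#' @seealso [default_protocol()], [segment_by_protocol()]
#' @export
pressure_protocol <- function(pressures, durations, name = "custom") {
  stopifnot(length(pressures) >= 1)
  if (length(durations) == 1L) durations <- rep(durations, length(pressures))
  if (length(durations) != length(pressures)) {
    stop("`pressures` and `durations` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(pressures)) || any(pressures <= 0)) {
    stop("step pressures must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(durations)) || any(durations <= 0)) {
    stop("step durations must be positive and finite", call. = FALSE)
  }
  out <- data.frame(pressure = as.numeric(pressures),
                    duration = as.numeric(durations))
  attr(out, "name") <- name
  class(out) <- c("pressure_protocol", "data.frame")
  out
}

#' Default pressure-step protocol
#'
#' The standard ex vivo assessment sequence: 3, 2, 1, 0.5, 3, 5, 8 and
#' 10 cmH2O, held 120 s each except 300 s at 0.5 cmH2O, where several minutes
#' may be needed to capture multiple contractions of a slowly beating vessel.
#' Note the protocol visits 3 cmH2O twice; [fit_fp()] reconciles the duplicate.
#'
#' @return A `pressure_protocol` with 8 steps (1140 s total).
#' @export
default_protocol <- function() {
  p <- c(3, 2, 1, 0.5, 3, 5, 8, 10)
  pressure_protocol(p, ifelse(p == 0.5, 300, 120), name = "default")
}

#' Total protocol duration in seconds
#' @param protocol a `pressure_protocol`.
#' @return numeric scalar (s).
#' @export
protocol_duration <- function(protocol) {
  stopifnot(inherits(protocol, "pressure_protocol"))
  sum(protocol$duration)
}

#' Read a protocol from a YAML or JSON file
#'
#' The file holds a list of records with fields `pressure_cmH2O` and
#' `duration_s` (YAML list or JSON array).
#'
#' @param path file path (`.yaml`/`.yml`/`.json`).
#' @param name optional label; defaults to the file name.
#' @return A `pressure_protocol`.
#' @export
read_protocol <- function(path, name = NULL) {
  if (!file.exists(path)) stop("protocol file not found: ", path, call. = FALSE)
  steps <- yaml::read_yaml(path)  # yaml is a superset of JSON
  if (!length(steps)) stop("protocol file lists no steps", call. = FALSE)
  get_field <- function(s, f) {
    if (is.null(s[[f]])) stop("protocol step missing field `", f, "`", call. = FALSE)
    as.numeric(s[[f]])
  }
  pressure_protocol(
    vapply(steps, get_field, numeric(1), f = "pressure_cmH2O"),
    vapply(steps, get_field, numeric(1), f = "duration_s"),
    name = if (is.null(name)) basename(path) else name
  )
}

#' Write a protocol to a YAML file
#' @param protocol a `pressure_protocol`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "pressure_protocol"))
  steps <- lapply(seq_len(nrow(protocol)), function(i) {
    list(pressure_cmH2O = protocol$pressure[i], duration_s = protocol$duration[i])
  })
  yaml::write_yaml(steps, path)
  invisible(path)
}

#' @export
print.pressure_protocol <- function(x, ...) {
  cat(sprintf("<pressure_protocol '%s'> %d steps, %g s total\n",
              attr(x, "name"), nrow(x), sum(x$duration)))
  cat("  pressures (cmH2O):", paste(x$pressure, collapse = ", "), "\n")
  invisible(x)
}
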
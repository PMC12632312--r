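#' Fit the frequency-pressure (F-P) relationship of one vessel
#'
#' Pressure-induced chronotropy is quantified by an ordinary least-squares
#' first-order fit of step-average contraction frequency against intraluminal
#' pressure over the range where the response is near-linear
#' (0.5-5 cmH2O by default; frequency tends to plateau above 5 cmH2O, so
#' higher pressures are excluded from the fit but kept in summary plots).
#' Pressures visited more than once (the default protocol holds 3 cmH2O
#' twice) are reconciled before fitting according to `dup_policy`. Zero
#' frequencies are real observations and enter the fit as 0; they are never
#' dropped.
#'
#' Conventions for degenerate input: when the (averaged) frequencies have zero
#' variance the slope is 0, the intercept is the common frequency, and r2 —
#' mathematically undefined — is reported as 0.
#'
#' @param summaries a `step_summary` data frame (or any data frame with
#'   `pressure` and `freq` columns) for one vessel.
#' @param p_min,p_max fit range in cmH2O (defaults 0.5 and 5, inclusive).
#' @param dup_policy how to reconcile repeated pressures: `"mean"` (default),
#'   `"first"` or `"last"` visit.
#' @return An `fp_fit` list: `slope` (min^-1 cmH2O^-1), `intercept` (min^-1),
#'   `r2`, `deltaF` (min^-1, `NA` if 0.5 or 5 cmH2O is absent),
#'   `pressures_used`, `n_points`.
#' @export
fit_fp <- function(summaries, p_min = 0.5, p_max = 5,
                   dup_policy = c("mean", "first", "last")) {
  dup_policy <- match.arg(dup_policy)
  if (is.null(summaries$pressure) || is.null(summaries$freq)) {
    stop("`summaries` must have pressure and freq columns", call. = FALSE)
  }
  dat <- collapse_duplicates(summaries, dup_policy)
  dat <- dat[dat$pressure >= p_min & dat$pressure <= p_max, , drop = FALSE]
  if (nrow(dat) < 3L) {
    stop("need at least 3 distinct pressures in [", p_min, ", ", p_max,
         "] cmH2O to fit the F-P relationship (got ", nrow(dat), ")",
         call. = FALSE)
  }
  if (stats::var(dat$freq) == 0) {
    slope <- 0; intercept <- dat$freq[1]; r2 <- 0
  } else {
    fit <- stats::lm(freq ~ pressure, data = dat)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum((dat$freq - mean(dat$freq))^2)
  }
  dF <- tryCatch(delta_f(summaries, dup_policy = dup_policy),
                 error = function(e) NA_real_)
  structure(list(slope = slope, intercept = intercept, r2 = r2, deltaF = dF,
                 pressures_used = dat$pressure, n_points = nrow(dat)),
            class = "fp_fit")
}

collapse_duplicates <- function(summaries, dup_policy) {
  dat <- data.frame(pressure = summaries$pressure, freq = summaries$freq)
  pick <- switch(dup_policy,
                 mean = function(v) mean(v),
                 first = function(v) v[1],
                 last = function(v) v[length(v)])
  agg <- stats::aggregate(list(freq = dat$freq), list(pressure = dat$pressure), pick)
  agg[order(agg$pressure), , drop = FALSE]
}

#' Frequency difference between 5 and 0.5 cmH2O
#'
#' deltaF = FREQ(5) - FREQ(0.5). A frequency ratio across the same range is
#' undefined whenever a vessel is silent at 0.5 cmH2O (ratio of infinity);
#' the difference stays finite, which is why it is the reported alternative to
#' the slope.
#'
#' @inheritParams fit_fp
#' @param p_low,p_high the two endpoint pressures (defaults 0.5 and 5 cmH2O).
#' @return deltaF in min^-1.
#' @export
delta_f <- function(summaries, p_low = 0.5, p_high = 5,
                    dup_policy = c("mean", "first", "last")) {
  dup_policy <- match.arg(dup_policy)
  dat <- collapse_duplicates(summaries, dup_policy)
  f_at <- function(p) {
    i <- which(abs(dat$pressure - p) <= 1e-9)
    if (!length(i)) {
      stop("summaries lack the ", p, " cmH2O endpoint needed for deltaF",
           call. = FALSE)
    }
    dat$freq[i]
  }
  f_at(p_high) - f_at(p_low)
}

#' Flag questionable F-P fits for review
#'
#' Linear fits over 0.5-5 cmH2O are normally of high quality; a fit with low
#' r2 or a negative slope (inverted F-P relation) deserves manual review.
#' Flags never alter the fit itself.
#'
#' @param fit an `fp_fit`.
#' @param r2_floor minimum acceptable r2 (default 0.7).
#' @return A list with `pass` (logical), `flags` (character vector, possibly
#'   empty: `"low linearity"`, `"inverted F-P"`), and `message`.
#' @export
fit_quality_report <- function(fit, r2_floor = 0.7) {
  stopifnot(inherits(fit, "fp_fit"))
  flags <- character(0)
  if (fit$r2 < r2_floor) flags <- c(flags, "low linearity")
  if (fit$slope < 0) flags <- c(flags, "inverted F-P")
  list(pass = length(flags) == 0L,
       flags = flags,
       message = if (length(flags)) {
         sprintf("fit flagged for review: %s (slope=%.3g, r2=%.3f)",
                 paste(flags, collapse = ", "), fit$slope, fit$r2)
       } else {
         sprintf("fit ok (slope=%.3g, r2=%.3f)", fit$slope, fit$r2)
       })
}

#' @export
print.fp_fit <- function(x, ...) {
  cat(sprintf(
    "<fp_fit> slope %.3f min^-1 cmH2O^-1, intercept %.3f, r2 %.3f, deltaF %s (n=%d)\n",
    x$slope, x$intercept, x$r2,
    if (is.na(x$deltaF)) "NA" else sprintf("%.3f", x$deltaF), x$n_points))
  invisible(x)
}
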
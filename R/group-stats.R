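#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for `m` simultaneous tests; with `m = 1` the raw
#' p-value is returned unchanged.
#'
#' @param p raw p-value(s) in `[0, 1]`.
#' @param m number of simultaneous comparisons (positive integer).
#' @return Adjusted p-value(s).
#' @export
sidak_adjust <- function(p, m) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  if (any(m < 1)) stop("`m` must be a positive integer", call. = FALSE)
  1 - (1 - p)^m
}

#' Significance stars
#'
#' The conventional rendering: `****` p<0.0001, `***` p<0.001, `**` p<0.01,
#' `*` p<0.05, `n.s.` otherwise.
#'
#' @param p p-value(s).
#' @return Character vector of star labels.
#' @export
signif_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "n.s.")) |> as.character()
}

new_group_comparison <- function(test_name, groups, statistic, df, p_value,
                                 posthoc = NULL, notes = character(0)) {
  structure(list(test_name = test_name, groups = groups, statistic = statistic,
                 df = df, p_value = p_value, posthoc = posthoc, notes = notes),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s\n", x$test_name))
  cat(sprintf("  statistic = %.4g, df = %s, p = %.4g %s\n", x$statistic,
              paste(signif(x$df, 4), collapse = ", "), x$p_value,
              signif_stars(x$p_value)))
  if (!is.null(x$posthoc)) {
    cat("  post hoc:\n")
    print(x$posthoc, row.names = FALSE)
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Unpaired two-tailed t-test on F-P slopes
#'
#' Compares per-vessel chronotropy slopes between two groups with the
#' unpaired, two-tailed Student t-test (pooled variance,
#' `df = n1 + n2 - 2`). Welch's unequal-variance form is available behind
#' `welch = TRUE`.
#'
#' @param group_a,group_b numeric vectors of per-vessel slopes (each n >= 2).
#' @param labels length-2 character vector naming the groups.
#' @param welch logical; use Welch's t instead of the pooled form.
#' @return A `group_comparison` with `statistic` (t), `df`, `p_value`.
#' @export
slopes_ttest <- function(group_a, group_b, labels = c("A", "B"), welch = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 vessels", call. = FALSE)
  }
  ht <- stats::t.test(group_a, group_b, var.equal = !welch)
  new_group_comparison(
    test_name = if (welch) "Welch two-sample t-test (two-tailed)"
                else "unpaired two-tailed t-test (pooled variance)",
    groups = stats::setNames(c(length(group_a), length(group_b)), labels),
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value)
}

# Two-sided Dunnett many-to-one adjusted p for a vector of t statistics,
# via the equicorrelated multivariate t distribution (numerical integration
# through mvtnorm, seeded for the quasi-Monte-Carlo error term).
dunnett_p_adjust <- function(t_stats, n_treat, n_control, df, seed = 1) {
  rho <- outer(sqrt(n_treat / (n_treat + n_control)),
               sqrt(n_treat / (n_treat + n_control)))
  diag(rho) <- 1
  vapply(abs(t_stats), function(tt) {
    inside <- withr::with_seed(seed, mvtnorm::pmvt(
      lower = rep(-tt, length(t_stats)), upper = rep(tt, length(t_stats)),
      df = as.integer(df), corr = rho))
    max(0, min(1, 1 - as.numeric(inside)))
  }, numeric(1))
}

#' One-way ANOVA with Dunnett's many-to-one post hoc
#'
#' Compares three or more groups of per-vessel slopes against a designated
#' control: one-way ANOVA F-test, then Dunnett-adjusted two-sided p-values
#' for each non-control group versus the control, computed from the
#' equicorrelated multivariate-t distribution (numerical integration; the
#' evaluation method is recorded in the output notes).
#'
#' @param groups named list of numeric slope vectors (>= 3 groups).
#' @param control name of the control group (must be in `names(groups)`).
#' @param seed integer seed for the multivariate-t evaluation.
#' @return A `group_comparison`: ANOVA `statistic` (F), `df` (c(between,
#'   within)), `p_value`, and a `posthoc` table with one row per non-control
#'   group (`comparison`, `t`, `p_raw`, `p_adj`, `stars`).
#' @export
slopes_anova_dunnett <- function(groups, control, seed = 1) {
  if (length(groups) < 3) stop("need at least 3 groups", call. = FALSE)
  if (!control %in% names(groups)) {
    stop("control group '", control, "' not found", call. = FALSE)
  }
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("each group needs at least 2 vessels", call. = FALSE)
  }
  dat <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1))),
                   levels = names(groups)))
  fit <- stats::aov(value ~ group, data = dat)
  atab <- stats::anova(fit)
  mse <- atab[["Mean Sq"]][2]
  df_err <- atab[["Df"]][2]
  trt <- setdiff(names(groups), control)
  n0 <- length(groups[[control]])
  m0 <- mean(groups[[control]])
  n_t <- vapply(groups[trt], length, integer(1))
  t_stats <- vapply(trt, function(g) {
    (mean(groups[[g]]) - m0) / sqrt(mse * (1 / length(groups[[g]]) + 1 / n0))
  }, numeric(1))
  p_raw <- 2 * stats::pt(abs(t_stats), df_err, lower.tail = FALSE)
  p_adj <- dunnett_p_adjust(t_stats, n_t, n0, df_err, seed = seed)
  p_adj <- pmax(p_adj, p_raw)  # adjustment can never fall below the raw p
  posthoc <- data.frame(comparison = paste(trt, "vs", control),
                        t = t_stats, p_raw = p_raw, p_adj = p_adj,
                        stars = signif_stars(p_adj))
  new_group_comparison(
    test_name = "one-way ANOVA with Dunnett post hoc",
    groups = vapply(groups, length, integer(1)),
    statistic = atab[["F value"]][1], df = atab[["Df"]],
    p_value = atab[["Pr(>F)"]][1], posthoc = posthoc,
    notes = "Dunnett p: equicorrelated multivariate t, numerical integration (mvtnorm, seeded)")
}

#' Repeated-measures ANOVA across pressures with Sidak post hoc
#'
#' Two-way repeated-measures ANOVA on a per-vessel, per-pressure contractile
#' parameter (factors: group, pressure; pressure repeated within vessel),
#' followed by per-pressure group contrasts (pooled-variance t-tests against
#' the control group) with Sidak adjustment over the number of pressures
#' tested. Vessels missing any pressure are dropped (complete-case analysis;
#' the number dropped is recorded in the notes).
#'
#' @param table data frame with columns `vessel_id`, `group`, `pressure`,
#'   `value`.
#' @param control control group label; defaults to the first group level.
#' @return A `group_comparison`: `statistic`/`df`/`p_value` for the group main
#'   effect, `posthoc` rows per pressure x non-control group with Sidak-
#'   adjusted p, and `effects` (group, pressure, interaction p-values) in
#'   `notes`-adjacent field `effects`.
#' @export
pressurewise_rm_anova_sidak <- function(table, control = NULL) {
  need <- c("vessel_id", "group", "pressure", "value")
  if (!all(need %in% names(table))) {
    stop("`table` needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  table$group <- factor(table$group)
  if (is.null(control)) control <- levels(table$group)[1]
  if (!control %in% levels(table$group)) {
    stop("control group '", control, "' not found", call. = FALSE)
  }
  pressures <- sort(unique(table$pressure))
  m <- length(pressures)
  # complete cases: vessels observed (non-missing) at every pressure
  ok <- !is.na(table$value)
  counts <- table(table$vessel_id[ok])
  complete <- names(counts)[counts == m]
  n_dropped <- length(unique(table$vessel_id)) - length(complete)
  dat <- table[ok & table$vessel_id %in% complete, , drop = FALSE]
  dat$pressure_f <- factor(dat$pressure)
  dat$vessel_id <- factor(dat$vessel_id)
  per_group <- tapply(as.character(dat$vessel_id), dat$group,
                      function(v) length(unique(v)))
  if (any(is.na(per_group)) || any(per_group < 2)) {
    stop("fewer than 2 complete vessels in some group after dropping ",
         "incomplete cases", call. = FALSE)
  }
  fit <- stats::aov(value ~ group * pressure_f + Error(vessel_id),
                    data = dat)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: vessel_id"]][[1]])
  within <- as.data.frame(sm[["Error: Within"]][[1]])
  grp_row <- grep("^group", trimws(rownames(between)))[1]
  effects <- c(group = between[["Pr(>F)"]][grp_row],
               pressure = within[["Pr(>F)"]][grep("^pressure_f$", trimws(rownames(within)))],
               interaction = within[["Pr(>F)"]][grep("group:pressure_f", trimws(rownames(within)))])
  trt <- setdiff(levels(dat$group), control)
  posthoc <- do.call(rbind, lapply(pressures, function(p) {
    do.call(rbind, lapply(trt, function(g) {
      a <- dat$value[dat$pressure == p & dat$group == g]
      b <- dat$value[dat$pressure == p & dat$group == control]
      ht <- stats::t.test(a, b, var.equal = TRUE)
      data.frame(pressure = p, comparison = paste(g, "vs", control),
                 t = unname(ht$statistic), p_raw = ht$p.value,
                 p_adj = sidak_adjust(ht$p.value, m))
    }))
  }))
  posthoc$stars <- signif_stars(posthoc$p_adj)
  out <- new_group_comparison(
    test_name = "two-way repeated-measures ANOVA with Sidak post hoc",
    groups = per_group,
    statistic = between[["F value"]][grp_row],
    df = c(between[["Df"]][grp_row], between[["Df"]][nrow(between)]),
    p_value = effects[["group"]], posthoc = posthoc,
    notes = c(sprintf("%d incomplete vessel(s) dropped (complete-case analysis)",
                      n_dropped),
              sprintf("Sidak adjustment over m = %d pressures", m)))
  out$effects <- effects
  out
}
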
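# Deterministic raised-cosine dip train: baseline diameter with n_dips
# symmetric dips of given depth and total width, centred every `spacing` s.
make_dip_trace <- function(baseline = 100, depth = 40, n_dips = 5,
                           spacing = 20, dip_width = 3, total = NULL,
                           sr = 30, noise_sd = 0, seed = NULL,
                           pressure = 3, is_passive = FALSE, ...) {
  if (is.null(total)) total <- spacing * (n_dips + 1)
  time <- (seq_len(round(total * sr)) - 1) / sr
  d <- rep(baseline, length(time))
  centers <- spacing * seq_len(n_dips)
  for (ct in centers) {
    sel <- abs(time - ct) <= dip_width / 2
    d[sel] <- baseline - depth / 2 * (1 + cos(2 * pi * (time[sel] - ct) / dip_width))
  }
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) rnorm(length(d), 0, noise_sd) else
      withr::with_seed(seed, rnorm(length(d), 0, noise_sd))
    d <- d + noise
  }
  tr <- diameter_trace(time, d, rep(pressure, length(time)),
                       sample_rate = sr, is_passive = is_passive, ...)
  attr(tr, "dip_centers") <- centers
  tr
}

window_for <- function(trace, pressure = 3, step_index = 1L) {
  data.frame(step_index = step_index, pressure = pressure,
             start_time = trace$time[1],
             end_time = trace$time[nrow(trace)] + 1 / attr(trace, "sample_rate"))
}

events_df <- function(nadir_time, edd = 100, esd = 60, onset_time = nadir_time - 1) {
  n <- length(nadir_time)
  ev <- data.frame(onset_time = onset_time, nadir_time = nadir_time,
                   edd = rep_len(edd, n), esd = rep_len(esd, n),
                   amplitude = rep_len(edd - esd, n))
  class(ev) <- c("contraction_events", "data.frame")
  ev
}

# Toy single-cell fixture: `n_pass` well-behaved cells plus one violator of
# each QC criterion. 600 real genes + 13 mitochondrial genes.
toy_counts <- function(n_pass = 6, seed = 11) {
  withr::with_seed(seed, {
    genes <- c(paste0("g", seq_len(600)), paste0("mt-", seq_len(13)))
    mk_cell <- function(n_genes_expr, total, mito_frac = 0.02) {
      counts <- numeric(length(genes))
      mito_total <- round(total * mito_frac)
      body_genes <- sample(600, n_genes_expr)
      # every selected gene gets at least one count, so genes-detected is exact
      counts[body_genes] <- 1 + as.numeric(
        stats::rmultinom(1, total - mito_total - n_genes_expr,
                         rep(1, n_genes_expr)))
      counts[600 + sample(13, 3)] <- as.numeric(
        stats::rmultinom(1, mito_total, rep(1, 3)))
      counts
    }
    cells <- lapply(seq_len(n_pass), function(i) mk_cell(520, 2000))
    cells <- c(cells, list(
      high_mito = mk_cell(520, 2000, mito_frac = 0.25),   # >10% mito
      few_genes = mk_cell(100, 1500),                      # <500 genes
      few_umis = mk_cell(520, 800),                        # <1000 UMIs
      doublet = mk_cell(520, 2000)                         # doublet score 0.8
    ))
    m <- do.call(cbind, cells)
    rownames(m) <- genes
    colnames(m) <- c(sprintf("pass%02d", seq_len(n_pass)),
                     "high_mito", "few_genes", "few_umis", "doublet")
    dbl <- stats::setNames(rep(0.1, ncol(m)), colnames(m))
    dbl["doublet"] <- 0.8
    clusters <- stats::setNames(rep(c("LMC", "LEC"), length.out = ncol(m)),
                                colnames(m))
    count_matrix(m, clusters = clusters, doublet_score = dbl)
  })
}
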
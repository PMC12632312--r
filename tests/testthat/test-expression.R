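test_that("QC filter removes exactly the constructed violators", {
  mat <- toy_counts(n_pass = 6)
  res <- qc_filter_cells(mat)
  expect_equal(res$report$n_input, 10)
  expect_equal(res$report$n_kept, 6)
  expect_equal(res$report$fail_mito, 1)
  expect_equal(res$report$fail_genes, 1)
  expect_equal(res$report$fail_umis, 1)
  expect_equal(res$report$fail_doublet, 1)
  expect_setequal(res$matrix$cells$barcode, sprintf("pass%02d", 1:6))

  # exhaustive per-cell re-check straight from the raw counts
  counts <- mat$counts
  mito <- grepl("^mt-", rownames(counts))
  for (j in seq_len(ncol(counts))) {
    v <- counts[, j]
    expected_keep <- (100 * sum(v[mito]) / sum(v) <= 10) &&
      (sum(v > 0) >= 500) && (sum(v) >= 1000) &&
      (mat$cells$doublet_score[j] < 0.5)
    expect_identical(unname(res$keep[j]), expected_keep,
                     label = colnames(counts)[j])
  }
})

test_that("QC filter is idempotent and drops zero-sum genes", {
  mat <- toy_counts()
  once <- qc_filter_cells(mat)
  twice <- qc_filter_cells(once$matrix)
  expect_equal(twice$report$n_kept, once$report$n_kept)
  expect_equal(twice$report$genes_dropped, 0)
  expect_identical(dim(twice$matrix$counts), dim(once$matrix$counts))
  # no gene with zero total count survives
  expect_true(all(Matrix::rowSums(once$matrix$counts) > 0))
  # all-passing matrix: identity on cells
  clean <- qc_filter_cells(once$matrix)
  expect_identical(clean$matrix$cells$barcode, once$matrix$cells$barcode)
  # extreme thresholds remove nothing
  lax <- qc_filter_cells(mat, qc_thresholds(max_mito_pct = 100, min_genes = 0,
                                            min_umis = 0, doublet_cutoff = 2))
  expect_equal(lax$report$n_kept, 10)
})

test_that("doublet criterion direction is switchable and logged", {
  mat <- toy_counts()
  conv <- qc_filter_cells(mat)
  expect_match(conv$report$notes[1], ">=")
  expect_false("doublet" %in% conv$matrix$cells$barcode)
  inv <- qc_filter_cells(mat, doublet_remove_high = FALSE)
  expect_match(inv$report$notes[1], "<")
  expect_true("doublet" %in% inv$matrix$cells$barcode)
  # without scores the criterion is skipped and logged
  noscore <- count_matrix(as.matrix(mat$counts),
                          clusters = setNames(mat$cells$cluster,
                                              mat$cells$barcode))
  res <- qc_filter_cells(noscore)
  expect_match(paste(res$report$notes, collapse = ";"), "skipped")
  expect_equal(res$report$fail_doublet, 0)
})

test_that("dot-plot statistics count expressing cells per cluster", {
  m <- rbind(Ano1 = c(3, 1, 2, 0, 0, 0, 0, 0),
             Acta2 = c(5, 4, 6, 7, 0, 0, 0, 0),
             Other = c(1, 1, 1, 1, 5, 5, 5, 5))
  colnames(m) <- paste0("c", 1:8)
  cl <- setNames(rep(c("LMC", "LEC"), each = 4), colnames(m))
  mat <- count_matrix(m, clusters = cl)
  st <- dotplot_stats(mat, "Ano1", "Acta2")
  lmc <- st[st$cluster == "LMC", ]
  lec <- st[st$cluster == "LEC", ]
  expect_equal(lmc$pct_expressing, 75)   # 3 of 4 cells
  expect_equal(lec$pct_expressing, 0)
  expect_equal(lec$rel_level, 0)
  expect_true(lec$ref_zero)
  expect_gt(lmc$rel_level, 0)
  # manual recomputation of the normalized means for the LMC cluster
  umis <- colSums(m)[1:4]
  mg <- mean(log1p(m["Ano1", 1:4] / umis * 1e4))
  mr <- mean(log1p(m["Acta2", 1:4] / umis * 1e4))
  expect_equal(lmc$mean_norm_expr, mg, tolerance = 1e-12)
  expect_equal(lmc$rel_level, mg / mr, tolerance = 1e-12)
  expect_error(dotplot_stats(mat, "Nope", "Acta2"), "not found")
})

test_that("dot-plot statistics respect their scaling invariances", {
  m <- rbind(Ano1 = c(3, 1, 2, 0), Acta2 = c(5, 4, 6, 7),
             Other = c(2, 0, 4, 1))
  colnames(m) <- paste0("c", 1:4)
  cl <- setNames(rep("LMC", 4), colnames(m))
  base <- dotplot_stats(count_matrix(m, clusters = cl), "Ano1", "Acta2")
  # global count scaling never changes percent expressing
  scaled <- dotplot_stats(count_matrix(m * 5, clusters = cl), "Ano1", "Acta2")
  expect_equal(scaled$pct_expressing, base$pct_expressing)
  # per-cell library-size scaling leaves rel_level unchanged by construction
  libscaled <- sweep(m, 2, c(2, 3, 1, 4), `*`)
  rel2 <- dotplot_stats(count_matrix(libscaled, clusters = cl), "Ano1", "Acta2")
  expect_equal(rel2$rel_level, base$rel_level, tolerance = 1e-12)
})

test_that("percent expressing tracks a binomial generating probability", {
  # an LMC-like cluster with expression probability 0.8 for the gene:
  # the detected percent should agree with the generator within CLT bounds
  # (and in particular exceed 75%)
  n <- 400
  withr::with_seed(77, {
    expr <- rbinom(n, 1, 0.8) * rpois(n, 3)
    m <- rbind(Ano1 = expr, Acta2 = rpois(n, 5) + 1, Pad = rpois(n, 2))
    colnames(m) <- paste0("c", seq_len(n))
    mat <- count_matrix(m, clusters = setNames(rep("LMC", n), colnames(m)))
  })
  st <- dotplot_stats(mat, "Ano1", "Acta2")
  p_obs <- st$pct_expressing / 100
  p_true <- 0.8 * (1 - exp(-3))  # zero-inflation from the Poisson counts
  expect_lt(abs(p_obs - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
  expect_gt(st$pct_expressing, 70)
})

test_that("MTX triplet and dense CSV readers agree", {
  mat <- toy_counts(n_pass = 3)
  dir <- withr::local_tempdir()
  Matrix::writeMM(mat$counts, file.path(dir, "matrix.mtx"))
  writeLines(colnames(mat$counts), file.path(dir, "barcodes.tsv"))
  write.table(data.frame(id = rownames(mat$counts),
                         symbol = rownames(mat$counts)),
              file.path(dir, "features.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  from_mtx <- read_count_matrix(dir)
  expect_equal(as.matrix(from_mtx$counts), as.matrix(mat$counts))

  csv <- withr::local_tempfile(fileext = ".csv")
  dense <- as.matrix(mat$counts)
  write.csv(data.frame(gene = rownames(dense), dense, check.names = FALSE),
            csv, row.names = FALSE)
  from_csv <- read_count_matrix(csv)
  expect_equal(as.matrix(from_csv$counts), dense)
  expect_equal(from_csv$cells$n_umis, unname(colSums(dense)))
  expect_equal(from_csv$cells$n_genes, unname(colSums(dense > 0)))
})
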
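#' Assemble a cells-by-genes count matrix container
#'
#' Wraps a sparse gene x cell count matrix (genes in rows, cell barcodes in
#' columns, the 10x convention) together with per-cell annotations. The
#' derived annotations — genes detected, total UMIs, percent mitochondrial —
#' are always recomputed from the counts; cluster labels and doublet scores
#' are supplied externally.
#'
#' @param counts a matrix or `Matrix::dgCMatrix` of non-negative integer
#'   counts with rownames (gene symbols) and colnames (cell barcodes).
#' @param clusters optional named vector (by barcode) or vector in column
#'   order of cluster labels.
#' @param doublet_score optional named/ordered numeric vector of per-cell
#'   doublet scores.
#' @param mito_pattern regex identifying mitochondrial genes from their
#'   symbols (default `"^mt-"`, the mouse convention).
#' @return A `count_matrix` list: `counts` (dgCMatrix), `cells` (data frame:
#'   `barcode`, `cluster`, `n_genes`, `n_umis`, `pct_mito`, `doublet_score`).
#' @export
count_matrix <- function(counts, clusters = NULL, doublet_score = NULL,
                         mito_pattern = "^mt-") {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "dMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene rownames and barcode colnames", call. = FALSE)
  }
  bc <- colnames(counts)
  align <- function(v, what) {
    if (is.null(v)) return(rep(NA, length(bc)))
    if (!is.null(names(v))) {
      if (!all(bc %in% names(v))) {
        stop("`", what, "` does not cover every barcode", call. = FALSE)
      }
      v <- v[bc]
    } else if (length(v) != length(bc)) {
      stop("`", what, "` must be named by barcode or given in column order",
           call. = FALSE)
    }
    unname(v)
  }
  n_umis <- Matrix::colSums(counts)
  mito <- grepl(mito_pattern, rownames(counts))
  cells <- data.frame(
    barcode = bc,
    cluster = as.character(align(clusters, "clusters")),
    n_genes = Matrix::colSums(counts > 0),
    n_umis = n_umis,
    pct_mito = ifelse(n_umis > 0,
                      100 * Matrix::colSums(counts[mito, , drop = FALSE]) / n_umis,
                      0),
    doublet_score = as.numeric(align(doublet_score, "doublet_score")))
  structure(list(counts = counts, cells = cells), class = "count_matrix")
}

#' Read a count matrix from an MTX triplet directory or dense CSV
#'
#' `path` may be a directory holding `matrix.mtx`, `barcodes.tsv` and
#' `features.tsv` (genes in rows), or a dense CSV with genes in rows
#' (first column = gene symbol) and barcodes as the header.
#'
#' @param path directory or CSV file.
#' @param ... passed to [count_matrix()].
#' @return A `count_matrix`.
#' @export
read_count_matrix <- function(path, ...) {
  if (dir.exists(path)) {
    m <- Matrix::readMM(file.path(path, "matrix.mtx"))
    bc <- readLines(file.path(path, "barcodes.tsv"))
    feat <- utils::read.delim(file.path(path, "features.tsv"), header = FALSE)
    rownames(m) <- feat[[if (ncol(feat) >= 2) 2 else 1]]
    colnames(m) <- bc
  } else {
    dat <- utils::read.csv(path, check.names = FALSE)
    m <- as.matrix(dat[, -1, drop = FALSE])
    rownames(m) <- dat[[1]]
  }
  count_matrix(m, ...)
}

#' Cell-QC thresholds
#'
#' Defaults follow the standard low-quality-cell filter: more than 10%
#' mitochondrial counts, fewer than 500 detected genes, fewer than 1,000
#' UMIs, or a doublet score at/above 0.5.
#'
#' @param max_mito_pct maximum percent mitochondrial counts (default 10).
#' @param min_genes minimum genes detected (default 500).
#' @param min_umis minimum total UMIs (default 1000).
#' @param doublet_cutoff doublet-score cutoff (default 0.5).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(max_mito_pct = 10, min_genes = 500, min_umis = 1000,
                          doublet_cutoff = 0.5) {
  vals <- c(max_mito_pct = max_mito_pct, min_genes = min_genes,
            min_umis = min_umis, doublet_cutoff = doublet_cutoff)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("thresholds must be non-negative", call. = FALSE)
  }
  structure(as.list(vals), class = "qc_thresholds")
}

#' Filter low-quality cells and non-expressed genes
#'
#' Removes every cell failing any criterion — mito% above `max_mito_pct`,
#' fewer than `min_genes` genes detected, fewer than `min_umis` UMIs, or
#' doublet score at/above `doublet_cutoff` — then drops genes with zero total
#' count across the retained cells. The doublet criterion follows the
#' conventional direction (high score = likely doublet = removed);
#' `doublet_remove_high = FALSE` inverts it (remove scores below the cutoff),
#' and the direction used is recorded in the report. Cells with no doublet
#' score are not subject to that criterion (logged).
#'
#' Filtering is idempotent: applying the same filter to its own output
#' removes nothing further.
#'
#' @param mat a `count_matrix`.
#' @param thresholds a [qc_thresholds()] list.
#' @param doublet_remove_high logical; see above.
#' @return A list with `matrix` (filtered `count_matrix`), `keep` (logical
#'   vector over input cells) and `report` (cells failing each criterion,
#'   cells removed, genes dropped, notes).
#' @export
qc_filter_cells <- function(mat, thresholds = qc_thresholds(),
                            doublet_remove_high = TRUE) {
  stopifnot(inherits(mat, "count_matrix"), inherits(thresholds, "qc_thresholds"))
  cells <- mat$cells
  fail_mito <- cells$pct_mito > thresholds$max_mito_pct
  fail_genes <- cells$n_genes < thresholds$min_genes
  fail_umis <- cells$n_umis < thresholds$min_umis
  notes <- sprintf("doublet criterion: remove score %s %.3g",
                   if (doublet_remove_high) ">=" else "<",
                   thresholds$doublet_cutoff)
  if (all(is.na(cells$doublet_score))) {
    fail_doublet <- rep(FALSE, nrow(cells))
    notes <- c(notes, "no doublet scores supplied; criterion skipped")
  } else {
    fail_doublet <- if (doublet_remove_high) {
      cells$doublet_score >= thresholds$doublet_cutoff
    } else {
      cells$doublet_score < thresholds$doublet_cutoff
    }
    fail_doublet[is.na(fail_doublet)] <- FALSE
  }
  keep <- !(fail_mito | fail_genes | fail_umis | fail_doublet)
  kept <- mat$counts[, keep, drop = FALSE]
  gene_keep <- Matrix::rowSums(kept) > 0
  filtered <- count_matrix(kept[gene_keep, , drop = FALSE],
                           clusters = stats::setNames(cells$cluster, cells$barcode)[keep],
                           doublet_score = stats::setNames(cells$doublet_score,
                                                           cells$barcode)[keep])
  list(matrix = filtered, keep = keep,
       report = list(
         n_input = nrow(cells), n_kept = sum(keep),
         fail_mito = sum(fail_mito), fail_genes = sum(fail_genes),
         fail_umis = sum(fail_umis), fail_doublet = sum(fail_doublet),
         genes_dropped = sum(!gene_keep), notes = notes))
}

# log-normalized expression: log1p(counts-per-10k)
norm_expr <- function(mat) {
  umis <- mat$cells$n_umis
  x <- mat$counts
  x@x <- x@x / rep.int(pmax(umis, 1), diff(x@p)) * 1e4
  x@x <- log1p(x@x)
  x
}

#' Per-cluster dot-plot statistics for a gene
#'
#' For each cluster: the percent of cells expressing the gene (count > 0 —
#' the dot size of a standard dot plot) and the mean normalized expression
#' (`log1p(count / total UMIs * 1e4)`) expressed relative to a reference gene
#' (the dot colour), i.e. `rel_level = mean_norm_expr(gene) /
#' mean_norm_expr(ref_gene)` within the cluster. When the reference mean is 0
#' in a cluster, `rel_level` is reported as 0 and flagged.
#'
#' @param mat a `count_matrix` with cluster labels.
#' @param gene gene symbol of interest.
#' @param ref_gene reference gene symbol (e.g. a pan-muscle marker).
#' @return Data frame: `cluster`, `n_cells`, `pct_expressing`,
#'   `mean_norm_expr`, `ref_mean_norm_expr`, `rel_level`, `ref_zero` flag.
#' @export
dotplot_stats <- function(mat, gene, ref_gene) {
  stopifnot(inherits(mat, "count_matrix"))
  for (g in c(gene, ref_gene)) {
    if (!g %in% rownames(mat$counts)) {
      stop("gene not found in matrix: ", g, call. = FALSE)
    }
  }
  cl <- mat$cells$cluster
  if (all(is.na(cl))) stop("count_matrix carries no cluster labels", call. = FALSE)
  nx <- norm_expr(mat)
  g_counts <- mat$counts[gene, ]
  g_norm <- nx[gene, ]
  r_norm <- nx[ref_gene, ]
  out <- do.call(rbind, lapply(sort(unique(cl)), function(k) {
    sel <- which(cl == k)
    mg <- mean(g_norm[sel])
    mr <- mean(r_norm[sel])
    data.frame(cluster = k, n_cells = length(sel),
               pct_expressing = 100 * mean(g_counts[sel] > 0),
               mean_norm_expr = mg, ref_mean_norm_expr = mr,
               rel_level = if (mr > 0) mg / mr else 0,
               ref_zero = mr == 0)
  }))
  rownames(out) <- NULL
  out
}
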
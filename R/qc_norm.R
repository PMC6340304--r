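#' Quality-control thresholds for single cells
#'
#' Cells failing any rule are removed; all comparisons are strict, so a cell
#' sitting exactly on a threshold is retained.
#'
#' @param min_total_reads minimum total unique reads per cell (removal when
#'   total < this; default 100000).
#' @param min_genes_detected minimum genes with nonzero count (removal when
#'   detected < this; default 1000).
#' @param max_sparsity maximum fraction of zero-count genes in a cell (removal
#'   when sparsity > this; default 0.95).
#' @param max_gene_zero_fraction gene filter: a gene is removed when its
#'   zero-count fraction across retained cells exceeds this (default 0.95).
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_total_reads = 100000, min_genes_detected = 1000,
                          max_sparsity = 0.95, max_gene_zero_fraction = 0.95) {
  stopifnot(min_total_reads >= 0, min_genes_detected >= 0,
            max_sparsity >= 0, max_sparsity <= 1,
            max_gene_zero_fraction >= 0, max_gene_zero_fraction <= 1)
  structure(list(min_total_reads = min_total_reads,
                 min_genes_detected = min_genes_detected,
                 max_sparsity = max_sparsity,
                 max_gene_zero_fraction = max_gene_zero_fraction),
            class = "qc_thresholds")
}

#' Per-cell quality metrics
#'
#' Total reads, genes detected, sparsity (fraction of genes at zero), and the
#' fraction of counts attributable to technical (ERCC-like) control genes when
#' any are flagged. The technical fraction is reported but never used as a
#' removal filter.
#'
#' @param counts a [count_matrix()].
#' @return data.frame with one row per cell: `unit_id`, `total_reads`,
#'   `genes_detected`, `sparsity`, and `ercc_fraction` if technical genes are
#'   flagged.
#' @export
compute_cell_qc <- function(counts) {
  m <- counts$counts
  qc <- data.frame(unit_id = colnames(m),
                   total_reads = colSums(m),
                   genes_detected = colSums(m > 0),
                   sparsity = colMeans(m == 0),
                   stringsAsFactors = FALSE, row.names = NULL)
  tech <- counts$gene_meta$is_technical
  if (any(tech)) {
    tot <- qc$total_reads
    qc$ercc_fraction <- ifelse(tot > 0, colSums(m[tech, , drop = FALSE]) / tot, NA_real_)
  }
  qc
}

#' Remove poor-quality cells
#'
#' A cell is removed iff `total_reads < min_total_reads` OR
#' `genes_detected < min_genes_detected` OR `sparsity > max_sparsity`
#' (strict comparisons). The removal report lists every removed cell with the
#' rule(s) that triggered.
#'
#' @param counts a [count_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return list with `retained` (a `count_matrix`), `report` (data.frame of
#'   removed cells and triggering rules), and `qc` (the full metric table).
#' @export
filter_cells <- function(counts, thresholds = qc_thresholds()) {
  qc <- compute_cell_qc(counts)
  low_reads <- qc$total_reads < thresholds$min_total_reads
  low_genes <- qc$genes_detected < thresholds$min_genes_detected
  high_sparsity <- qc$sparsity > thresholds$max_sparsity
  removed <- low_reads | low_genes | high_sparsity
  rules <- vapply(seq_len(nrow(qc)), function(i) {
    paste(c("low_total_reads", "low_genes_detected", "high_sparsity")[
      c(low_reads[i], low_genes[i], high_sparsity[i])], collapse = ";")
  }, character(1))
  report <- data.frame(unit_id = qc$unit_id[removed],
                       rules = rules[removed],
                       stringsAsFactors = FALSE, row.names = NULL)
  if (all(removed)) warning("empty-result: all cells removed by QC filters")
  list(retained = subset_count_matrix(counts, units = which(!removed)),
       report = report, qc = qc)
}

#' Remove genes with near-ubiquitous dropout
#'
#' A gene is removed iff its zero-count fraction across (already QC-filtered)
#' cells strictly exceeds `max_gene_zero_fraction`. Technical (ERCC-like)
#' control genes are exempt and always retained, since they are needed for the
#' technical mean-variance trend downstream.
#'
#' @param counts a [count_matrix()] of QC-passing cells.
#' @param max_gene_zero_fraction default 0.95.
#' @return a `count_matrix` with the sparse genes removed.
#' @export
filter_genes <- function(counts, max_gene_zero_fraction = 0.95) {
  zero_frac <- rowMeans(counts$counts == 0)
  keep <- zero_frac <= max_gene_zero_fraction | counts$gene_meta$is_technical
  subset_count_matrix(counts, genes = which(keep))
}

#' Pool-deconvolution size factors
#'
#' Cell-specific size factors estimated by summing counts over pools of cells
#' and deconvolving the pooled factors. Cells are placed on a ring ordered by
#' library size; for every pool of consecutive cells (all rotations, each pool
#' size), the pooled count vector is compared against the average pseudo-cell
#' by the median ratio over genes with positive pseudo-cell expression. Each
#' pool yields one linear equation (the sum of member-cell factors equals the
#' pool's median ratio, on the scale where factors average 1); the
#' overdetermined system is solved by least squares and factors are rescaled
#' to geometric mean 1. Pooling cancels the zero-inflation that biases
#' per-cell median ratios.
#'
#' Technical (ERCC-like) genes are excluded from estimation: spike-ins do not
#' scale with cell content. Non-positive least-squares solutions trigger a
#' non-negative refit; cells still degenerate after that fall back to
#' library-size factors (with a warning).
#'
#' @param counts a [count_matrix()] of QC-filtered cells and genes.
#' @param pool_sizes integer pool sizes; default the subsequence of
#'   (21, 41, 61, 81, 101) not exceeding the cell count, with a floor of
#'   `min(21, n_cells)`.
#' @return list of class `size_factors` with `unit_ids` and `factors`
#'   (positive, geometric mean 1).
#' @export
deconvolution_size_factors <- function(counts, pool_sizes = NULL) {
  m <- counts$counts[!counts$gene_meta$is_technical, , drop = FALSE]
  n <- ncol(m)
  if (is.null(pool_sizes)) {
    pool_sizes <- c(21, 41, 61, 81, 101)
    pool_sizes <- pool_sizes[pool_sizes <= n]
    if (length(pool_sizes) == 0) pool_sizes <- min(21L, n)
  }
  if (n < min(pool_sizes))
    stop("insufficient-cells: ", n, " cells but smallest pool is ", min(pool_sizes))

  lib <- colSums(m)
  if (any(lib <= 0)) stop("cells with zero library size cannot be normalized")
  ring <- order(lib)                       # ring ordered by library size
  ref <- rowMeans(m)                       # average pseudo-cell
  pos <- ref > 0
  mr <- m[pos, ring, drop = FALSE]
  refp <- ref[pos]

  # one equation per (pool size, rotation): sum of member factors = median ratio
  n_eq <- length(pool_sizes) * n
  A <- matrix(0, n_eq, n)
  b <- numeric(n_eq)
  row <- 0L
  # pooled counts for consecutive ring windows via cumulative sums
  cs <- cbind(0, t(apply(mr, 1, cumsum)))
  for (k in pool_sizes) {
    for (start in seq_len(n)) {
      row <- row + 1L
      idx <- ((start - 1L):(start + k - 2L)) %% n + 1L
      if (start + k - 1L <= n) {
        pooled <- cs[, start + k] - cs[, start]
      } else {
        pooled <- (cs[, n + 1] - cs[, start]) + cs[, (start + k - 1L) %% n + 1L]
      }
      A[row, ring[idx]] <- 1
      b[row] <- stats::median(pooled / refp)
    }
  }
  # low-weight anchor on library-size factors for identifiability of small systems
  lib_fac <- lib / mean(lib)
  w <- 0.01
  A <- rbind(A, diag(w, n))
  b <- c(b, w * lib_fac)

  fac <- stats::lm.fit(A, b)$coefficients
  if (any(!is.finite(fac) | fac <= 0)) {
    fit <- pracma::lsqnonneg(A, b)
    fac <- fit$x
    bad <- fac <= 0 | !is.finite(fac)
    if (any(bad)) {
      warning("library-size fallback for ", sum(bad), " cell(s) with degenerate factors")
      fac[bad] <- lib_fac[bad]
    }
  }
  fac <- fac / exp(mean(log(fac)))         # geometric mean 1
  structure(list(unit_ids = colnames(m), factors = unname(fac)),
            class = "size_factors")
}

#' Library-size factors (total-count normalization)
#'
#' Baseline comparator for the deconvolution estimator.
#'
#' @param counts a [count_matrix()].
#' @return a `size_factors` object, geometric mean 1.
#' @export
library_size_factors <- function(counts) {
  m <- counts$counts[!counts$gene_meta$is_technical, , drop = FALSE]
  lib <- colSums(m)
  if (any(lib <= 0)) stop("cells with zero library size cannot be normalized")
  fac <- lib / exp(mean(log(lib)))
  structure(list(unit_ids = colnames(m), factors = unname(fac)),
            class = "size_factors")
}

#' Size-factor normalization and log2 transform
#'
#' `value(g, c) = log2(count(g, c) / factor(c) + offset)`.
#'
#' @param counts a [count_matrix()].
#' @param size_factors a `size_factors` object aligned to the matrix units.
#' @param offset pseudo-count, default 1.
#' @return object of class `normalized_matrix` with `values` (log2 scale),
#'   `linear` (size-factor-normalized counts), `offset`, `size_factors`, and
#'   the gene/unit metadata carried over.
#' @export
normalize_log2 <- function(counts, size_factors, offset = 1) {
  if (!identical(size_factors$unit_ids, colnames(counts$counts)))
    stop("alignment error: size-factor unit ids do not match matrix units")
  if (any(size_factors$factors <= 0)) stop("size factors must be positive")
  linear <- sweep(counts$counts, 2, size_factors$factors, "/")
  structure(list(values = log2(linear + offset), linear = linear,
                 offset = offset, size_factors = size_factors,
                 unit_meta = counts$unit_meta, gene_meta = counts$gene_meta),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "units (log2, offset", x$offset, ")\n")
  invisible(x)
}
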
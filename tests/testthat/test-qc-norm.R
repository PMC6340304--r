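test_that("per-cell QC metrics equal brute-force tallies", {
  set.seed(3)
  m <- matrix(rpois(100 * 5, 2), 100, 5,
              dimnames = list(paste0("g", 1:100), paste0("c", 1:5)))
  m[, 1] <- 0                      # all-zero cell
  m[, 2] <- 1                      # every gene detected
  cm <- count_matrix(m, gene_meta = data.frame(is_technical = c(rep(TRUE, 10),
                                                                rep(FALSE, 90))))
  qc <- compute_cell_qc(cm)
  expect_equal(qc$total_reads[1], 0)
  expect_equal(qc$genes_detected[1], 0)
  expect_equal(qc$sparsity[1], 1.0)
  expect_equal(qc$sparsity[2], 0.0)
  for (j in 3:5) {
    expect_equal(qc$total_reads[j], sum(m[, j]))
    expect_equal(qc$genes_detected[j], sum(m[, j] > 0))
    expect_equal(qc$sparsity[j], mean(m[, j] == 0))
    expect_equal(qc$ercc_fraction[j], sum(m[1:10, j]) / sum(m[, j]))
  }
})

test_that("cell filters apply the three removal rules with strict boundaries", {
  # 5 cells: boundary-retained, low reads, low genes, high sparsity, all-zero
  n_genes <- 2000
  mk_cell <- function(total, detected) {
    x <- numeric(n_genes)
    if (detected > 0) {
      x[seq_len(detected)] <- 1
      x[1] <- total - (detected - 1)
    }
    x
  }
  m <- cbind(boundary = mk_cell(100000, 1200),   # exactly at thresholds: kept
             lowreads = mk_cell(99999, 1200),
             lowgenes = mk_cell(100000, 999),
             sparse = mk_cell(100000, 99),       # sparsity 0.9505 > 0.95
             zero = mk_cell(0, 0))
  rownames(m) <- paste0("g", seq_len(n_genes))
  cm <- count_matrix(m)
  fc <- filter_cells(cm)
  expect_identical(colnames(fc$retained$counts), "boundary")
  expect_setequal(fc$report$unit_id, c("lowreads", "lowgenes", "sparse", "zero"))
  zero_rules <- fc$report$rules[fc$report$unit_id == "zero"]
  expect_match(zero_rules, "low_total_reads")
  expect_match(zero_rules, "low_genes_detected")
  expect_match(zero_rules, "high_sparsity")
  expect_equal(fc$report$rules[fc$report$unit_id == "lowreads"], "low_total_reads")
  # idempotent
  fc2 <- filter_cells(fc$retained)
  expect_identical(fc2$retained$counts, fc$retained$counts)
  # removing everything warns rather than errors
  expect_warning(filter_cells(cm, qc_thresholds(min_total_reads = 1e9)),
                 "empty-result")
})

test_that("gene filter removes genes with > 95% zeros, exempting spike-ins", {
  set.seed(4)
  n_cells <- 100
  m <- rbind(dense = rpois(n_cells, 5) + 1,
             at95 = c(rep(1, 5), rep(0, 95)),     # exactly 95%: retained
             at96 = c(rep(1, 4), rep(0, 96)),     # 96% > 95%: removed
             sparse_tech = c(1, rep(0, 99)))
  colnames(m) <- paste0("c", seq_len(n_cells))
  cm <- count_matrix(m, gene_meta = data.frame(
    is_technical = c(FALSE, FALSE, FALSE, TRUE)))
  kept <- filter_genes(cm)
  expect_setequal(rownames(kept$counts), c("dense", "at95", "sparse_tech"))

  m2 <- matrix(rbinom(200 * 50, 1, 0.04), 200, 50,
               dimnames = list(paste0("g", 1:200), paste0("c", 1:50)))
  cm2 <- count_matrix(m2)
  kept2 <- filter_genes(cm2, 0.9)
  expect_setequal(rownames(kept2$counts),
                  rownames(m2)[rowMeans(m2 == 0) <= 0.9])
  # idempotent
  expect_identical(filter_genes(kept2, 0.9)$counts, kept2$counts)
})

test_that("deconvolution factors are exact on constructed cells", {
  # two identical cells
  m <- matrix(rep(c(5, 3, 8, 1, 9, 2, 7, 4, 6, 10), 2), ncol = 2,
              dimnames = list(paste0("g", 1:10), c("a", "b")))
  sf <- deconvolution_size_factors(count_matrix(m))
  expect_equal(sf$factors, c(1, 1), tolerance = 1e-8)

  # cell type B = 2 x cell type A, 40 cells alternating
  set.seed(6)
  a <- rpois(300, 20) + 1
  m2 <- sapply(1:40, function(i) if (i %% 2) a else 2 * a)
  dimnames(m2) <- list(paste0("g", 1:300), paste0("c", 1:40))
  sf2 <- deconvolution_size_factors(count_matrix(m2))
  ratios <- sf2$factors[seq(2, 40, 2)] / sf2$factors[seq(1, 39, 2)]
  expect_equal(ratios, rep(2, 20), tolerance = 1e-6)
  expect_equal(exp(mean(log(sf2$factors))), 1, tolerance = 1e-10)

  expect_error(deconvolution_size_factors(count_matrix(m), pool_sizes = 5),
               "insufficient-cells")
})

test_that("deconvolution recovers lognormal truth on DE-free cells and is scale-equivariant", {
  set.seed(7)
  ng <- 1000; nc <- 200
  mu <- rlnorm(ng, log(20), 1.3)
  truth <- rlnorm(nc, 0, 0.5); truth <- truth / exp(mean(log(truth)))
  m <- matrix(rpois(ng * nc, outer(mu, truth)), ng, nc,
              dimnames = list(paste0("g", 1:ng), paste0("c", 1:nc)))
  est <- deconvolution_size_factors(count_matrix(m))
  expect_gt(cor(est$factors, truth), 0.99)

  # multiplying one cell's counts by c multiplies its factor by c (up to the
  # global geometric-mean rescale)
  m2 <- m; m2[, 1] <- m[, 1] * 3
  est2 <- deconvolution_size_factors(count_matrix(m2))
  rel <- est2$factors / est$factors
  expect_equal(rel[1] / rel[2], 3, tolerance = 0.02)
})

test_that("deconvolution agrees with the scran implementation", {
  set.seed(8)
  ng <- 500; nc <- 100
  mu <- rlnorm(ng, log(15), 1)
  truth <- rlnorm(nc, 0, 0.4)
  m <- matrix(rpois(ng * nc, outer(mu, truth)), ng, nc,
              dimnames = list(paste0("g", 1:ng), paste0("c", 1:nc)))
  ours <- deconvolution_size_factors(count_matrix(m))$factors
  ref <- scran::calculateSumFactors(m)
  ref <- ref / exp(mean(log(ref)))
  expect_gt(cor(ours, ref), 0.995)
})

test_that("log2 normalization matches its definition and invariances", {
  m <- matrix(c(0, 3, 2, 6), 2, 2, dimnames = list(c("ga", "gb"), c("u1", "u2")))
  cm <- count_matrix(m)
  sf <- structure(list(unit_ids = c("u1", "u2"), factors = c(1, 2)),
                  class = "size_factors")
  nm <- normalize_log2(cm, sf, offset = 1)
  expect_equal(nm$values["ga", "u1"], 0)
  expect_equal(nm$values["gb", "u1"], log2(3 / 1 + 1))
  expect_equal(nm$values["gb", "u2"], log2(6 / 2 + 1))
  expect_equal(nm$values["gb", "u1"], log2(4), tolerance = 1e-12)
  expect_equal(log2(3 / 2 + 1), 1.3219, tolerance = 1e-4)

  # doubling all counts and all factors leaves values unchanged
  cm2 <- count_matrix(2 * m)
  sf2 <- structure(list(unit_ids = c("u1", "u2"), factors = 2 * c(1, 2)),
                   class = "size_factors")
  expect_equal(normalize_log2(cm2, sf2)$values, nm$values)

  sf_bad <- structure(list(unit_ids = c("u2", "u1"), factors = c(1, 2)),
                      class = "size_factors")
  expect_error(normalize_log2(cm, sf_bad), "alignment")
})
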
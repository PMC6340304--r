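# Shared fixtures and small oracles, all built in code.

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# Cells drawn around group-specific gene profiles, so rank correlation carries
# the group structure (a constant shift would not).
make_group_profiles <- function(sizes, n_genes = 40, sd = 1, seed = 2) {
  set.seed(seed)
  pats <- lapply(sizes, function(s) rnorm(n_genes, 0, 2))
  v <- do.call(cbind, lapply(seq_along(sizes), function(i)
    pats[[i]] + matrix(rnorm(n_genes * sizes[i], 0, sd), n_genes, sizes[i])))
  dimnames(v) <- list(paste0("g", seq_len(n_genes)),
                      paste0("c", seq_len(sum(sizes))))
  list(values = v, labels = rep(seq_along(sizes), sizes))
}

# Wrap a plain matrix as a normalized_matrix with unit size factors.
as_normed <- function(linear, is_technical = NULL, offset = 1) {
  is_technical <- is_technical %||% rep(FALSE, nrow(linear))
  structure(list(values = log2(linear + offset), linear = linear,
                 offset = offset,
                 size_factors = structure(list(unit_ids = colnames(linear),
                                               factors = rep(1, ncol(linear))),
                                          class = "size_factors"),
                 unit_meta = data.frame(row.names = colnames(linear)),
                 gene_meta = data.frame(is_technical = is_technical,
                                        row.names = rownames(linear))),
            class = "normalized_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-gene rows with exact sample mean mu and exact sample CV^2 (half the
# cells at mu + delta, half at mu - delta).
exact_cv2_matrix <- function(mu, cv2, n_cells) {
  stopifnot(n_cells %% 2 == 0)
  v <- t(vapply(seq_along(mu), function(g) {
    delta <- sqrt(cv2[g] * mu[g]^2 * (n_cells - 1) / n_cells)
    mu[g] + rep(c(delta, -delta), n_cells / 2)
  }, numeric(n_cells)))
  dimnames(v) <- list(paste0("g", seq_along(mu)), paste0("c", seq_len(n_cells)))
  v
}

# Simulated experiment for HVG calibration: Poisson null genes, a planted set
# with 8x-inflated variance, and Poisson ERCC-like controls for the trend.
make_hvg_experiment <- function(n_null = 1900, n_plant = 100, n_tech = 50,
                                n_cells = 100, seed = 11) {
  set.seed(seed)
  mu_null <- rlnorm(n_null, log(40), 1)
  mu_plant <- rlnorm(n_plant, log(40), 1)
  mu_tech <- rlnorm(n_tech, log(40), 1)
  m_null <- matrix(rpois(n_null * n_cells, mu_null), n_null, n_cells)
  alpha <- 7 / mu_plant                 # variance = 8 * Poisson variance
  m_plant <- matrix(rnbinom(n_plant * n_cells, mu = mu_plant, size = 1 / alpha),
                    n_plant, n_cells)
  m_tech <- matrix(rpois(n_tech * n_cells, mu_tech), n_tech, n_cells)
  m <- rbind(m_plant, m_null, m_tech)
  dimnames(m) <- list(c(sprintf("plant%d", seq_len(n_plant)),
                        sprintf("null%d", seq_len(n_null)),
                        sprintf("ERCC-%d", seq_len(n_tech))),
                      sprintf("c%d", seq_len(n_cells)))
  as_normed(m, is_technical = grepl("^ERCC-", rownames(m)))
}

# Brute-force Benjamini-Hochberg from the step-up definition.
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    cand <- p[o][i:n] * n / (i:n)
    q[o[i]] <- min(1, min(cand))
  }
  q
}

# Exhaustive 1-D k-means over all contiguous partitions of the sorted values.
wcss_brute <- function(x, k) {
  n <- length(x)
  xs <- sort(x)
  best <- Inf
  splits <- utils::combn(n - 1, k - 1)
  for (j in seq_len(ncol(splits))) {
    b <- c(0, splits[, j], n)
    w <- 0
    for (i in seq_len(k)) {
      seg <- xs[(b[i] + 1):b[i + 1]]
      w <- w + sum((seg - mean(seg))^2)
    }
    best <- min(best, w)
  }
  best
}

# Standard three-population bulk design: one promiscuous (mTEC-like)
# population against two TRA-silent (DC-like) populations, genes shared with
# a planted atlas.
make_tra_contrast <- function(atlas_seed = 7, bulk_seed = 8, n_genes = 2000) {
  at <- make_tissue_atlas(atlas_spec(n_genes = n_genes, seed = atlas_seed))
  tra_ids <- at$truth$gene_id[at$truth$category == "TRA"]
  bs <- bulk_sim_spec(populations = list(
    list(name = "mTEC", n_replicates = 3, tra_program_on = TRUE,
         tra_expression_level = 30, library_size = 2e6),
    list(name = "cDC", n_replicates = 4, tra_program_on = FALSE,
         library_size = 2e6),
    list(name = "eTAC", n_replicates = 4, tra_program_on = FALSE,
         library_size = 2e6)),
    gene_ids = at$truth$gene_id, tra_gene_ids = tra_ids, seed = bulk_seed)
  list(atlas = at, bulk = make_bulk_populations(bs))
}
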
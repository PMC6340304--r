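# Multiplicative lognormal noise with unit mean and a given CV
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# NB(mean, dispersion alpha) with variance mu + alpha * mu^2; alpha = 0 -> Poisson
rnb <- function(n, mu, alpha) {
  if (alpha == 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, mu = mu, size = 1 / alpha)
}

#' Specification of a synthetic tissue atlas
#'
#' Plants three gene classes over `n_tissue_groups` tissue groups:
#' tissue-restricted genes expressed in `tra_breadth` tissues and zero
#' elsewhere, constitutive genes uniform across all tissues, and
#' "miscellaneous" genes expressed uniformly in an intermediate random subset
#' of tissues (33-60% of groups), which lands their tau between the two
#' classification thresholds. Multiplicative lognormal noise with the given CV
#' is applied to all positive entries.
#'
#' @param n_genes total genes, default 2000.
#' @param n_tissue_groups default 107.
#' @param fraction_tra,fraction_constitutive,fraction_misc class fractions,
#'   must sum to 1 (defaults 0.1 / 0.6 / 0.3).
#' @param tra_breadth candidate tissues-per-TRA-gene counts, default 1:3.
#' @param noise_cv multiplicative lognormal coefficient of variation,
#'   default 0.1.
#' @param seed RNG seed.
#' @return an `atlas_spec` list.
#' @export
atlas_spec <- function(n_genes = 2000, n_tissue_groups = 107,
                       fraction_tra = 0.1, fraction_constitutive = 0.6,
                       fraction_misc = 0.3, tra_breadth = 1:3,
                       noise_cv = 0.1, seed = 1) {
  if (abs(fraction_tra + fraction_constitutive + fraction_misc - 1) > 1e-8)
    stop("spec error: class fractions must sum to 1")
  stopifnot(noise_cv >= 0, n_tissue_groups >= 2)
  structure(as.list(environment()), class = "atlas_spec")
}

#' Generate a synthetic tissue atlas with known class labels
#'
#' @param spec an [atlas_spec()].
#' @return list: `atlas` (a [tissue_atlas()]) and `truth` (data.frame
#'   `gene_id`, `category` of the planted class).
#' @export
make_tissue_atlas <- function(spec) {
  set.seed(spec$seed)
  N <- spec$n_tissue_groups
  n_tra <- round(spec$n_genes * spec$fraction_tra)
  n_const <- round(spec$n_genes * spec$fraction_constitutive)
  n_misc <- spec$n_genes - n_tra - n_const
  gene_ids <- sprintf("gene%05d", seq_len(spec$n_genes))
  groups <- sprintf("tissue%03d", seq_len(N))
  category <- rep(c("TRA", "constitutive", "miscellaneous"),
                  c(n_tra, n_const, n_misc))
  expr <- matrix(0, spec$n_genes, N, dimnames = list(gene_ids, groups))

  for (i in seq_len(n_tra)) {
    b <- sample(spec$tra_breadth, 1)
    tiss <- sample(N, b)
    expr[i, tiss] <- stats::rlnorm(b, log(100), 0.5)
  }
  if (n_const > 0)
    expr[n_tra + seq_len(n_const), ] <-
      stats::rlnorm(n_const, log(20), 0.5)  # one level per gene, recycled by column
  m_lo <- round(0.33 * N); m_hi <- round(0.60 * N)
  for (i in seq_len(n_misc)) {
    m <- sample(m_lo:m_hi, 1)
    tiss <- sample(N, m)
    expr[n_tra + n_const + i, tiss] <- stats::rlnorm(1, log(20), 0.5)
  }
  pos <- expr > 0
  expr[pos] <- expr[pos] * lognormal_noise(sum(pos), spec$noise_cv)
  list(atlas = tissue_atlas(expr),
       truth = data.frame(gene_id = gene_ids, category = category,
                          stringsAsFactors = FALSE))
}

#' Specification of a synthetic single-cell experiment
#'
#' Emulates a plate-based single-cell experiment with donor and plate-column
#' structure: each cell carries a latent maturation time `t ~ Uniform(0, 1)`
#' (optionally bimodal, mimicking two density branches), a lognormal true size
#' factor, and multiplicative lognormal donor and plate-column batch effects.
#' Counts are negative binomial with variance `mu + alpha * mu^2`. Three
#' marker programs ride the trajectory: a monotone-up set (CCR7/CCL19-like),
#' a monotone-down set (CCR6-like), and a transient set (AIRE-like) whose
#' mean is nonzero only inside a late pseudotime window. ERCC-like technical
#' genes are independent of the cell size factor and batch.
#'
#' @param n_cells default 200.
#' @param n_genes biological genes including programs, default 2000.
#' @param n_donors default 2.
#' @param n_plate_columns default 12.
#' @param true_size_factor_sdlog lognormal sd of true size factors,
#'   default 0.3.
#' @param nb_dispersion NB dispersion alpha, default 0.1.
#' @param n_up,n_down,n_transient program sizes (defaults 25 / 25 / 10).
#' @param transient_window latent-time window of the transient program,
#'   default c(0.75, 1).
#' @param donor_effect_sdlog,plate_effect_sdlog batch-effect lognormal sds
#'   (defaults 0.15 / 0.08).
#' @param n_technical_genes ERCC-like controls, default 50.
#' @param bimodal_time draw latent time from a two-mode mixture instead of
#'   uniform, default FALSE.
#' @param seed RNG seed.
#' @return an `sc_sim_spec` list.
#' @export
sc_sim_spec <- function(n_cells = 200, n_genes = 2000, n_donors = 2,
                        n_plate_columns = 12, true_size_factor_sdlog = 0.3,
                        nb_dispersion = 0.1, n_up = 25, n_down = 25,
                        n_transient = 10, transient_window = c(0.75, 1),
                        donor_effect_sdlog = 0.15, plate_effect_sdlog = 0.08,
                        n_technical_genes = 50, bimodal_time = FALSE,
                        seed = 1) {
  stopifnot(transient_window[1] >= 0, transient_window[2] <= 1,
            transient_window[1] < transient_window[2],
            n_up + n_down + n_transient <= n_genes)
  structure(as.list(environment()), class = "sc_sim_spec")
}

#' Generate a synthetic single-cell count matrix with full ground truth
#'
#' @param spec an [sc_sim_spec()].
#' @return list: `counts` (a [count_matrix()] with donor / plate metadata and
#'   technical-gene flags) and `truth` (latent_time, true_size_factors with
#'   geometric mean 1, program gene-id sets, donor, plate_col).
#' @export
make_sc_experiment <- function(spec) {
  set.seed(spec$seed)
  nc <- spec$n_cells; ng <- spec$n_genes
  up_ids <- sprintf("up%03d", seq_len(spec$n_up))
  down_ids <- sprintf("down%03d", seq_len(spec$n_down))
  tr_ids <- sprintf("transient%03d", seq_len(spec$n_transient))
  n_fill <- ng - spec$n_up - spec$n_down - spec$n_transient
  fill_ids <- sprintf("gene%05d", seq_len(n_fill))
  tech_ids <- sprintf("ERCC-%04d", seq_len(spec$n_technical_genes))
  gid <- c(up_ids, down_ids, tr_ids, fill_ids, tech_ids)
  cid <- sprintf("cell%04d", seq_len(nc))

  t_lat <- if (spec$bimodal_time) {
    side <- stats::runif(nc) < 0.5
    ifelse(side, stats::rbeta(nc, 2, 6), stats::rbeta(nc, 6, 2))
  } else stats::runif(nc)
  sf <- stats::rlnorm(nc, 0, spec$true_size_factor_sdlog)
  sf <- sf / exp(mean(log(sf)))
  donor <- sample(sprintf("donor%d", seq_len(spec$n_donors)), nc, replace = TRUE)
  plate_col <- sample(sprintf("col%02d", seq_len(spec$n_plate_columns)), nc,
                      replace = TRUE)

  base_prog <- stats::rlnorm(spec$n_up + spec$n_down + spec$n_transient,
                             log(80), 0.3)
  base_fill <- stats::rlnorm(n_fill, log(50), 1.2)
  # genes x cells expected expression before size factor / batch
  mu <- matrix(0, ng, nc)
  i <- 0
  for (g in seq_len(spec$n_up))
    mu[i + g, ] <- base_prog[i + g] * (0.1 + 1.9 * t_lat)
  i <- spec$n_up
  for (g in seq_len(spec$n_down))
    mu[i + g, ] <- base_prog[i + g] * (2.0 - 1.9 * t_lat)
  i <- spec$n_up + spec$n_down
  inside <- t_lat >= spec$transient_window[1] & t_lat <= spec$transient_window[2]
  # linear onset within the window, exactly zero outside, maximal at window end
  ramp <- inside * (t_lat - spec$transient_window[1]) /
    (spec$transient_window[2] - spec$transient_window[1])
  for (g in seq_len(spec$n_transient))
    mu[i + g, ] <- base_prog[i + g] * 2 * ramp
  mu[spec$n_up + spec$n_down + spec$n_transient + seq_len(n_fill), ] <- base_fill

  donor_eff <- matrix(stats::rlnorm(spec$n_donors * ng, 0, spec$donor_effect_sdlog),
                      ng, spec$n_donors,
                      dimnames = list(NULL, sprintf("donor%d", seq_len(spec$n_donors))))
  plate_eff <- matrix(stats::rlnorm(spec$n_plate_columns * ng, 0, spec$plate_effect_sdlog),
                      ng, spec$n_plate_columns,
                      dimnames = list(NULL, sprintf("col%02d", seq_len(spec$n_plate_columns))))
  m_cell <- mu * donor_eff[, donor] * plate_eff[, plate_col]
  m_cell <- sweep(m_cell, 2, sf, "*")
  counts_bio <- matrix(rnb(length(m_cell), as.vector(m_cell), spec$nb_dispersion),
                       ng, nc)
  tech_mu <- stats::rlnorm(spec$n_technical_genes, log(30), 1)
  counts_tech <- matrix(rnb(spec$n_technical_genes * nc,
                            rep(tech_mu, nc), spec$nb_dispersion),
                        spec$n_technical_genes, nc)
  counts <- rbind(counts_bio, counts_tech)
  dimnames(counts) <- list(gid, cid)

  cm <- count_matrix(counts,
                     unit_meta = data.frame(donor = donor, plate_col = plate_col,
                                            population = NA_character_,
                                            group = NA_character_,
                                            stringsAsFactors = FALSE),
                     gene_meta = data.frame(
                       is_technical = gid %in% tech_ids))
  list(counts = cm,
       truth = list(latent_time = stats::setNames(t_lat, cid),
                    true_size_factors = stats::setNames(sf, cid),
                    base_means = stats::setNames(
                      c(base_prog, base_fill, tech_mu), gid),
                    programs = list(up = up_ids, down = down_ids,
                                    transient = tr_ids),
                    transient_window = spec$transient_window,
                    donor = stats::setNames(donor, cid),
                    plate_col = stats::setNames(plate_col, cid)))
}

#' Specification of synthetic bulk populations
#'
#' Emulates the bulk contrast between a promiscuously TRA-expressing
#' (mTEC-like) population and TRA-silent (DC-like) populations: all
#' populations share baseline means over the non-TRA genes; populations with
#' `tra_program_on` additionally express the planted TRA panel at
#' `tra_expression_level`, others leave it near zero.
#'
#' @param populations list of lists with fields `name`, `n_replicates`,
#'   `tra_program_on`, `tra_expression_level`, `library_size`.
#' @param n_genes total genes if `gene_ids` not given, default 2000.
#' @param n_tra_genes planted TRA panel size if `tra_gene_ids` not given,
#'   default 300.
#' @param nb_dispersion NB dispersion, default 0.05.
#' @param gene_ids,tra_gene_ids optional explicit gene universe and TRA panel
#'   (e.g. from [make_tissue_atlas()] truth), `tra_gene_ids` a subset of
#'   `gene_ids`.
#' @param seed RNG seed.
#' @return a `bulk_sim_spec` list.
#' @export
bulk_sim_spec <- function(populations, n_genes = 2000, n_tra_genes = 300,
                          nb_dispersion = 0.05, gene_ids = NULL,
                          tra_gene_ids = NULL, seed = 1) {
  if (length(populations) < 2) stop("need at least 2 populations")
  for (p in populations)
    stopifnot(!is.null(p$name), (p$n_replicates %||% 1) >= 1)
  if (!is.null(tra_gene_ids) && !all(tra_gene_ids %in% gene_ids))
    stop("tra_gene_ids must be a subset of gene_ids")
  structure(as.list(environment()), class = "bulk_sim_spec")
}

#' Generate synthetic bulk population profiles with ground truth
#'
#' @param spec a [bulk_sim_spec()].
#' @return list: `counts` (a [count_matrix()] with `population` metadata) and
#'   `truth` (baseline means, TRA panel ids, per-sample population).
#' @export
make_bulk_populations <- function(spec) {
  set.seed(spec$seed)
  if (is.null(spec$gene_ids)) {
    gid <- sprintf("gene%05d", seq_len(spec$n_genes))
    tra <- sample(gid, spec$n_tra_genes)
  } else {
    gid <- spec$gene_ids
    tra <- spec$tra_gene_ids %||% character(0)
  }
  ng <- length(gid)
  is_tra <- gid %in% tra
  base <- numeric(ng)
  base[!is_tra] <- stats::rlnorm(sum(!is_tra), log(50), 1)
  # leaky low-level TRA baseline shared by every population, so TRA-silent
  # populations still share a (weak) structured profile over TRA genes
  base[is_tra] <- stats::rlnorm(sum(is_tra), log(0.05), 1)
  # unit promiscuous-program profile, shared by all program-on populations
  prog_profile <- stats::rlnorm(sum(is_tra), 0, 1)

  cols <- list(); pops <- character(0); cn <- character(0)
  for (p in spec$populations) {
    reps <- p$n_replicates %||% 3
    lvl <- p$tra_expression_level %||% 30
    lib <- p$library_size %||% 2e6
    mu <- base
    if (isTRUE(p$tra_program_on)) mu[is_tra] <- lvl * prog_profile
    mu <- mu * lib / sum(mu)                 # expected depth = library_size
    for (r in seq_len(reps)) {
      cols[[length(cols) + 1]] <- rnb(ng, mu, spec$nb_dispersion)
      pops <- c(pops, p$name)
      cn <- c(cn, sprintf("%s_rep%d", p$name, r))
    }
  }
  m <- do.call(cbind, cols)
  dimnames(m) <- list(gid, cn)
  cm <- count_matrix(m, unit_meta = data.frame(population = pops,
                                               stringsAsFactors = FALSE))
  list(counts = cm,
       truth = list(baseline_means = stats::setNames(base, gid),
                    tra_gene_ids = tra,
                    population = stats::setNames(pops, cn)))
}
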
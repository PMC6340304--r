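#' Tau tissue-specificity index
#'
#' For a gene's expression profile over N tissue groups,
#' `tau = sum_i (1 - x_i / max_j x_j) / (N - 1)`: 0 for a perfectly uniform
#' profile, 1 for expression confined to a single tissue. Max-normalization of
#' the profile keeps tau in \[0, 1\] and makes it invariant to rescaling.
#' Computed on linear-scale atlas values by default; `log2_first` applies a
#' `log2(x + 1)` transform beforehand (the convention of the original tau
#' literature).
#'
#' @param profile numeric vector (one gene) or genes x tissues matrix of
#'   non-negative expression values.
#' @param log2_first log2(x + 1)-transform before computing tau.
#' @return tau value(s) in \[0, 1\]; NA for all-zero profiles.
#' @export
tau_index <- function(profile, log2_first = FALSE) {
  if (is.matrix(profile)) {
    return(apply(profile, 1, tau_index, log2_first = log2_first))
  }
  if (length(profile) < 2) stop("tau needs at least 2 tissue groups")
  if (any(profile < 0)) stop("tau requires non-negative expression")
  if (log2_first) profile <- log2(profile + 1)
  mx <- max(profile)
  if (mx == 0) return(NA_real_)
  sum(1 - profile / mx) / (length(profile) - 1)
}

#' Classify genes by tissue specificity
#'
#' Genes with `tau >= tau_tra` are tissue-restricted antigens (TRA), genes
#' with `tau <= tau_const` are constitutive, the rest miscellaneous (boundary
#' values included exactly as stated). Genes with an all-zero atlas profile
#' cannot be scored and are excluded as unclassified.
#'
#' @param atlas a [tissue_atlas()].
#' @param tau_tra TRA threshold, default 0.8.
#' @param tau_const constitutive threshold, default 0.4.
#' @param log2_first see [tau_index()].
#' @return data.frame of class `tau_classification`: `gene_id`, `tau`,
#'   `category` in {TRA, constitutive, miscellaneous, unclassified}; attribute
#'   `n_groups`.
#' @export
classify_genes <- function(atlas, tau_tra = 0.8, tau_const = 0.4,
                           log2_first = FALSE) {
  stopifnot(tau_const <= tau_tra)
  tau <- tau_index(atlas$expression, log2_first = log2_first)
  category <- ifelse(is.na(tau), "unclassified",
              ifelse(tau >= tau_tra, "TRA",
              ifelse(tau <= tau_const, "constitutive", "miscellaneous")))
  out <- data.frame(gene_id = rownames(atlas$expression), tau = unname(tau),
                    category = category, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "n_groups") <- ncol(atlas$expression)
  attr(out, "thresholds") <- c(tau_tra = tau_tra, tau_const = tau_const)
  class(out) <- c("tau_classification", class(out))
  out
}

expressed_genes <- function(linear_values, pops, expressed_min = 1) {
  lapply(split(seq_along(pops), pops), function(cols) {
    rownames(linear_values)[
      rowMeans(linear_values[, cols, drop = FALSE]) >= expressed_min]
  })
}

#' Per-population proportions of TRA / constitutive / miscellaneous genes
#'
#' For each population, "expressed" genes are those with mean normalized count
#' at or above `expressed_min` across the population's replicates (applied
#' after depth downsampling); proportions are computed over the classified
#' expressed genes and sum to 1 across the three categories.
#'
#' @param linear_values genes x samples matrix of size-factor-normalized
#'   counts (linear scale).
#' @param pops factor of population labels per sample.
#' @param classification a `tau_classification` from [classify_genes()].
#' @param expressed_min expressed-gene rule threshold, default 1.
#' @return data.frame: `population`, `n_expressed`, `prop_tra`,
#'   `prop_constitutive`, `prop_miscellaneous`. Populations with zero
#'   classified expressed genes get NA proportions with a warning.
#' @export
tra_proportions <- function(linear_values, pops, classification,
                            expressed_min = 1) {
  cls <- stats::setNames(classification$category, classification$gene_id)
  ex <- expressed_genes(linear_values, pops, expressed_min)
  rows <- lapply(names(ex), function(pop) {
    cats <- cls[intersect(ex[[pop]], names(cls))]
    cats <- cats[cats != "unclassified"]
    n <- length(cats)
    if (n == 0) {
      warning("no classified expressed genes in population ", pop)
      return(data.frame(population = pop, n_expressed = 0, prop_tra = NA,
                        prop_constitutive = NA, prop_miscellaneous = NA))
    }
    data.frame(population = pop, n_expressed = n,
               prop_tra = mean(cats == "TRA"),
               prop_constitutive = mean(cats == "constitutive"),
               prop_miscellaneous = mean(cats == "miscellaneous"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "expressed_min") <- expressed_min
  out
}

#' Distribution of tau over expressed genes, with pairwise shift tests
#'
#' Summarizes the per-population empirical distribution of tau over expressed
#' genes (quantiles) and reports a one-sided Mann-Whitney location-shift
#' statistic for every ordered population pair (descriptive, no multiplicity
#' correction): large values indicate the first population's expressed genes
#' skew toward higher tissue specificity.
#'
#' @inheritParams tra_proportions
#' @return list with `quantiles` (population x probs matrix over
#'   c(0, .25, .5, .75, 1)), `tau_values` (named list), and `shifts`
#'   (data.frame of pairwise one-sided Mann-Whitney tests).
#' @export
tau_shift_summary <- function(linear_values, pops, classification,
                              expressed_min = 1) {
  if (nlevels(as.factor(pops)) < 2) stop("need at least 2 populations")
  tau <- stats::setNames(classification$tau, classification$gene_id)
  ex <- expressed_genes(linear_values, pops, expressed_min)
  vals <- lapply(ex, function(g) tau[intersect(g, names(tau)[!is.na(tau)])])
  probs <- c(0, 0.25, 0.5, 0.75, 1)
  qs <- t(vapply(vals, stats::quantile, numeric(length(probs)), probs = probs,
                 na.rm = TRUE))
  pairs <- utils::combn(names(vals), 2)
  shifts <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    wt <- stats::wilcox.test(vals[[a]], vals[[b]], alternative = "greater",
                             exact = FALSE)
    data.frame(higher = a, lower = b, W = unname(wt$statistic),
               p = wt$p.value,
               median_diff = stats::median(vals[[a]]) - stats::median(vals[[b]]),
               stringsAsFactors = FALSE)
  }))
  list(quantiles = qs, tau_values = vals, shifts = shifts)
}

#' PCA of samples on expressed TRA genes
#'
#' Gene-centered principal components analysis of the samples, restricted to
#' the supplied TRA genes.
#'
#' @param log2_values genes x samples matrix (log2 normalized).
#' @param tra_genes character vector of TRA gene ids to use.
#' @return list: `scores` (samples x components), `variance_fraction`
#'   (descending, sums to <= 1), `genes_used`.
#' @export
pca_on_tra <- function(log2_values, tra_genes) {
  genes <- intersect(tra_genes, rownames(log2_values))
  if (length(genes) < 2) stop("need at least 2 TRA genes present in the matrix")
  if (ncol(log2_values) < 2) stop("need at least 2 samples")
  x <- t(log2_values[genes, , drop = FALSE])
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  vf <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = pr$x, variance_fraction = vf, genes_used = genes)
}

#' Pearson-correlation clades over TRA genes
#'
#' Sample-by-sample Pearson correlation of TRA expression, clustered by
#' average linkage on the dissimilarity `1 - r`; the two-clade membership is
#' reported. Zero-variance samples are excluded with a warning.
#'
#' @param log2_values genes x samples matrix (log2 normalized), typically
#'   already restricted to TRA genes.
#' @return list: `correlation` (samples x samples), `tree` (`hclust`),
#'   `clades` (two-group membership), `excluded`.
#' @export
correlation_clades <- function(log2_values) {
  if (ncol(log2_values) < 2) stop("need at least 2 samples")
  sds <- apply(log2_values, 2, stats::sd)
  excluded <- colnames(log2_values)[sds == 0]
  if (length(excluded) > 0)
    warning("zero-variance sample(s) excluded: ", paste(excluded, collapse = ", "))
  x <- log2_values[, sds > 0, drop = FALSE]
  r <- stats::cor(x, method = "pearson")
  tree <- average_linkage_tree(1 - r)
  clades <- stats::cutree(tree, k = min(2, ncol(x)))
  list(correlation = r, tree = tree, clades = clades, excluded = excluded)
}

#' Expression panel for a homolog gene set
#'
#' Per-sample log2 expression and per-population means for each gene of the
#' set (e.g. human homologs of murine Aire-dependent TRAs); genes absent from
#' the matrix are reported as missing, not errors.
#'
#' @param log2_values genes x samples matrix (log2 normalized).
#' @param homologs a [gene_set()].
#' @param pops factor of population labels per sample.
#' @return list: `per_sample` (genes x samples), `population_means`
#'   (genes x populations), `missing`.
#' @export
homolog_panel <- function(log2_values, homologs, pops) {
  present <- intersect(homologs$ids, rownames(log2_values))
  missing <- setdiff(homologs$ids, present)
  if (length(present) == 0)
    return(list(per_sample = log2_values[integer(0), , drop = FALSE],
                population_means = NULL, missing = missing))
  sub <- log2_values[present, , drop = FALSE]
  pops <- as.factor(pops)
  pm <- vapply(levels(pops), function(p)
    rowMeans(sub[, pops == p, drop = FALSE]), numeric(length(present)))
  pm <- matrix(pm, nrow = length(present),
               dimnames = list(present, levels(pops)))
  list(per_sample = sub, population_means = pm, missing = missing)
}
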
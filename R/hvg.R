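#' Fit the technical CV2-mean trend
#'
#' Fits the squared coefficient of variation against mean expression as
#' `CV2 = a1 / mu + alpha0` by a gamma-family generalized linear fit with
#' identity link on the covariate `1/mu`. By default the mean and CV2 are
#' computed on size-factor-normalized counts (linear scale), the
#' parameterization under which the chi-squared excess test has its stated
#' theory; `fit_on = "log2"` fits the trend against mean log2 expression
#' instead, for comparison.
#'
#' Fit genes: the flagged technical (ERCC-like) controls when at least 20 are
#' present and `use_technical = TRUE`; otherwise all genes with mean above the
#' 10th percentile of positive means. Constant genes (zero variance) are
#' excluded from fitting but recorded with CV2 = 0.
#'
#' @param normed a `normalized_matrix` from [normalize_log2()].
#' @param use_technical prefer flagged technical genes for the trend fit.
#' @param fit_on `"linear"` (default) or `"log2"`: scale on which mu and CV2
#'   are computed.
#' @return object of class `hvg_fit`: per-gene `mu`, `cv2`, trend parameters
#'   `a1` and `alpha0`, `fit_gene` flag, `n_cells`.
#' @export
fit_cv2_trend <- function(normed, use_technical = TRUE,
                          fit_on = c("linear", "log2")) {
  fit_on <- match.arg(fit_on)
  expr <- if (fit_on == "linear") normed$linear else normed$values
  mu <- rowMeans(expr)
  v <- apply(expr, 1, stats::var)
  cv2 <- ifelse(mu > 0, v / mu^2, 0)
  cv2[v == 0] <- 0

  n_pos <- sum(mu > 0)
  if (n_pos < 20) stop("need at least 20 genes with positive mean to fit the trend")
  tech <- normed$gene_meta$is_technical
  if (use_technical && sum(tech & mu > 0 & v > 0) >= 20) {
    fit_gene <- tech & mu > 0 & v > 0
  } else {
    floor_mu <- stats::quantile(mu[mu > 0], 0.1)
    fit_gene <- mu >= floor_mu & v > 0
  }

  x <- 1 / mu[fit_gene]
  y <- cv2[fit_gene]
  start <- stats::coef(stats::lm(y ~ x))
  start <- c(max(start[1], 1e-8), max(start[2], 1e-8))
  g <- tryCatch(
    suppressWarnings(stats::glm(y ~ x, family = stats::Gamma(link = "identity"),
                                start = start, control = list(maxit = 100))),
    error = function(e) NULL)
  cf <- if (!is.null(g)) stats::coef(g) else stats::coef(stats::lm(y ~ x))
  alpha0 <- unname(cf[1]); a1 <- unname(cf[2])

  trend_at <- a1 / mu[mu > 0] + alpha0
  if (any(trend_at <= 0))
    stop(sprintf("degenerate-fit: trend non-positive over observed means (a1 = %.4g, alpha0 = %.4g, min trend = %.4g)",
                 a1, alpha0, min(trend_at)))
  structure(list(gene_ids = rownames(expr), mu = unname(mu), cv2 = unname(cv2),
                 a1 = a1, alpha0 = alpha0, fit_gene = unname(fit_gene),
                 n_cells = ncol(expr), fit_on = fit_on),
            class = "hvg_fit")
}

#' Evaluate the fitted CV2 trend at given means
#'
#' @param fit an `hvg_fit`.
#' @param mu means at which to evaluate.
#' @return trend CV2 values `a1 / mu + alpha0`.
#' @export
cv2_trend <- function(fit, mu) fit$a1 / mu + fit$alpha0

#' Call highly variable genes by chi-squared excess over the trend
#'
#' Per gene the statistic `(n_cells - 1) * CV2_g / trend(mu_g)` is compared
#' against the upper tail of a chi-squared distribution with
#' `df_adjust * (n_cells - 1)` degrees of freedom. Genes with `p <= alpha` are
#' flagged highly variable; no multiple-testing correction is applied before
#' the cut (an optional FDR mode adjusts by Benjamini-Hochberg first).
#'
#' @param fit an `hvg_fit` from [fit_cv2_trend()].
#' @param alpha significance threshold, default 0.01.
#' @param df_adjust multiplier on the nominal `n_cells - 1` degrees of
#'   freedom, default 1.
#' @param fdr if TRUE, apply the cut to BH-adjusted p-values instead.
#' @return data.frame: `gene_id`, `mu`, `cv2`, `trend`, `p`, `hvg`. Genes with
#'   zero mean get p = 1.
#' @export
call_hvgs <- function(fit, alpha = 0.01, df_adjust = 1, fdr = FALSE) {
  df <- df_adjust * (fit$n_cells - 1)
  trend <- cv2_trend(fit, fit$mu)
  stat <- ifelse(fit$mu > 0, df * fit$cv2 / trend, NA_real_)
  p <- ifelse(is.na(stat), 1, stats::pchisq(stat, df = df, lower.tail = FALSE))
  p_cut <- if (fdr) stats::p.adjust(p, "BH") else p
  data.frame(gene_id = fit$gene_ids, mu = fit$mu, cv2 = fit$cv2,
             trend = ifelse(fit$mu > 0, trend, NA_real_), p = p,
             hvg = p_cut <= alpha, stringsAsFactors = FALSE, row.names = NULL)
}
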
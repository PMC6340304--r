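#' Blocked per-gene linear models
#'
#' Ordinary least squares of log2 expression on a two-level group contrast,
#' blocking on nuisance factors (donor, plate column) as additive categorical
#' covariates with treatment coding and an intercept. Block columns aliased
#' with other columns are dropped (and recorded); if the group contrast itself
#' is aliased with the blocks the design is unusable and an error names the
#' confounded factors.
#'
#' @param values genes x units numeric matrix (log2 scale).
#' @param group factor (or coercible) of length n_units with exactly two
#'   levels; the contrast is level 2 minus level 1.
#' @param blocks optional data.frame of blocking factors (e.g. `donor`,
#'   `plate_col`), one row per unit.
#' @return list of class `gene_fits`: per-gene `beta` (log2 fold change),
#'   `s2` (residual variance), `df` (residual degrees of freedom),
#'   `unscaled_var` (the contrast's unscaled variance from the design),
#'   `dropped` (aliased block columns removed).
#' @export
fit_blocked_models <- function(values, group, blocks = NULL) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if (any(table(group) < 2)) stop("need at least 2 units per group level")
  dat <- data.frame(.group = group)
  if (!is.null(blocks)) {
    blocks <- as.data.frame(blocks)
    for (nm in colnames(blocks)) dat[[nm]] <- droplevels(as.factor(blocks[[nm]]))
  }
  X <- stats::model.matrix(~ ., dat)
  gcol <- grep("^\\.group", colnames(X), value = TRUE)
  # the contrast is unusable if the group indicator lies in the span of the
  # intercept and blocking columns
  others <- X[, setdiff(colnames(X), gcol), drop = FALSE]
  g_resid <- stats::lm.fit(others, X[, gcol])$residuals
  if (max(abs(g_resid)) < 1e-8)
    stop("design error: group contrast confounded with blocking factors (",
         paste(setdiff(colnames(others), "(Intercept)"), collapse = ", "), ")")
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    dropped <- colnames(X)[-keep]
    X <- X[, keep, drop = FALSE]
  }
  fit <- stats::lm.fit(X, t(values))
  cf <- fit$coefficients
  if (is.null(dim(cf))) cf <- matrix(cf, ncol = 1, dimnames = list(names(cf), NULL))
  gname <- grep("^\\.group", rownames(cf), value = TRUE)
  beta <- cf[gname, ]
  res <- as.matrix(fit$residuals)
  df <- nrow(X) - fit$rank
  s2 <- colSums(res^2) / df
  XtXi <- chol2inv(chol(crossprod(X)))
  uv <- XtXi[match(gname, colnames(X)), match(gname, colnames(X))]
  structure(list(gene_ids = rownames(values), beta = unname(beta),
                 s2 = unname(s2), df = df, unscaled_var = uv,
                 dropped = dropped, design = X,
                 y_scale = max(abs(values), 1e-300)),
            class = "gene_fits")
}

trigamma_inverse <- function(x) {
  # Newton iteration on 1/trigamma, monotone and convex in 1/y
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderation of per-gene variances
#'
#' Fits a scaled inverse chi-squared prior to the observed residual variances
#' by the method of moments on log s2: under the prior, log s2 follows a
#' shifted log-F distribution whose mean and variance are closed forms in
#' digamma/trigamma functions, so the prior degrees of freedom d0 and prior
#' variance s0^2 are recovered by inverting those moments. Posterior
#' (moderated) variances are the precision-weighted blend
#' `s2_tilde = (d0 * s0^2 + df * s2) / (d0 + df)`.
#'
#' When the observed spread of log s2 does not exceed what sampling alone
#' explains, d0 = Inf and every moderated variance equals s0^2 = mean(s2).
#'
#' @param s2 per-gene residual variances (zeros are floored to the smallest
#'   positive value for the log-moment fit and recorded).
#' @param df residual degrees of freedom (scalar or per gene).
#' @param prior_df optional override for d0 (e.g. 0 for no shrinkage, Inf for
#'   complete pooling); s0^2 is still estimated from the data.
#' @return list of class `eb_moderation`: `d0`, `s02`, `s2_tilde`.
#' @export
empirical_bayes_moderate <- function(s2, df, prior_df = NULL) {
  if (length(s2) < 10) stop("need at least 10 genes to moderate variances")
  if (all(s2 == 0)) stop("degenerate-variance: all residual variances are zero")
  df <- rep_len(df, length(s2))
  pos <- s2 > 0
  s2f <- s2
  s2f[!pos] <- min(s2[pos])
  z <- log(s2f)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- mean(s2)
  }
  if (!is.null(prior_df)) d0 <- prior_df
  s2_tilde <- if (is.infinite(d0)) rep(s02, length(s2))
              else if (d0 == 0) s2
              else (d0 * s02 + df * s2) / (d0 + df)
  structure(list(d0 = d0, s02 = s02, s2_tilde = s2_tilde),
            class = "eb_moderation")
}

#' Moderated t-test
#'
#' `t = beta / sqrt(s2_tilde * unscaled_var)` with two-sided p-values from a
#' t distribution with `df + d0` degrees of freedom (normal in the d0 = Inf
#' limit). Genes with zero moderated variance and zero effect get t = 0,
#' p = 1 rather than being dropped.
#'
#' @param fits a `gene_fits` from [fit_blocked_models()].
#' @param moderation an `eb_moderation` from [empirical_bayes_moderate()].
#' @return data.frame: `gene_id`, `beta`, `s2`, `s2_tilde`, `t`, `p`.
#' @export
moderated_t_test <- function(fits, moderation) {
  # numerically-zero variances and effects (constant genes) get t = 0, p = 1;
  # "zero" is judged relative to the magnitude of the fitted data
  tol <- (fits$y_scale %||% max(abs(fits$beta), 1e-300)) * 1e-10
  beta <- ifelse(abs(fits$beta) < tol, 0, fits$beta)
  se <- sqrt(moderation$s2_tilde * fits$unscaled_var)
  se[se < tol] <- 0
  t <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, Inf * sign(beta)))
  df_total <- fits$df + moderation$d0
  p <- 2 * stats::pt(-abs(t), df = df_total)
  data.frame(gene_id = fits$gene_ids, beta = beta, s2 = fits$s2,
             s2_tilde = moderation$s2_tilde, t = t, p = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH with monotonicity enforcement (via `p.adjust`).
#'
#' @param p p-values in \[0, 1\].
#' @return q-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Full differential-expression test between two groups
#'
#' Blocked OLS per gene, empirical-Bayes variance moderation, moderated t,
#' and BH FDR control; genes at `q <= fdr` are flagged significant.
#'
#' @inheritParams fit_blocked_models
#' @param fdr FDR threshold, default 0.01.
#' @param prior_df optional d0 override (see [empirical_bayes_moderate()]).
#' @return data.frame of class `de_result` with `gene_id`, `beta`, `s2`,
#'   `s2_tilde`, `t`, `p`, `q`, `significant`; attributes `d0`, `s02`, `df`.
#' @export
run_de <- function(values, group, blocks = NULL, fdr = 0.01, prior_df = NULL) {
  fits <- fit_blocked_models(values, group, blocks)
  mod <- empirical_bayes_moderate(fits$s2, fits$df, prior_df = prior_df)
  out <- moderated_t_test(fits, mod)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q <= fdr
  attr(out, "d0") <- mod$d0
  attr(out, "s02") <- mod$s02
  attr(out, "df") <- fits$df
  class(out) <- c("de_result", class(out))
  out
}

#' Median-of-ratios size factors for bulk samples
#'
#' For genes with a positive count in every sample, the per-sample factor is
#' the median over those genes of `count(g, j) / geometric_mean_g`. Log2
#' values downstream use `log2(count / factor + 1)`.
#'
#' @param counts a [count_matrix()] of bulk samples.
#' @return a `size_factors` object (not rescaled: the median-of-ratios scale
#'   is kept, as the reference is the geometric-mean pseudo-sample).
#' @export
median_ratio_size_factors <- function(counts) {
  m <- counts$counts
  allpos <- rowSums(m > 0) == ncol(m)
  if (!any(allpos))
    stop("no-reference-gene: no gene has positive counts in every sample")
  lg <- log(m[allpos, , drop = FALSE])
  # median of log ratios (exponentiated), the reference implementation's
  # convention; identical to the ratio-space median for an odd gene count
  fac <- exp(apply(lg - rowMeans(lg), 2, stats::median))
  structure(list(unit_ids = colnames(m), factors = unname(fac)),
            class = "size_factors")
}

#' Downsample counts to a fixed depth per unit
#'
#' Per unit, `target` reads are drawn without replacement from the unit's
#' reads (a multivariate hypergeometric draw over genes, realized by
#' sequential univariate hypergeometric draws), so column sums equal the
#' target exactly. With unique-read counts this is distributionally the same
#' as subsampling the alignment. Units already at or below the target pass
#' through unchanged (recorded in the `passed_through` attribute).
#'
#' @param counts a [count_matrix()].
#' @param target_per_unit reads to keep per unit, default 2e7.
#' @param seed RNG seed for reproducibility.
#' @return a `count_matrix` of the downsampled counts.
#' @export
downsample_counts <- function(counts, target_per_unit = 2e7, seed = 1) {
  if (target_per_unit < 0) stop("parameter error: negative downsampling target")
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  m <- counts$counts
  out <- m
  passed <- character(0)
  for (j in seq_len(ncol(m))) {
    tot <- sum(m[, j])
    if (tot <= target_per_unit) {
      passed <- c(passed, colnames(m)[j])
      next
    }
    remaining <- tot
    need <- target_per_unit
    col <- m[, j]
    newcol <- numeric(length(col))
    for (g in which(col > 0)) {
      if (need == 0) break
      x <- stats::rhyper(1, col[g], remaining - col[g], need)
      newcol[g] <- x
      need <- need - x
      remaining <- remaining - col[g]
    }
    out[, j] <- newcol
  }
  res <- count_matrix(out, unit_meta = counts$unit_meta, gene_meta = counts$gene_meta)
  attr(res, "passed_through") <- passed
  res
}
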
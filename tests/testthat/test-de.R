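test_that("per-gene OLS matches the normal equations, with and without blocking", {
  vals <- rbind(clean = c(0, 0, 0, 1, 1, 1))
  colnames(vals) <- paste0("s", 1:6)
  f <- fit_blocked_models(vals, rep(c("a", "b"), each = 3))
  expect_equal(f$beta, 1)
  expect_equal(f$s2, 0)
  expect_equal(f$df, 4)

  # hand-worked 6-unit example with one blocking factor
  set.seed(41)
  group <- factor(rep(c("a", "b"), each = 3))
  donor <- factor(c("d1", "d2", "d1", "d2", "d1", "d2"))
  y <- matrix(rnorm(3 * 6), 3, 6,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:6)))
  f2 <- fit_blocked_models(y, group, data.frame(donor = donor))
  X <- model.matrix(~ group + donor)
  for (g in 1:3) {
    beta_hat <- solve(crossprod(X), crossprod(X, y[g, ]))
    expect_equal(f2$beta[g], unname(beta_hat["groupb", 1]), tolerance = 1e-12)
    res <- y[g, ] - X %*% beta_hat
    expect_equal(f2$s2[g], sum(res^2) / (6 - 3), tolerance = 1e-12)
  }
  expect_equal(f2$unscaled_var,
               solve(crossprod(X))["groupb", "groupb"], tolerance = 1e-12)

  # donor perfectly confounded with group
  expect_error(
    fit_blocked_models(y, group, data.frame(donor = group)),
    "confounded")
})

test_that("variance moderation has the stated limits and recovers the prior", {
  set.seed(42)
  s2 <- rchisq(100, 5)
  # d0 = 0: no shrinkage
  eb0 <- empirical_bayes_moderate(s2, 10, prior_df = 0)
  expect_equal(eb0$s2_tilde, s2)
  # all variances equal: fixed point
  ebv <- empirical_bayes_moderate(rep(3, 50), 10)
  expect_equal(ebv$s02, 3)
  expect_equal(ebv$s2_tilde, rep(3, 50))
  expect_equal(ebv$d0, Inf)
  # degenerate input
  expect_error(empirical_bayes_moderate(rep(0, 50), 10), "degenerate-variance")

  # scaled inverse-chi-squared simulation: d0 within 1, s02 within 10%
  set.seed(43)
  d0_true <- 4; s02_true <- 2; d <- 10
  sigma2 <- d0_true * s02_true / rchisq(5000, d0_true)
  s2sim <- sigma2 * rchisq(5000, d) / d
  eb <- empirical_bayes_moderate(s2sim, d)
  expect_lt(abs(eb$d0 - d0_true), 1)
  expect_lt(abs(eb$s02 - s02_true) / s02_true, 0.1)

  # agrees with the limma implementation
  sv <- limma::squeezeVar(s2sim, d)
  expect_equal(eb$d0, sv$df.prior, tolerance = 1e-6)
  expect_equal(eb$s02, sv$var.prior, tolerance = 1e-6)
  expect_equal(eb$s2_tilde, sv$var.post, tolerance = 1e-6)
})

test_that("moderated t reduces to the classical t at d0 = 0 and handles zero effects", {
  set.seed(44)
  group <- rep(c("a", "b"), each = 5)
  y <- matrix(rnorm(20 * 10), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  fits <- fit_blocked_models(y, group)
  eb <- empirical_bayes_moderate(fits$s2, fits$df, prior_df = 0)
  mt <- moderated_t_test(fits, eb)
  for (g in c(1, 7, 20)) {
    ct <- t.test(y[g, group == "b"], y[g, group == "a"], var.equal = TRUE)
    expect_equal(mt$t[g], unname(ct$statistic), tolerance = 1e-10)
    expect_equal(mt$p[g], ct$p.value, tolerance = 1e-10)
  }

  y0 <- rbind(zero = rep(2, 10))
  colnames(y0) <- paste0("s", 1:10)
  f0 <- fit_blocked_models(y0, group)
  m0 <- moderated_t_test(f0, structure(list(d0 = 0, s02 = 1,
                                            s2_tilde = f0$s2),
                                       class = "eb_moderation"))
  expect_equal(m0$t, 0)
  expect_equal(m0$p, 1)
})

test_that("null simulation with donor and plate blocking is calibrated", {
  set.seed(45)
  n <- 24; G <- 2000
  group <- rep(c("a", "b"), each = n / 2)
  blocks <- data.frame(donor = rep(c("d1", "d2"), n / 2),
                       plate_col = rep(c("p1", "p2", "p3"), length.out = n))
  vals <- matrix(rnorm(G * n), G, n,
                 dimnames = list(paste0("g", 1:G), paste0("s", 1:n)))
  de <- run_de(vals, group, blocks)
  frac <- mean(de$p < 0.05)
  expect_gte(frac, 0.035)
  expect_lte(frac, 0.065)
  expect_true(all(de$q >= de$p))
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(46)
  for (rep in 1:20) {
    p <- round(runif(sample(2:10, 1)), 3)
    expect_equal(bh_adjust(p), bh_brute(p))
  }
  # order invariance
  p <- runif(50)
  o <- sample(50)
  expect_equal(bh_adjust(p)[o], bh_adjust(p[o]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("median-of-ratios factors match hand computation and DESeq2", {
  m <- matrix(c(2, 4, 6, 8), 4, 3, dimnames = list(paste0("g", 1:4),
                                                   paste0("s", 1:3)))
  sf <- median_ratio_size_factors(count_matrix(m))
  expect_equal(sf$factors, rep(1, 3))

  m2 <- cbind(a = c(2, 4, 6, 8), b = 3 * c(2, 4, 6, 8), c = c(2, 4, 6, 8))
  rownames(m2) <- paste0("g", 1:4)
  sf2 <- median_ratio_size_factors(count_matrix(m2))
  expect_equal(sf2$factors[2] / sf2$factors[1], 3, tolerance = 1e-12)

  set.seed(47)
  m3 <- matrix(rpois(5 * 3, 50) + 1, 5, 3,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  sf3 <- median_ratio_size_factors(count_matrix(m3))
  geo <- exp(rowMeans(log(m3)))
  hand <- apply(m3 / geo, 2, median)   # odd gene count: plain median of ratios
  expect_equal(sf3$factors, unname(hand))
  ref <- DESeq2::estimateSizeFactorsForMatrix(m3)
  expect_equal(sf3$factors, unname(ref), tolerance = 1e-10)

  m4 <- matrix(c(0, 5, 3, 0), 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_error(median_ratio_size_factors(count_matrix(m4)), "no-reference-gene")
})

test_that("downsampling is exact, seeded, and distributionally additive", {
  set.seed(48)
  m <- matrix(rpois(50 * 3, 40), 50, 3,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:3)))
  cm <- count_matrix(m)
  ds <- downsample_counts(cm, 500, seed = 9)
  expect_equal(unname(colSums(ds$counts)), rep(500, 3))
  expect_true(all(ds$counts <= m))
  expect_identical(downsample_counts(cm, 500, seed = 9)$counts, ds$counts)

  # units at or below target pass through
  expect_equal(downsample_counts(cm, sum(m[, 1]), seed = 1)$counts[, 1],
               m[, 1], ignore_attr = TRUE)
  expect_equal(unname(colSums(downsample_counts(cm, 0, seed = 1)$counts)),
               rep(0, 3))
  expect_error(downsample_counts(cm, -5), "negative")

  # two disjoint draws of t1 + t2 match one draw of t in first moments
  m1 <- matrix(c(12, 28), 2, 1, dimnames = list(c("g1", "g2"), "u"))
  cmu <- count_matrix(m1)
  one <- vapply(1:400, function(s) downsample_counts(cmu, 20, seed = s)$counts[1, 1],
                numeric(1))
  two <- vapply(1:400, function(s) {
    a <- downsample_counts(cmu, 8, seed = s)$counts[, 1]
    rem <- count_matrix(m1 - a)
    a[1] + downsample_counts(rem, 12, seed = s + 1e4)$counts[1, 1]
  }, numeric(1))
  expect_equal(mean(one), mean(two), tolerance = 0.08)
  expect_equal(mean(one), 20 * 12 / 40, tolerance = 0.08)
})
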
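test_that("tau index matches its definition, bounds, and invariances", {
  expect_equal(tau_index(rep(7, 10)), 0)
  expect_equal(tau_index(c(3, 0, 0, 0, 0)), 1)
  expect_equal(tau_index(c(10, 5, 0, 0)), (0 + 0.5 + 1 + 1) / 3)
  expect_equal(tau_index(c(10, 5, 0, 0)), 0.8333, tolerance = 1e-4)
  expect_true(is.na(tau_index(c(0, 0, 0))))
  expect_error(tau_index(c(-1, 2)), "non-negative")
  expect_error(tau_index(5), "at least 2")

  set.seed(51)
  for (i in 1:20) {
    prof <- rexp(10)
    expect_equal(tau_index(prof * runif(1, 0.01, 100)), tau_index(prof))
    # zeroing a non-maximal tissue never decreases tau
    z <- prof
    z[-which.max(prof)][1] <- 0
    expect_gte(tau_index(z), tau_index(prof))
  }
  # matrix dispatch
  m <- rbind(u = rep(1, 4), s = c(1, 0, 0, 0))
  expect_equal(tau_index(m), c(u = 0, s = 1))
})

test_that("classification includes both boundaries exactly as stated", {
  # N = 2 profiles with exact tau values: tau = 1 - x2/x1
  expr <- rbind(tra_boundary = c(1, 0.2),      # tau = 0.8
                const_boundary = c(1, 0.6),    # tau = 0.4
                misc = c(1, 0.4),              # tau = 0.6
                silent = c(0, 0))
  colnames(expr) <- c("t1", "t2")
  cls <- classify_genes(tissue_atlas(expr))
  expect_equal(cls$category,
               c("TRA", "constitutive", "miscellaneous", "unclassified"))
  expect_equal(cls$tau[1:3], c(0.8, 0.4, 0.6))
})

test_that("TRA proportions follow the expressed-gene rule and sum to one", {
  expr <- rbind(t1 = c(100, 0), t2 = c(80, 0), c1 = c(50, 50), m1 = c(0, 30))
  colnames(expr) <- c("popA_r1", "popB_r1")
  cls <- data.frame(gene_id = c("t1", "t2", "c1", "m1"),
                    tau = c(0.9, 0.95, 0.1, 0.6),
                    category = c("TRA", "TRA", "constitutive", "miscellaneous"))
  pr <- tra_proportions(expr, c("A", "B"), cls)
  a <- pr[pr$population == "A", ]
  expect_equal(a$prop_tra, 2 / 3)
  expect_equal(a$prop_tra + a$prop_constitutive + a$prop_miscellaneous, 1)
  b <- pr[pr$population == "B", ]
  expect_equal(b$prop_tra, 0)

  only_tra <- expr[1:2, 1, drop = FALSE]
  pr2 <- tra_proportions(only_tra, "A", cls)
  expect_equal(pr2$prop_tra, 1.0)

  silent <- matrix(0, 2, 1, dimnames = list(c("t1", "t2"), "s1"))
  expect_warning(pr3 <- tra_proportions(silent, "A", cls), "no classified")
  expect_true(is.na(pr3$prop_tra))
})

test_that("tau shift summaries detect planted specificity differences", {
  cls <- data.frame(gene_id = paste0("g", 1:100),
                    tau = seq(0.01, 1, length.out = 100),
                    category = "miscellaneous")
  expr_same <- matrix(5, 100, 4, dimnames = list(paste0("g", 1:100),
                                                 paste0("s", 1:4)))
  sh <- tau_shift_summary(expr_same, c("A", "A", "B", "B"), cls)
  expect_equal(sh$quantiles["A", ], sh$quantiles["B", ])
  expect_equal(sh$shifts$median_diff, 0)

  # population B additionally expresses low-tau (constitutive-like) genes
  expr2 <- expr_same
  expr2[1:50, 1:2] <- 0    # A only expresses the high-tau half
  sh2 <- tau_shift_summary(expr2, c("A", "A", "B", "B"), cls)
  expect_gt(sh2$quantiles["A", "50%"], sh2$quantiles["B", "50%"])
  expect_lt(sh2$shifts$p[sh2$shifts$higher == "A"], 0.05)
})

test_that("PCA on TRA genes has valid spectra and separates planted structure", {
  set.seed(52)
  # rank-1 structure plus 1% noise
  load <- rnorm(100)
  score <- c(5, 4, -3, -4, -2)
  x <- outer(load, score) + matrix(rnorm(500, 0, 0.01 * sd(load * mean(abs(score)))),
                                   100, 5)
  dimnames(x) <- list(paste0("g", 1:100), paste0("s", 1:5))
  pc <- pca_on_tra(x, rownames(x))
  expect_true(all(diff(pc$variance_fraction) <= 1e-12))
  expect_lte(sum(pc$variance_fraction), 1 + 1e-9)
  expect_gte(pc$variance_fraction[1], 0.99)

  xd <- cbind(x, dup = x[, 1])
  pcd <- pca_on_tra(xd, rownames(x))
  expect_equal(pcd$scores["s1", ], pcd$scores["dup", ], ignore_attr = TRUE)
})

test_that("correlation clades have unit diagonal and merge replicates first", {
  set.seed(53)
  base <- rnorm(60, 5)
  x <- cbind(r1 = base, r2 = base, other = rnorm(60, 5))
  rownames(x) <- paste0("g", 1:60)
  cc <- correlation_clades(x)
  expect_true(isSymmetric(cc$correlation))
  expect_equal(diag(cc$correlation), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cc$correlation["r1", "r2"], 1)
  expect_equal(cc$tree$height[1], 0, tolerance = 1e-12)
  expect_equal(cc$clades[["r1"]], cc$clades[["r2"]])
  expect_false(cc$clades[["other"]] == cc$clades[["r1"]])

  xz <- cbind(x, flat = rep(2, 60))
  expect_warning(ccz <- correlation_clades(xz), "zero-variance")
  expect_equal(ccz$excluded, "flat")
})

test_that("homolog panels report per-population means and missing genes", {
  x <- rbind(AIRE = c(0, 0, 6, 7), INS = c(1, 1, 5, 5))
  colnames(x) <- paste0("s", 1:4)
  pops <- c("cDC", "cDC", "mTEC", "mTEC")
  hp <- homolog_panel(x, gene_set("tras", c("AIRE", "INS", "GAD2")), pops)
  expect_equal(hp$missing, "GAD2")
  expect_equal(hp$population_means["AIRE", "mTEC"], 6.5)
  expect_equal(hp$population_means["AIRE", "cDC"], 0)

  empty <- homolog_panel(x, gene_set("none", character(0)), pops)
  expect_equal(nrow(empty$per_sample), 0)
})
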
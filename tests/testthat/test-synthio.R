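test_that("LD scores are exact row sums of squared within-block correlations", {
  # singleton blocks: self-correlation only
  p1 <- simulate_ld_panel(5, 1)
  expect_equal(p1$variants$L2, rep(1, 5))
  # three uncorrelated variants in one block
  p2 <- simulate_ld_panel(1, 3, corr = 0)
  expect_equal(p2$variants$L2, rep(1, 3))
  # two variants at correlation 0.8: l = 1 + 0.8^2
  p3 <- simulate_ld_panel(1, 2, corr = 0.8, structure = "exchangeable")
  expect_equal(p3$variants$L2, c(1.64, 1.64))
  # property: reported L2 always matches a recompute from the block matrices
  p4 <- simulate_ld_panel(4, 6, corr = c(0.2, 0.5, 0.7, 0.9))
  recomputed <- unlist(lapply(p4$R, function(R) rowSums(R^2)))
  expect_equal(p4$variants$L2, unname(recomputed))
  expect_true(all(p4$variants$L2 >= 1))
  expect_true(all(diff(p4$variants$BP) > 0))
})

test_that("panel invariants: symmetric PSD blocks summing to M", {
  p <- simulate_ld_panel(3, 4, corr = 0.6)
  expect_equal(sum(vapply(p$R, nrow, integer(1))), p$M)
  for (R in p$R) {
    expect_equal(R, t(R))
    expect_equal(diag(R), rep(1, nrow(R)))
    expect_true(min(eigen(R, symmetric = TRUE)$values) > -1e-12)
  }
})

test_that("identical seed and configuration give byte-identical outputs", {
  panel <- simulate_ld_panel(10, 5, corr = 0.4, seed = 3)
  tr <- sim_truth(0.2, 0.2, 0.3, 5000, 5000)
  expect_identical(simulate_gwas_pair(panel, tr, seed = 11),
                   simulate_gwas_pair(panel, tr, seed = 11))
  conds <- data.frame(id = c("a", "b"), prevalence = c(0.2, 0.1))
  expect_identical(
    simulate_cohort(c(db1 = 500), conds, seed = 5),
    simulate_cohort(c(db1 = 500), conds, seed = 5))
  loc <- simulate_coloc_locus(20, 0.3, "H4", c(0.05, 0.05), 1e4, 1e4, seed = 2)
  loc2 <- simulate_coloc_locus(20, 0.3, "H4", c(0.05, 0.05), 1e4, 1e4, seed = 2)
  expect_identical(loc, loc2)
})

test_that("null GWAS has unit mean chi-square and no cross-trait moment", {
  panel <- simulate_ld_panel(100, 20, corr = 0.5, seed = 1)
  tr <- sim_truth(0, 0, 0, 10000, 10000)
  chi2 <- 0; cross <- 0
  reps <- 10
  for (s in seq_len(reps)) {
    ss <- simulate_gwas_pair(panel, tr, seed = s)
    chi2 <- chi2 + mean(ss[[1]]$Z^2)
    cross <- cross + mean(ss[[1]]$Z * ss[[2]]$Z)
  }
  expect_equal(chi2 / reps, 1, tolerance = 0.05)
  expect_lt(abs(cross / reps), 0.05)
})

test_that("sample overlap induces the predicted cross-trait error moment", {
  # h2 = 0, full overlap, phenotypic correlation 0.5 -> E[z1 z2] = 0.5
  panel <- simulate_ld_panel(100, 20, corr = 0.5, seed = 1)
  tr <- sim_truth(0, 0, 0, 10000, 10000, n_overlap = 10000, pheno_corr = 0.5)
  cross <- vapply(1:20, function(s) {
    ss <- simulate_gwas_pair(panel, tr, seed = s)
    mean(ss[[1]]$Z * ss[[2]]$Z)
  }, numeric(1))
  expect_equal(mean(cross), 0.5, tolerance = 0.05)
})

test_that("z-product regression on LD scores recovers the cross-trait slope", {
  # E[z1 z2 | l] has slope sqrt(n1 n2) rg sqrt(h2_1 h2_2) / M
  panel <- recovery_panel()
  tr <- sim_truth(0.3, 0.3, 0.5, 20000, 20000)
  expected <- sqrt(20000 * 20000) * 0.5 * sqrt(0.3 * 0.3) / panel$M
  slopes <- vapply(1:5, function(s) {
    ss <- simulate_gwas_pair(panel, tr, seed = s)
    unname(coef(lm(ss[[1]]$Z * ss[[2]]$Z ~ panel$variants$L2))[2])
  }, numeric(1))
  # Monte-Carlo tolerance ~ 4.5 standard errors of the 5-seed mean
  expect_equal(mean(slopes), expected, tolerance = 0.15 / expected)
})

test_that("degenerate genetic covariance structures are rejected", {
  panel <- simulate_ld_panel(5, 4, corr = 0.3)
  bad_rg <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3, 3)
  expect_error(
    simulate_gwas_set(panel, h2 = c(0.3, 0.3, 0.3), rg = bad_rg, n = 1e4),
    "positive semi-definite")
  expect_error(sim_truth(0.3, 0.3, 1.5, 1e4, 1e4), "rg")
  expect_error(sim_truth(0.3, 0.3, 0.5, 1e4, 1e4, n_overlap = 2e4), "n_overlap")
})

test_that("cohort generator hits requested marginals and odds ratios", {
  conds <- data.frame(id = c("condA", "condB"), prevalence = c(0.10, 0.10))
  # OR 1: empirical cross-product ratio ~ 1
  pairs1 <- data.frame(a = "condA", b = "condB", or = 1.0)
  co <- simulate_cohort(c(db1 = 50000), conds, pairs1, seed = 8)
  tab <- table(co$condA, co$condB)
  or_hat <- (tab["1","1"] * tab["0","0"]) / (tab["1","0"] * tab["0","1"])
  expect_equal(unname(or_hat), 1, tolerance = 0.15)
  # OR 4 at prevalences (0.10, 0.10): joint cell from the quadratic solution
  pairs4 <- data.frame(a = "condA", b = "condB", or = 4.0)
  co4 <- simulate_cohort(c(db1 = 200000), conds, pairs4, seed = 9)
  tab4 <- table(co4$condA, co4$condB)
  or4 <- (tab4["1","1"] * tab4["0","0"]) / (tab4["1","0"] * tab4["0","1"])
  expect_equal(unname(or4), 4, tolerance = 0.05)
  expect_equal(mean(co4$condA), 0.10, tolerance = 0.05)
  expect_equal(mean(co4$condB), 0.10, tolerance = 0.05)
  # joint cell matches a brute-force grid solution of the 2x2 system
  grid <- seq(1e-5, 0.0999, length.out = 20000)
  feas <- abs((grid * (1 - 0.2 + grid)) / ((0.1 - grid)^2) - 4)
  p11_grid <- grid[which.min(feas)]
  expect_equal(mean(co4$condA * co4$condB), p11_grid, tolerance = 0.05)
})

test_that("cohort covariate effects are recoverable and infeasible ORs rejected", {
  conds <- data.frame(id = "condA", prevalence = 0.2)
  co <- simulate_cohort(c(db1 = 30000), conds, age_coef = 0.05, seed = 4)
  fit <- glm(condA ~ age, family = binomial(), data = co)
  est <- summary(fit)$coefficients["age", ]
  expect_lt(abs(est["Estimate"] - 0.05), 2 * est["Std. Error"])
  expect_true(all(co$age >= 65 & co$age <= 90))
  # marginal/OR combinations whose implied cells degenerate are rejected
  conds2 <- data.frame(id = c("condA", "condB"), prevalence = c(0.9999, 0.9999))
  bad <- data.frame(a = "condA", b = "condB", or = 1e-14)
  expect_error(simulate_cohort(c(db1 = 100), conds2, bad, seed = 1),
               "infeasible")
  expect_error(simulate_cohort(c(db1 = 100), conds2,
                               data.frame(a = "condA", b = "condB", or = 1e300),
                               seed = 1),
               "infeasible")
  # a condition may be the conditional member of at most one pair
  conds3 <- data.frame(id = c("x", "y", "z"), prevalence = c(0.2, 0.2, 0.2))
  dup <- data.frame(a = c("x", "z"), b = c("y", "y"), or = c(2, 2))
  expect_error(simulate_cohort(c(db1 = 100), conds3, dup, seed = 1),
               "more than one pair")
})

test_that("coloc locus generator enforces hypothesis structure", {
  expect_error(
    simulate_coloc_locus(20, 0.1, "H3", c(0.05, 0.05), 1e4, 1e4,
                         causal = c(5, 5)),
    "distinct")
  loc0 <- simulate_coloc_locus(30, 0.2, "H0", c(0, 0), 1e4, 1e4, seed = 6)
  expect_lt(max(abs(loc0[[1]]$Z)), 6)
  tr <- attr(loc0, "coloc_truth")
  expect_equal(tr$hypothesis, "H0")
})
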
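test_that("QC filter applies the boundary rules for MAF and INFO", {
  ss <- data.frame(SNP = paste0("rs", 1:4), CHR = 1, BP = 1:4, A1 = "A",
                   A2 = "G", BETA = 0.1, SE = 0.1, Z = 1, P = 0.3, N = 100,
                   MAF = c(0.0005, 0.2, 0.3, 0.4),
                   INFO = c(0.9, 0.29, 0.30, 0.95))
  out <- qc_filter(ss)
  # MAF 0.0005 fails the strict > 0.001; INFO 0.29 fails, 0.30 is kept
  expect_equal(out$SNP, c("rs3", "rs4"))
  expect_equal(unname(attr(out, "drops")), c(1L, 1L, 0L))
  # all variants failing is an error
  low <- ss; low$MAF <- 0.0005
  expect_error(qc_filter(low), "every variant")
  # absent optional columns skip their filters
  expect_message(out2 <- qc_filter(ss[, 1:10]), "skipped")
  expect_equal(nrow(out2), 4)
})

test_that("a trait is perfectly genetically correlated with itself", {
  panel <- recovery_panel()
  ss <- simulate_gwas_pair(panel, sim_truth(0.3, 0.3, 0.5, 2e4, 2e4),
                           seed = 17)
  r <- estimate_rg(ss[[1]], ss[[1]], panel)
  expect_equal(r$rg, 1, tolerance = 0.02)
})

test_that("rg is symmetric in its arguments and equivariant to sign flips", {
  panel <- recovery_panel()
  ss <- simulate_gwas_pair(panel, sim_truth(0.3, 0.25, 0.4, 2e4, 2e4),
                           seed = 23)
  r12 <- estimate_rg(ss[[1]], ss[[2]], panel)
  r21 <- estimate_rg(ss[[2]], ss[[1]], panel)
  expect_equal(r12$rg, r21$rg, tolerance = 1e-10)
  expect_equal(r12$se, r21$se, tolerance = 1e-10)
  flip <- function(s) { s$BETA <- -s$BETA; s$Z <- -s$Z; s }
  r_neg <- estimate_rg(ss[[1]], flip(ss[[2]]), panel)
  expect_equal(r_neg$rg, -r12$rg, tolerance = 1e-10)
  r_both <- estimate_rg(flip(ss[[1]]), flip(ss[[2]]), panel)
  expect_equal(r_both$rg, r12$rg, tolerance = 1e-10)
})

test_that("jackknife SE equals a brute-force delete-one-block oracle", {
  panel <- simulate_ld_panel(10, 30, corr = seq(0.1, 0.9, length.out = 10),
                             seed = 5)
  ss <- simulate_gwas_set(panel, h2 = 0.4, rg = matrix(1, 1, 1), n = 1e4,
                          seed = 41)[[1]]
  est <- estimate_h2(ss, panel, n_blocks = 10)
  # oracle: same documented algorithm via lm() per deleted block
  l <- panel$variants$L2[match(ss$SNP, panel$variants$SNP)]
  ord <- order(ss$CHR, ss$BP)
  l <- l[ord]; chi2 <- ss$Z[ord]^2; nbar <- mean(ss$N)
  blk <- as.integer(cut(seq_along(l), 10, labels = FALSE))
  w <- rep(1, length(l))
  for (pass in 1:2) {   # unit pass then one refresh from the weighted fit
    p <- coef(lm(chi2 ~ l, weights = w))
    pred <- pmax(p[1] + p[2] * l, 0.1)
    w <- 1 / (pmax(l, 1) * pred^2)
  }
  full <- coef(lm(chi2 ~ l, weights = w))
  expect_equal(est$h2, unname(full[2]) * panel$M / nbar, tolerance = 1e-10)
  expect_equal(est$intercept, unname(full[1]), tolerance = 1e-10)
  theta <- vapply(1:10, function(b) {
    keep <- blk != b
    lk <- l[keep]; ck <- chi2[keep]
    wk <- rep(1, sum(keep))
    for (pass in 1:2) {   # the jackknife re-runs the whole procedure
      p <- coef(lm(ck ~ lk, weights = wk))
      wk <- 1 / (pmax(lk, 1) * pmax(p[1] + p[2] * lk, 0.1)^2)
    }
    unname(coef(lm(ck ~ lk, weights = wk))[2]) * panel$M / nbar
  }, numeric(1))
  se_oracle <- sqrt(9 / 10 * sum((theta - mean(theta))^2))
  expect_equal(est$se, se_oracle, tolerance = 1e-10)
})

test_that("null heritability is estimated as zero with a unit intercept", {
  panel <- recovery_panel()
  hits_h2 <- 0; hits_int <- 0
  for (s in 1:100) {
    ss <- simulate_gwas_set(panel, h2 = 0, rg = matrix(1, 1, 1), n = 1e4,
                            seed = 5000 + s)[[1]]
    est <- estimate_h2(ss, panel, n_blocks = 200)
    if (abs(est$h2) <= 2 * est$se) hits_h2 <- hits_h2 + 1
    if (abs(est$intercept - 1) <= 2 * est$intercept_se) hits_int <- hits_int + 1
  }
  expect_gte(hits_h2, 93)
  expect_gte(hits_int, 93)
})

test_that("heritability z-score gate and rg gate use strict inequalities", {
  gate <- function(z) z > 4
  expect_true(gate(5))
  expect_false(gate(3.9))
  expect_true(within_condition_gate(0.85)$pass)
  expect_false(within_condition_gate(0.80)$pass)   # strict > 0.8
  expect_false(within_condition_gate(0.79)$pass)
  g <- within_condition_gate(NA)
  expect_false(g$pass)
  expect_equal(g$reason, "rg_missing")
})

test_that("degenerate inputs are rejected or reduced with a warning", {
  flat <- simulate_ld_panel(10, 1)   # every L2 = 1
  ss <- simulate_gwas_set(flat, 0.2, matrix(1, 1, 1), n = 1e3, seed = 2)[[1]]
  expect_error(estimate_h2(ss, flat, n_blocks = 2), "degenerate")
  panel <- simulate_ld_panel(20, 2, corr = seq(0, 0.9, length.out = 20))
  ss2 <- simulate_gwas_set(panel, 0.2, matrix(1, 1, 1), n = 1e3, seed = 3)[[1]]
  expect_warning(est <- estimate_h2(ss2, panel, n_blocks = 200),
                 "reduced")
  expect_lt(est$n_blocks, 200)
})

test_that("FDR over an all-null pair battery keeps false positives at bay", {
  panel <- simulate_ld_panel(100, 20, corr = seq(0, 0.9, length.out = 100),
                             seed = 13)
  null_truth <- sim_truth(0.2, 0.2, 0, 1e4, 1e4)
  p <- vapply(1:200, function(s) {
    ss <- simulate_gwas_pair(panel, null_truth, seed = 9000 + s)
    estimate_rg(ss[[1]], ss[[2]], panel, n_blocks = 100)$p
  }, numeric(1))
  q <- bh_fdr(p)
  fp <- sum(q < 0.05)
  # observed false-positive proportion must not significantly exceed 5%
  expect_gt(binom.test(fp, 200, 0.05, alternative = "greater")$p.value, 0.01)
})
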
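mk_pairs <- function(log_or, or_q, rg, rg_q, domain = "within") {
  n <- length(log_or)
  data.frame(pair_id = paste0("p", seq_len(n)),
             domain_relation = rep_len(domain, n),
             log_or = log_or, or_q = or_q, rg = rg, rg_q = rg_q,
             stringsAsFactors = FALSE)
}

test_that("tercile cutoffs are the 1/3 and 2/3 quantiles of the basis subset", {
  p <- mk_pairs(log(1:9), rep(0.01, 9), seq(0.1, 0.9, by = 0.1), rep(0.01, 9))
  ct <- tercile_cutoffs(p, "observational_or")
  expect_equal(ct$lower, 11 / 3, tolerance = 1e-10)   # quantile(1:9, 1/3)
  expect_equal(ct$upper, 19 / 3, tolerance = 1e-10)
  cls <- .bincode(1:9, c(-Inf, ct$lower, ct$upper, Inf))
  expect_equal(as.integer(table(cls)), c(3L, 3L, 3L))  # balanced classes
  expect_error(tercile_cutoffs(mk_pairs(rep(log(2), 5), rep(0.01, 5),
                                        rep(0.3, 5), rep(0.01, 5)),
                               "observational_or"), "degenerate")
  expect_error(tercile_cutoffs(p[1:2, ], "genetic_rg"), "at least 3")
  # non-significant pairs are excluded from the basis
  p$or_q[1:6] <- 0.5
  expect_equal(tercile_cutoffs(p, "observational_or")$n_basis, 3L)
})

test_that("preset cutoffs reproduce the published class boundaries", {
  obs <- preset_cutoffs("observational_or")
  gen <- preset_cutoffs("genetic_rg")
  cls <- function(est, cut) ifelse(est <= cut$lower, "weak",
                                   ifelse(est <= cut$upper, "intermediate", "strong"))
  # boundary membership: lower class includes its upper boundary
  expect_equal(cls(1.46, obs), "weak")
  expect_equal(cls(1.47, obs), "intermediate")
  expect_equal(cls(1.90, obs), "intermediate")
  expect_equal(cls(1.91, obs), "strong")
  expect_equal(cls(0.25, gen), "weak")
  expect_equal(cls(0.48, gen), "intermediate")
  expect_equal(cls(0.49, gen), "strong")
})

test_that("worked pair examples land in the documented quadrants", {
  p <- mk_pairs(log(c(7.53, 0.84, 2.23)), c(1e-6, 0.01, 1e-4),
                c(0.60, 0.20, 0.04), c(1e-4, 0.001, 0.80))
  cl <- classify_pairs(p, preset_cutoffs("observational_or"),
                       preset_cutoffs("genetic_rg"))
  # strong co-occurrence with strong genetic correlation
  expect_equal(cl$quadrant[1], "concordant_positive")
  # under-co-occurring but genetically correlated
  expect_equal(cl$quadrant[2], "genetic_only")
  # co-occurring with null genetics
  expect_equal(cl$quadrant[3], "observational_only")
  expect_equal(cl$obs_class[1], "strong")
  expect_equal(cl$rg_class[3], "not_significant")
  # missing estimates are reported unclassified
  pm <- mk_pairs(c(NA, log(2)), c(NA, 0.01), c(0.3, 0.3), c(0.01, 0.01))
  clm <- classify_pairs(pm, preset_cutoffs("observational_or"),
                        preset_cutoffs("genetic_rg"))
  expect_equal(clm$quadrant[1], "unclassified")
})

test_that("negative concordance and ordering invariance hold", {
  p <- mk_pairs(log(c(0.8, 1.2)), c(0.001, 0.001), c(-0.2, 0.1),
                c(0.001, 0.3))
  cl <- classify_pairs(p, preset_cutoffs("observational_or"),
                       preset_cutoffs("genetic_rg"))
  expect_equal(cl$quadrant[1], "concordant_negative")
  expect_equal(cl$quadrant[2], "observational_only")
  # invariant under row shuffling
  cl_sh <- classify_pairs(p[2:1, ], preset_cutoffs("observational_or"),
                          preset_cutoffs("genetic_rg"))
  expect_equal(cl_sh$quadrant[match(cl$pair_id, cl_sh$pair_id)], cl$quadrant)
})

test_that("crosstab conserves counts and partitions by domain", {
  set.seed(19)
  n <- 120
  p <- mk_pairs(rnorm(n, 0.5, 0.5), runif(n), runif(n, -0.3, 0.8),
                runif(n), domain = sample(c("within", "across"), n, TRUE))
  cl <- classify_pairs(p, preset_cutoffs("observational_or"),
                       preset_cutoffs("genetic_rg"))
  ct_all <- crosstab(cl, "all")
  ct_w <- crosstab(cl, "within")
  ct_a <- crosstab(cl, "across")
  expect_equal(ct_all$n, n)
  expect_equal(ct_w$n + ct_a$n, ct_all$n)
  # marginals sum to the panel total
  expect_equal(sum(ct_all$counts[1:4, 1:4]), ct_all$n)
  expect_equal(unname(ct_all$counts[5, 5]), n)
  expect_equal(unname(colSums(ct_all$counts[1:4, 1:4])),
               unname(ct_all$counts[5, 1:4]))
  # empty input gives an all-zero table
  ct0 <- crosstab(cl[0, ], "all")
  expect_equal(sum(ct0$counts), 0)
})

test_that("published cross-tabulation arithmetic is reproduced from raw counts", {
  all_counts <- rbind(c(100, 765, 53, 7),
                      c(18, 692, 138, 19),
                      c(0, 265, 245, 69),
                      c(0, 18, 69, 88))
  within_counts <- rbind(c(2, 38, 8, 1),
                         c(2, 39, 23, 7),
                         c(0, 9, 36, 25),
                         c(0, 0, 18, 52))
  across_counts <- rbind(c(98, 727, 45, 6),
                         c(16, 653, 115, 12),
                         c(0, 256, 209, 44),
                         c(0, 18, 51, 36))
  s_all <- crosstab_summary(all_counts)
  s_w <- crosstab_summary(within_counts)
  s_a <- crosstab_summary(across_counts)
  expect_equal(s_all$total, 2546)
  expect_equal(s_w$total, 260)
  # within-domain pairs significant on both axes: 260 - 49 - 4 + 2
  expect_equal(s_w$both_significant, 209)
  # strong-genetic row totals
  expect_equal(unname(s_a$rg_row_totals[4]), 105)
  expect_equal(unname(s_all$rg_row_totals[4]), 175)
  # panel percentages at one decimal
  expect_equal(s_all$percent(33), 1.3)
  expect_equal(s_all$percent(s_all$rg_row_totals[4]), 6.9)
  expect_equal(s_w$percent(s_w$both_significant), 80.4)
})

test_that("rg-versus-odds regression matches the closed form", {
  rg <- seq(0.05, 0.6, length.out = 12)
  p <- mk_pairs(2 * rg, rep(0.01, 12), rg, rep(0.01, 12))
  reg <- suppressWarnings(regress_obs_on_rg(p))  # noise-free fit warns
  expect_equal(reg$slope, 2, tolerance = 1e-10)
  expect_equal(reg$percent_odds_per_0.01_rg, 100 * (exp(0.02) - 1),
               tolerance = 1e-10)
  expect_equal(reg$percent_odds_per_0.01_rg, 2.0201, tolerance = 1e-4)
  # slope 0 -> 0% change
  p0 <- mk_pairs(rep(c(0.5, 0.5, 0.5), 2), rep(0.01, 6),
                 rep(c(0.1, 0.3, 0.5), 2), rep(0.01, 6))
  expect_equal(suppressWarnings(regress_obs_on_rg(p0))$percent_odds_per_0.01_rg,
               0, tolerance = 1e-10)
  # degenerate regressor
  pc <- mk_pairs(c(0.1, 0.2, 0.3), rep(0.01, 3), rep(0.4, 3), rep(0.01, 3))
  expect_error(regress_obs_on_rg(pc), "degenerate")
  expect_error(regress_obs_on_rg(p[1:2, ]), "at least 3")
})
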
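# Shared fixtures, built in code at test time.

# heterogeneous-LD panel used by the estimator tests (memoised per session)
recovery_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_ld_panel(200, 25, corr = seq(0, 0.9, length.out = 200),
                                  seed = 424242)
    }
    cache
  }
})

# cohort with explicit 2x2 counts in a single database, no covariate signal
cohort_from_counts <- function(n11, n10, n01, n00, db = "db1",
                               a = "condA", b = "condB") {
  exposure <- c(rep(1, n11 + n10), rep(0, n01 + n00))
  outcome <- c(rep(1, n11), rep(0, n10), rep(1, n01), rep(0, n00))
  n <- length(exposure)
  out <- data.frame(person_id = paste0(db, "_", seq_len(n)), database = db,
                    age = 70, sex = "female", stringsAsFactors = FALSE)
  out[[a]] <- exposure
  out[[b]] <- outcome
  out
}

# independent brute-force step-up FDR rule (the oracle for bh_fdr)
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (rank_i in seq_len(m)) {
    cand <- vapply(rank_i:m, function(j) m * p[ord[j]] / j, numeric(1))
    q[ord[rank_i]] <- min(1, min(cand))
  }
  q
}

# brute-force enumeration of all single-causal configurations (coloc oracle)
coloc_bruteforce <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  n <- length(labf1)
  bf1 <- exp(labf1); bf2 <- exp(labf2)
  h0 <- 1
  h1 <- sum(p1 * bf1)
  h2 <- sum(p2 * bf2)
  h3 <- 0
  for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j != k) h3 <- h3 + p1 * p2 * bf1[j] * bf2[k]
  }
  h4 <- sum(p12 * bf1 * bf2)
  u <- c(h0, h1, h2, h3, h4)
  stats::setNames(u / sum(u), paste0("PP", 0:4))
}
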
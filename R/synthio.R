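#' Simulate a block-diagonal LD reference panel
#'
#' Builds a panel of `n_blocks * block_size` variants whose linkage
#' disequilibrium is block diagonal: variants are correlated only within
#' their block, with either AR(1) decay (`corr^|i-j|`) or exchangeable
#' (constant) correlation. The LD score of variant j, `l2`, is the exact row
#' sum of squared correlations within its block, so `l2 >= 1` always (the
#' self-correlation is included). Positions are strictly increasing.
#'
#' LD structure and positions are deterministic given the arguments; `seed`
#' only draws the per-variant allele pair labels. Alleles are drawn from
#' non-palindromic pairs so that simulated sources harmonise without strand
#' drops by default.
#'
#' @param n_blocks number of independent LD blocks (>= 1).
#' @param block_size variants per block (>= 1).
#' @param corr within-block correlation parameter(s) in `[0, 1)`; for
#'   `"ar1"` the lag-1 decay, for `"exchangeable"` the common correlation.
#'   A vector is recycled across blocks, giving the panel a heterogeneous
#'   LD-score distribution (as real genomes have); a scalar makes all
#'   blocks identical.
#' @param structure `"ar1"` (default) or `"exchangeable"`.
#' @param seed integer seed (allele labels only).
#' @param chr chromosome label for all variants.
#' @param bp_start,bp_spacing base-pair start and spacing (1-based).
#' @return an object of class `ld_panel`: a list with `variants` (data frame
#'   `SNP, CHR, BP, BLOCK, L2, A1, A2`), `M` (total variant count), the list
#'   of per-block correlation matrices `R` and their Cholesky factors `L`.
#' @export
simulate_ld_panel <- function(n_blocks, block_size, corr = 0,
                              structure = c("ar1", "exchangeable"),
                              seed = 1L, chr = 1L,
                              bp_start = 1e6, bp_spacing = 1000) {
  structure <- match.arg(structure)
  if (n_blocks < 1 || block_size < 1) stop("n_blocks and block_size must be >= 1")
  if (!is.numeric(corr) || any(corr < 0) || any(corr >= 1)) {
    stop("within-block correlation parameter must lie in [0, 1)")
  }
  m <- as.integer(block_size)
  idx <- seq_len(m)
  corr_b <- rep_len(corr, n_blocks)
  make_R <- function(rho) switch(structure,
    ar1 = rho^abs(outer(idx, idx, "-")),
    exchangeable = {
      x <- matrix(rho, m, m); diag(x) <- 1; x
    }
  )
  R <- lapply(corr_b, make_R)
  L <- lapply(R, function(Rb) {
    tryCatch(t(chol(Rb)), error = function(e) {
      stop("requested within-block correlation structure is not positive definite: ",
           conditionMessage(e))
    })
  })
  l2_block <- lapply(R, function(Rb) rowSums(Rb^2))
  M <- as.integer(n_blocks) * m
  set.seed(as.integer(seed))
  # non-palindromic allele pairs only
  pairs <- rbind(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"),
                 c("C", "A"), c("G", "A"), c("C", "T"), c("G", "T"))
  pick <- sample.int(nrow(pairs), M, replace = TRUE)
  variants <- data.frame(
    SNP = paste0("rs", seq_len(M)),
    CHR = chr,
    BP = as.integer(bp_start + (seq_len(M) - 1L) * bp_spacing),
    BLOCK = rep(seq_len(n_blocks), each = m),
    L2 = unlist(l2_block, use.names = FALSE),
    A1 = pairs[pick, 1L],
    A2 = pairs[pick, 2L],
    stringsAsFactors = FALSE
  )
  structure(
    list(variants = variants, M = M, n_blocks = as.integer(n_blocks),
         block_size = m, corr = corr_b, corr_structure = structure,
         R = R, L = L),
    class = "ld_panel"
  )
}

#' @export
print.ld_panel <- function(x, ...) {
  cat("LD panel:", x$M, "variants in", x$n_blocks, "blocks of", x$block_size,
      sprintf("(%s, corr %g..%g)\n", x$corr_structure, min(x$corr), max(x$corr)))
  cat("  mean LD score:", round(mean(x$variants$L2), 3), "\n")
  invisible(x)
}

#' Ground-truth container for synthetic GWAS pairs
#'
#' Validated bundle of the generating parameters for a pair of traits:
#' observed-scale SNP heritabilities, the true genetic correlation, per-trait
#' GWAS sample sizes, the number of shared samples and their phenotypic
#' correlation (which together set the cross-trait error correlation
#' `n_overlap * pheno_corr / sqrt(n1 * n2)`).
#'
#' @param h2_1,h2_2 SNP heritability of each trait, in `[0, 1]`.
#' @param rg true genetic correlation in `[-1, 1]`.
#' @param n1,n2 GWAS sample sizes (> 0).
#' @param n_overlap shared samples, `<= min(n1, n2)`.
#' @param pheno_corr phenotypic correlation among shared samples, `[-1, 1]`.
#' @return a list of class `sim_truth`.
#' @export
sim_truth <- function(h2_1, h2_2, rg, n1, n2, n_overlap = 0, pheno_corr = 0) {
  stopifnot_scalar_prob(h2_1, "h2_1")
  stopifnot_scalar_prob(h2_2, "h2_2")
  if (abs(rg) > 1) stop("rg must lie in [-1, 1]")
  if (n1 <= 0 || n2 <= 0) stop("sample sizes must be positive")
  if (n_overlap < 0 || n_overlap > min(n1, n2)) {
    stop("n_overlap must lie in [0, min(n1, n2)]")
  }
  if (abs(pheno_corr) > 1) stop("pheno_corr must lie in [-1, 1]")
  structure(list(h2_1 = h2_1, h2_2 = h2_2, rg = rg, n1 = n1, n2 = n2,
                 n_overlap = n_overlap, pheno_corr = pheno_corr),
            class = "sim_truth")
}

# one summary-statistics data frame from a z vector
.ss_from_z <- function(panel, z, n, condition_id, source_id) {
  v <- panel$variants
  ss <- data.frame(
    SNP = v$SNP, CHR = v$CHR, BP = v$BP, A1 = v$A1, A2 = v$A2,
    BETA = z / sqrt(n), SE = 1 / sqrt(n), Z = z, P = p_from_z(z),
    N = rep(n, nrow(v)), stringsAsFactors = FALSE
  )
  attr(ss, "condition_id") <- condition_id
  attr(ss, "source_id") <- source_id
  ss
}

#' Simulate GWAS summary statistics for a set of genetically correlated traits
#'
#' Per-variant true effects for the K traits are drawn jointly with
#' per-variant covariance `Sigma_g / M`, where
#' `Sigma_g = diag(sqrt(h2)) %*% Rg %*% diag(sqrt(h2))` (standardized-genotype
#' scale, infinitesimal model). The marginal z-score of trait t is
#' `sqrt(n_t) * (R %*% beta_t) + eps_t`, with `eps` having the block LD
#' covariance `R` within trait and cross-trait correlation
#' `n_overlap[t,u] * pheno_corr[t,u] / sqrt(n_t * n_u)` at matched variants.
#' Output tables carry `BETA = Z / sqrt(n)` and `SE = 1 / sqrt(n)`.
#'
#' @param panel an [simulate_ld_panel()] object.
#' @param h2 numeric vector of trait heritabilities (length K).
#' @param rg genetic correlation: scalar (K = 2) or K x K correlation matrix.
#' @param n per-trait sample sizes (length K, recycled if scalar).
#' @param n_overlap scalar or K x K matrix of pairwise shared sample counts.
#' @param pheno_corr scalar or K x K matrix of phenotypic correlations among
#'   shared samples.
#' @param seed integer seed.
#' @param condition_ids,source_ids labels attached to each output table.
#' @param beta_true optional M x K matrix of true per-variant effects,
#'   overriding the random draw (e.g. to simulate several GWAS sources of
#'   the same underlying condition).
#' @return a list of K summary-statistics data frames
#'   (`SNP, CHR, BP, A1, A2, BETA, SE, Z, P, N`), each carrying its true
#'   effect vector in attribute `beta_true`.
#' @export
simulate_gwas_set <- function(panel, h2, rg, n, n_overlap = 0, pheno_corr = 0,
                              seed = 1L,
                              condition_ids = paste0("trait", seq_along(h2)),
                              source_ids = "synthetic", beta_true = NULL) {
  K <- length(h2)
  if (K < 1) stop("need at least one trait")
  n <- as.numeric(rep_len(n, K))
  if (is.matrix(rg)) Rg <- rg else {
    if (K == 1) Rg <- matrix(1, 1, 1)
    else if (K == 2) Rg <- matrix(c(1, rg, rg, 1), 2, 2)
    else stop("for K > 2 traits, rg must be a K x K correlation matrix")
  }
  for (h in h2) stopifnot_scalar_prob(h, "h2")
  Sigma_g <- diag(sqrt(h2), K) %*% Rg %*% diag(sqrt(h2), K)
  Cg <- tryCatch(chol(Sigma_g / panel$M, pivot = FALSE),
                 error = function(e) NULL)
  if (is.null(Cg)) {
    # semi-definite cases (h2 = 0, |rg| = 1) handled via eigendecomposition
    eg <- eigen(Sigma_g / panel$M, symmetric = TRUE)
    if (min(eg$values) < -1e-12) {
      stop("implied genetic covariance matrix is not positive semi-definite")
    }
    Cg <- t(eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), K))
  }
  ovl <- if (is.matrix(n_overlap)) n_overlap else matrix(n_overlap, K, K)
  pc <- if (is.matrix(pheno_corr)) pheno_corr else matrix(pheno_corr, K, K)
  P <- diag(1, K)
  for (t in seq_len(K)) for (u in seq_len(K)) {
    if (t != u) {
      if (ovl[t, u] > min(n[t], n[u])) stop("n_overlap exceeds min(n1, n2)")
      P[t, u] <- ovl[t, u] * pc[t, u] / sqrt(n[t] * n[u])
    }
  }
  eP <- eigen(P, symmetric = TRUE)
  if (min(eP$values) < -1e-12) {
    stop("implied error-correlation matrix is not positive semi-definite")
  }
  Cp <- t(eP$vectors %*% diag(sqrt(pmax(eP$values, 0)), K))

  set.seed(as.integer(seed))
  M <- panel$M
  beta <- if (is.null(beta_true)) {
    matrix(stats::rnorm(M * K), M, K) %*% Cg         # true effects, M x K
  } else {
    if (!is.matrix(beta_true) || !all(dim(beta_true) == c(M, K))) {
      stop("beta_true must be an M x K matrix")
    }
    beta_true
  }
  m <- panel$block_size
  z <- matrix(0, M, K)
  sn <- sqrt(n)
  for (b in seq_len(panel$n_blocks)) {
    rows <- ((b - 1L) * m + 1L):(b * m)
    sig <- panel$R[[b]] %*% beta[rows, , drop = FALSE]      # R beta
    eps <- panel$L[[b]] %*% matrix(stats::rnorm(m * K), m, K) %*% Cp
    z[rows, ] <- sweep(sig, 2L, sn, "*") + eps
  }
  condition_ids <- rep_len(condition_ids, K)
  source_ids <- rep_len(source_ids, K)
  lapply(seq_len(K), function(t) {
    ss <- .ss_from_z(panel, z[, t], n[t], condition_ids[t], source_ids[t])
    attr(ss, "beta_true") <- beta[, t]
    ss
  })
}

#' Simulate a pair of GWAS summary-statistics tables from a ground truth
#'
#' Two-trait wrapper around [simulate_gwas_set()] driven by a validated
#' [sim_truth()] bundle.
#'
#' @param panel an [simulate_ld_panel()] object.
#' @param truth a [sim_truth()] object.
#' @param seed integer seed.
#' @inheritParams simulate_gwas_set
#' @return list of two summary-statistics data frames.
#' @export
simulate_gwas_pair <- function(panel, truth, seed = 1L,
                               condition_ids = c("trait1", "trait2"),
                               source_ids = "synthetic") {
  if (!inherits(truth, "sim_truth")) truth <- do.call(sim_truth, truth)
  simulate_gwas_set(panel,
                    h2 = c(truth$h2_1, truth$h2_2), rg = truth$rg,
                    n = c(truth$n1, truth$n2), n_overlap = truth$n_overlap,
                    pheno_corr = truth$pheno_corr, seed = seed,
                    condition_ids = condition_ids, source_ids = source_ids)
}

# solve the joint-exposure cell probability of a 2x2 table with marginals
# (pa, pb) and odds ratio psi; vectorised over persons
.joint_cell <- function(pa, pb, psi) {
  if (psi == 1) return(pa * pb)
  s <- 1 + (pa + pb) * (psi - 1)
  disc <- s^2 - 4 * psi * (psi - 1) * pa * pb
  if (any(!is.finite(disc) | disc < 0)) {
    stop("infeasible (prevalence, odds ratio) combination")
  }
  (s - sqrt(disc)) / (2 * (psi - 1))
}

#' Simulate a person-level multimorbidity cohort
#'
#' Generates one or more database cohorts of persons aged >= 65 with binary
#' indicators per condition. Marginal prevalences are modulated on the
#' log-odds scale by centred age and by sex; for each configured pair
#' `(a, b, or)` the indicator of `b` is drawn conditional on `a` from the
#' exact 2x2 cell probabilities solving the person-specific marginals and
#' the requested odds ratio, so the age/sex-adjusted odds ratio equals the
#' target exactly.
#'
#' Each condition may be the conditional ("b") member of at most one
#' configured pair (a dependency forest); unconfigured pairs are
#' conditionally independent given age and sex.
#'
#' @param n_per_database named integer vector: persons per database.
#' @param conditions data frame with column `id` and either a single
#'   `prevalence` column or one prevalence column per database name.
#' @param pair_ors optional data frame `a, b, or` of target odds ratios.
#' @param age_coef per-year log-odds coefficient on every condition (age
#'   centred at the midpoint of `age_range`).
#' @param sex_coef male-vs-female log-odds shift on every condition.
#' @param age_range ages drawn uniformly on this range (minimum 65).
#' @param sex_prob probability of male sex.
#' @param seed integer seed.
#' @return a `CohortTable` data frame: `person_id, database, age, sex` and
#'   one 0/1 column per condition.
#' @export
simulate_cohort <- function(n_per_database, conditions, pair_ors = NULL,
                            age_coef = 0, sex_coef = 0,
                            age_range = c(65, 90), sex_prob = 0.457,
                            seed = 1L) {
  if (is.null(names(n_per_database))) {
    names(n_per_database) <- paste0("db", seq_along(n_per_database))
  }
  if (age_range[1] < 65) stop("cohort eligibility requires minimum age 65")
  ids <- as.character(conditions$id)
  dbs <- names(n_per_database)
  prev <- matrix(NA_real_, length(ids), length(dbs),
                 dimnames = list(ids, dbs))
  for (d in dbs) {
    col <- if (d %in% names(conditions)) conditions[[d]] else conditions$prevalence
    if (is.null(col)) stop("no prevalence column for database '", d, "'")
    prev[, d] <- col
  }
  if (any(prev <= 0 | prev >= 1)) stop("prevalences must lie in (0, 1)")

  # dependency forest: each condition conditional on at most one parent
  parent <- stats::setNames(rep(NA_character_, length(ids)), ids)
  psi <- stats::setNames(rep(NA_real_, length(ids)), ids)
  if (!is.null(pair_ors) && nrow(pair_ors) > 0) {
    for (i in seq_len(nrow(pair_ors))) {
      a <- as.character(pair_ors$a[i]); b <- as.character(pair_ors$b[i])
      if (!a %in% ids || !b %in% ids) stop("pair references unknown condition")
      if (!is.na(parent[b])) {
        stop("condition '", b, "' is the conditional member of more than one pair")
      }
      if (pair_ors$or[i] <= 0) stop("odds ratios must be positive")
      parent[b] <- a; psi[b] <- pair_ors$or[i]
    }
  }
  order_ids <- character(0)
  remaining <- ids
  while (length(remaining) > 0) {
    ready <- remaining[is.na(parent[remaining]) |
                         parent[remaining] %in% order_ids]
    if (length(ready) == 0) stop("pair dependency structure contains a cycle")
    order_ids <- c(order_ids, ready)
    remaining <- setdiff(remaining, ready)
  }

  set.seed(as.integer(seed))
  mid_age <- mean(age_range)
  out <- vector("list", length(dbs))
  for (di in seq_along(dbs)) {
    d <- dbs[di]
    n <- n_per_database[[d]]
    age <- stats::runif(n, age_range[1], age_range[2])
    sex <- ifelse(stats::rbinom(n, 1, sex_prob) == 1, "male", "female")
    shift <- age_coef * (age - mid_age) + sex_coef * (sex == "male")
    tab <- data.frame(person_id = paste0(d, "_", seq_len(n)),
                      database = d, age = age, sex = sex,
                      stringsAsFactors = FALSE)
    pmat <- list()
    for (cid in order_ids) {
      p_i <- stats::plogis(stats::qlogis(prev[cid, d]) + shift)
      if (is.na(parent[cid])) {
        tab[[cid]] <- stats::rbinom(n, 1, p_i)
      } else {
        pa_i <- pmat[[parent[cid]]]
        p11 <- .joint_cell(pa_i, p_i, psi[cid])
        bad <- p11 <= 0 | p11 >= pmin(pa_i, p_i) |
          (pa_i - p11) < 0 | (p_i - p11) < 0 |
          (1 - pa_i - p_i + p11) <= 0
        if (any(bad)) {
          j <- which(bad)[1]
          stop(sprintf(
            "infeasible (prevalence, odds ratio) combination for '%s': joint cell %.4f with marginals (%.4f, %.4f)",
            cid, p11[j], pa_i[j], p_i[j]))
        }
        a_val <- tab[[parent[cid]]]
        p_cond <- ifelse(a_val == 1, p11 / pa_i, (p_i - p11) / (1 - pa_i))
        tab[[cid]] <- stats::rbinom(n, 1, p_cond)
      }
      pmat[[cid]] <- p_i
    }
    out[[di]] <- tab[, c("person_id", "database", "age", "sex", ids)]
  }
  do.call(rbind, out)
}

#' Simulate a colocalisation locus under one of the five hypotheses
#'
#' Generates two traits' marginal summary statistics at a single region with
#' AR(1) LD (`ld_corr^|i-j|`): `betahat = R %*% beta_true + noise`, noise
#' covariance `R / n_t`, `SE = 1 / sqrt(n_t)`. The causal configuration
#' follows the requested hypothesis: H0 no effects; H1/H2 one causal variant
#' in trait 1/2 only; H3 two distinct causal variants; H4 one shared causal
#' variant.
#'
#' @param n_variants number of variants in the region.
#' @param ld_corr AR(1) lag-1 correlation in `[0, 1)`.
#' @param hypothesis one of `"H0" ... "H4"`.
#' @param effect_sizes length-2 standardized effect sizes (per trait) at the
#'   causal variant(s).
#' @param n1,n2 per-trait sample sizes.
#' @param seed integer seed.
#' @param causal causal variant index (H1/H2/H4) or two distinct indices
#'   (H3); defaults to central / quartile positions.
#' @param chr,bp_start,bp_span position layout of the region.
#' @return list of two summary-statistics data frames with attribute
#'   `coloc_truth` (hypothesis and causal indices).
#' @export
simulate_coloc_locus <- function(n_variants, ld_corr, hypothesis,
                                 effect_sizes, n1, n2, seed = 1L,
                                 causal = NULL, chr = 1L,
                                 bp_start = 1e6, bp_span = 2e5) {
  hypothesis <- match.arg(hypothesis, c("H0", "H1", "H2", "H3", "H4"))
  if (ld_corr < 0 || ld_corr >= 1) stop("ld_corr must lie in [0, 1)")
  nv <- as.integer(n_variants)
  if (is.null(causal)) {
    causal <- if (hypothesis == "H3") {
      c(max(1L, round(nv / 4)), min(nv, round(3 * nv / 4)))
    } else ceiling(nv / 2)
  }
  if (any(causal < 1 | causal > nv)) stop("causal indices out of range")
  if (hypothesis == "H3") {
    if (length(causal) != 2 || causal[1] == causal[2]) {
      stop("H3 requires two distinct causal variant indices")
    }
  }
  idx <- seq_len(nv)
  R <- ld_corr^abs(outer(idx, idx, "-"))
  L <- t(chol(R))
  b1 <- b2 <- numeric(nv)
  if (hypothesis == "H1") b1[causal[1]] <- effect_sizes[1]
  if (hypothesis == "H2") b2[causal[1]] <- effect_sizes[2]
  if (hypothesis == "H3") { b1[causal[1]] <- effect_sizes[1]; b2[causal[2]] <- effect_sizes[2] }
  if (hypothesis == "H4") { b1[causal[1]] <- effect_sizes[1]; b2[causal[1]] <- effect_sizes[2] }
  set.seed(as.integer(seed))
  bh1 <- as.vector(R %*% b1 + L %*% stats::rnorm(nv) / sqrt(n1))
  bh2 <- as.vector(R %*% b2 + L %*% stats::rnorm(nv) / sqrt(n2))
  bp <- as.integer(round(seq(bp_start, bp_start + bp_span, length.out = nv)))
  mk <- function(bh, n, cond) {
    ss <- data.frame(SNP = paste0("rs", idx), CHR = chr, BP = bp,
                     A1 = "A", A2 = "G", BETA = bh, SE = 1 / sqrt(n),
                     Z = bh * sqrt(n), P = p_from_z(bh * sqrt(n)),
                     N = rep(n, nv), stringsAsFactors = FALSE)
    attr(ss, "condition_id") <- cond
    ss
  }
  out <- list(mk(bh1, n1, "trait1"), mk(bh2, n2, "trait2"))
  attr(out, "coloc_truth") <- list(hypothesis = hypothesis, causal = causal)
  out
}
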
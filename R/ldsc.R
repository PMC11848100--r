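# LD-score regression: univariate heritability and cross-trait genetic
# correlation from GWAS summary statistics plus per-variant LD scores.
#
# Model (observed scale, standardized genotypes):
#   E[chi2_j]    = 1 + n*a       + (n * h2 / M)            * l_j
#   E[z1_j z2_j] = overlap term  + (sqrt(n1 n2) * rho_g/M) * l_j
# Estimation is a three-pass weighted regression: a unit-weight pass gives
# provisional fitted means, which define variance-model weights for a
# weighted pass; the weights are refreshed once more from that weighted
# fit (an unweighted first pass is dominated by the high-LD variants and
# yields unstable weights) before the final fit. Standard errors come from
# a delete-one-block jackknife over contiguous variant blocks that re-runs
# the entire procedure, weights included, on every leave-one-block subset.

# contiguous jackknife block assignment (position order), reducing the
# block count when there are fewer than 2 variants per block
.jk_blocks <- function(nv, n_blocks) {
  if (nv < 2L * n_blocks) {
    n_blocks <- max(2L, nv %/% 2L)
    warning("fewer variants than 2 * n_blocks; reduced to ", n_blocks, " blocks")
  }
  as.integer(cut(seq_len(nv), breaks = n_blocks, labels = FALSE))
}

# weighted simple regression via accumulated sums
.wls <- function(x, y, w) {
  W <- sum(w); Sx <- sum(w * x); Sxx <- sum(w * x * x)
  Sy <- sum(w * y); Sxy <- sum(w * x * y)
  det <- W * Sxx - Sx^2
  slope <- (W * Sxy - Sx * Sy) / det
  c(int = (Sy - slope * Sx) / W, slope = slope)
}

# three-pass weighted fit of y on x: unit weights, then two refreshes of
# the variance-model weights 1 / (lf * pred^2)
.wls_3pass <- function(x, y, lf) {
  w <- rep(1, length(x))
  for (pass in 1:2) {
    f <- .wls(x, y, w)
    pred <- pmax(f["int"] + f["slope"] * x, 0.1)
    w <- 1 / (lf * pred^2)
  }
  .wls(x, y, w)
}

.jack_se <- function(theta) {
  theta <- theta[is.finite(theta)]
  B <- length(theta)
  if (B < 2) return(NA_real_)
  sqrt((B - 1) / B * sum((theta - mean(theta))^2))
}

#' Variant quality-control filter for summary statistics
#'
#' Drops variants failing minor-allele-frequency (strict `>`), imputation
#' INFO (inclusive `>=`) and maximum chi-square filters. The `MAF` and
#' `INFO` columns are optional: an absent column skips its filter with a
#' message.
#'
#' @param ss summary-statistics data frame.
#' @param maf_min MAF threshold (keep MAF > maf_min), default 0.001.
#' @param info_min INFO threshold (keep INFO >= info_min), default 0.3.
#' @param chi2_max drop variants with `Z^2 > chi2_max` (default `Inf`).
#' @return the filtered table, with attribute `drops` counting removals
#'   per rule. Errors if every variant is removed.
#' @export
qc_filter <- function(ss, maf_min = 0.001, info_min = 0.3, chi2_max = Inf) {
  drops <- c(maf = 0L, info = 0L, chi2 = 0L)
  keep <- rep(TRUE, nrow(ss))
  if ("MAF" %in% names(ss)) {
    bad <- !(ss$MAF > maf_min)
    drops["maf"] <- sum(bad & keep); keep <- keep & !bad
  } else message("no MAF column: allele-frequency filter skipped")
  if ("INFO" %in% names(ss)) {
    bad <- !(ss$INFO >= info_min)
    drops["info"] <- sum(bad & keep); keep <- keep & !bad
  } else message("no INFO column: imputation-quality filter skipped")
  if (is.finite(chi2_max)) {
    z <- if ("Z" %in% names(ss)) ss$Z else ss$BETA / ss$SE
    bad <- z^2 > chi2_max
    drops["chi2"] <- sum(bad & keep); keep <- keep & !bad
  }
  if (!any(keep)) stop("quality-control filters removed every variant")
  out <- ss[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drops") <- drops
  out
}

# align one or two summary-stats tables with the panel's LD scores
.ldsc_prepare <- function(ss, panel) {
  v <- if (inherits(panel, "ld_panel")) panel$variants else panel
  shared <- intersect(ss$SNP, v$SNP)
  if (length(shared) < 10) stop("too few variants shared with the LD panel")
  ss <- ss[match(shared, ss$SNP), , drop = FALSE]
  ss$L2 <- v$L2[match(shared, v$SNP)]
  ss[order(ss$CHR, ss$BP), , drop = FALSE]
}

#' Estimate SNP heritability by LD-score regression
#'
#' Weighted regression of per-variant chi-square statistics on LD scores:
#' the slope times `M / mean(n)` is the observed-scale SNP heritability and
#' the intercept captures confounding/overlap inflation. Weights
#' `1 / (l_j * E[chi2_j]^2)` are built from an initial unit-weight pass
#' and refreshed once from the resulting weighted fit; the standard error
#' is a delete-one-block jackknife over `n_blocks` contiguous variant
#' blocks that re-runs the full weighting procedure on every subset.
#'
#' @param ss summary-statistics data frame (needs `SNP, Z` or `BETA/SE`,
#'   `N`).
#' @param panel an `ld_panel` (or its `variants` table) supplying `L2`;
#'   when a plain table is given, `M` must be supplied.
#' @param n_blocks jackknife block count (default 200).
#' @param M panel variant count; defaults to `panel$M`.
#' @return object of class `h2_estimate`: `h2, se, z_h2, intercept,
#'   intercept_se, mean_chi2, M, n_blocks, n_variants`.
#' @export
estimate_h2 <- function(ss, panel, n_blocks = 200, M = NULL) {
  M <- M %||% (if (inherits(panel, "ld_panel")) panel$M else
    stop("M must be supplied when panel is not an ld_panel"))
  d <- .ldsc_prepare(ss, panel)
  if ("Z" %in% names(d)) z <- d$Z else z <- d$BETA / d$SE
  x <- d$L2
  if (stats::var(x) < 1e-12) stop("degenerate LD-score variance")
  chi2 <- z^2
  nbar <- mean(d$N)
  block <- .jk_blocks(length(x), n_blocks)
  B <- max(block)
  lf <- pmax(x, 1)
  full <- .wls_3pass(x, chi2, lf)
  jack <- t(vapply(seq_len(B), function(b) {
    k <- block != b
    .wls_3pass(x[k], chi2[k], lf[k])
  }, c(int = 0, slope = 0)))
  h2 <- unname(full["slope"]) * M / nbar
  se <- .jack_se(jack[, "slope"] * M / nbar)
  int_se <- .jack_se(jack[, "int"])
  structure(list(h2 = h2, se = se, z_h2 = h2 / se,
                 intercept = unname(full["int"]), intercept_se = int_se,
                 mean_chi2 = mean(chi2), M = M, n_blocks = B,
                 n_variants = length(x)),
            class = "h2_estimate")
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("LDSC h2 (observed scale): %.4f (se %.4f, z = %.2f)\n",
              x$h2, x$se, x$z_h2))
  cat(sprintf("  intercept %.4f (se %.4f); mean chi2 %.3f; %d variants, %d blocks\n",
              x$intercept, x$intercept_se, x$mean_chi2, x$n_variants, x$n_blocks))
  invisible(x)
}

#' Estimate cross-trait genetic correlation by LD-score regression
#'
#' Weighted regression of the per-variant z-score products on LD scores:
#' the slope times `M / sqrt(n1 n2)` is the genetic covariance `rho_g`, and
#' the intercept estimates the sample-overlap term
#' `n_overlap * pheno_corr / sqrt(n1 n2)`. The genetic correlation is
#' `rg = rho_g / sqrt(h2_1 * h2_2)` with both heritabilities estimated on
#' the same harmonised variant set; its standard error is a
#' delete-one-block jackknife of the full ratio. Reported rg is clipped to
#' `[-1.25, 1.25]` with a flag when the raw value leaves `[-1, 1]`.
#'
#' @param ss1,ss2 summary-statistics data frames (harmonised internally via
#'   [harmonise_alleles()] when allele columns are present).
#' @param panel an `ld_panel` (or its `variants` table).
#' @param n_blocks jackknife block count (default 200).
#' @param M panel variant count; defaults to `panel$M`.
#' @return object of class `rg_estimate`: `gencov, rg, se, z, p,
#'   intercept, intercept_se, h2_1, h2_2, clipped, reason, n_variants,
#'   n_blocks`. When either heritability estimate is non-positive, `rg` is
#'   reported missing with a reason.
#' @export
estimate_rg <- function(ss1, ss2, panel, n_blocks = 200, M = NULL) {
  M <- M %||% (if (inherits(panel, "ld_panel")) panel$M else
    stop("M must be supplied when panel is not an ld_panel"))
  if (all(c("A1", "A2") %in% names(ss1)) && all(c("A1", "A2") %in% names(ss2))) {
    h <- harmonise_alleles(ss1, ss2)
    ss1 <- h$ref; ss2 <- h$other
  } else {
    shared <- intersect(ss1$SNP, ss2$SNP)
    ss1 <- ss1[match(shared, ss1$SNP), , drop = FALSE]
    ss2 <- ss2[match(shared, ss2$SNP), , drop = FALSE]
  }
  d1 <- .ldsc_prepare(ss1, panel)
  d2 <- ss2[match(d1$SNP, ss2$SNP), , drop = FALSE]
  z1 <- if ("Z" %in% names(d1)) d1$Z else d1$BETA / d1$SE
  z2 <- if ("Z" %in% names(d2)) d2$Z else d2$BETA / d2$SE
  x <- d1$L2
  if (stats::var(x) < 1e-12) stop("degenerate LD-score variance")
  n1 <- mean(d1$N); n2 <- mean(d2$N)
  block <- .jk_blocks(length(x), n_blocks)
  B <- max(block)
  y11 <- z1^2; y22 <- z2^2; y12 <- z1 * z2
  lf <- pmax(x, 1)
  # jointly iterated three-series fit: the cross-product weights use the
  # current fitted means of all three regressions
  fit_pair <- function(k) {
    xx <- x[k]; lfk <- lf[k]
    a <- y11[k]; bb <- y22[k]; ab <- y12[k]
    w11 <- w22 <- w12 <- rep(1, length(xx))
    for (pass in 1:2) {
      f11 <- .wls(xx, a, w11); f22 <- .wls(xx, bb, w22); f12 <- .wls(xx, ab, w12)
      e11 <- pmax(f11[["int"]] + f11[["slope"]] * xx, 0.1)
      e22 <- pmax(f22[["int"]] + f22[["slope"]] * xx, 0.1)
      e12 <- f12[["int"]] + f12[["slope"]] * xx
      w11 <- 1 / (lfk * e11^2)
      w22 <- 1 / (lfk * e22^2)
      w12 <- 1 / (lfk * (e11 * e22 + e12^2))
    }
    f12 <- .wls(xx, ab, w12)
    c(s11 = unname(.wls(xx, a, w11)[["slope"]]),
      s22 = unname(.wls(xx, bb, w22)[["slope"]]),
      i12 = unname(f12[["int"]]), s12 = unname(f12[["slope"]]))
  }
  full <- fit_pair(rep(TRUE, length(x)))
  jack <- t(vapply(seq_len(B), function(b) fit_pair(block != b),
                   c(s11 = 0, s22 = 0, i12 = 0, s12 = 0)))
  h2_1 <- full[["s11"]] * M / n1
  h2_2 <- full[["s22"]] * M / n2
  gencov <- full[["s12"]] * M / sqrt(n1 * n2)
  intercept <- full[["i12"]]
  intercept_se <- .jack_se(jack[, "i12"])
  out <- list(gencov = gencov, rg = NA_real_, se = NA_real_, z = NA_real_,
              p = NA_real_, intercept = intercept,
              intercept_se = intercept_se, h2_1 = h2_1, h2_2 = h2_2,
              clipped = FALSE, reason = NA_character_,
              n_variants = length(x), n_blocks = B)
  if (h2_1 <= 0 || h2_2 <= 0) {
    out$reason <- "non-positive heritability estimate"
    return(structure(out, class = "rg_estimate"))
  }
  rg_raw <- gencov / sqrt(h2_1 * h2_2)
  h2_1j <- jack[, "s11"] * M / n1
  h2_2j <- jack[, "s22"] * M / n2
  gcj <- jack[, "s12"] * M / sqrt(n1 * n2)
  rg_j <- ifelse(h2_1j > 0 & h2_2j > 0, gcj / sqrt(h2_1j * h2_2j), NA_real_)
  se <- .jack_se(rg_j)
  out$rg <- max(-1.25, min(1.25, rg_raw))
  out$clipped <- abs(rg_raw) > 1
  out$se <- se
  out$z <- rg_raw / se
  out$p <- p_from_z(out$z)
  structure(out, class = "rg_estimate")
}

#' @export
print.rg_estimate <- function(x, ...) {
  if (is.na(x$rg)) {
    cat("LDSC rg: undefined (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("LDSC rg: %.4f (se %.4f, p = %.3g)%s\n", x$rg, x$se, x$p,
                if (x$clipped) " [clipped]" else ""))
    cat(sprintf("  gencov %.4f; cross-trait intercept %.4f (se %.4f); h2: %.4f / %.4f\n",
                x$gencov, x$intercept, x$intercept_se, x$h2_1, x$h2_2))
  }
  invisible(x)
}

#' Within-condition genetic-correlation gate
#'
#' A candidate GWAS source passes only when its within-condition genetic
#' correlation with the reference source is strictly greater than the
#' threshold; a missing estimate fails with a reason code.
#'
#' @param rg_result an `rg_estimate`, or a bare numeric rg.
#' @param threshold gate (strict `>`), default 0.8.
#' @return list `pass` (logical) and `reason`.
#' @export
within_condition_gate <- function(rg_result, threshold = 0.8) {
  rg <- if (inherits(rg_result, "rg_estimate")) rg_result$rg else rg_result
  if (is.null(rg) || length(rg) != 1 || is.na(rg)) {
    return(list(pass = FALSE, reason = "rg_missing"))
  }
  if (rg > threshold) list(pass = TRUE, reason = "rg_above_threshold")
  else list(pass = FALSE, reason = "rg_at_or_below_threshold")
}
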
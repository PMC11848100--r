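#' Colocalisation configuration
#'
#' Defaults follow the conventional single-causal-variant colocalisation
#' setup: genome-wide significance 5e-8 for lead variants, a 250 kb lead
#' separation window, prior probabilities p1 = p2 = 1e-4 (variant causal
#' for one trait) and p12 = 1e-5 (shared causal variant), prior effect
#' standard deviation 0.15 for quantitative and 0.2 for binary traits, and
#' a PP4 decision threshold of 0.9.
#'
#' @param p_threshold lead-variant significance threshold.
#' @param window lead separation / region half-width in base pairs
#'   (compared strictly).
#' @param p1,p2,p12 prior probabilities (must satisfy `p1 + p2 + p12 < 1`).
#' @param prior_sd1,prior_sd2 per-trait prior effect standard deviations.
#' @param pp4_threshold decision threshold on PP4.
#' @return list of class `coloc_config`.
#' @export
coloc_config <- function(p_threshold = 5e-8, window = 250000,
                         p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         prior_sd1 = 0.2, prior_sd2 = 0.2,
                         pp4_threshold = 0.9) {
  if (p1 + p2 + p12 >= 1) stop("p1 + p2 + p12 must be < 1")
  if (window <= 0) stop("window must be positive")
  structure(list(p_threshold = p_threshold, window = window,
                 p1 = p1, p2 = p2, p12 = p12,
                 prior_sd1 = prior_sd1, prior_sd2 = prior_sd2,
                 pp4_threshold = pp4_threshold),
            class = "coloc_config")
}

#' Greedy distance clumping of lead variants
#'
#' Repeatedly takes the smallest-p variant below the significance
#' threshold and suppresses all variants within `min_gap` base pairs on
#' the same chromosome, until none remain. Ties on p are broken by
#' position, then id.
#'
#' @param ss summary-statistics data frame (`SNP, CHR, BP, P`).
#' @param threshold significance threshold (default 5e-8).
#' @param min_gap suppression distance in base pairs (strict `<`).
#' @return data frame of lead variants (possibly empty).
#' @export
find_lead_snps <- function(ss, threshold = 5e-8, min_gap = 250000) {
  cand <- ss[ss$P < threshold, , drop = FALSE]
  cand <- cand[order(cand$P, cand$BP, cand$SNP), , drop = FALSE]
  leads <- cand[0, , drop = FALSE]
  while (nrow(cand) > 0) {
    top <- cand[1, , drop = FALSE]
    leads <- rbind(leads, top)
    near <- cand$CHR == top$CHR & abs(cand$BP - top$BP) < min_gap
    cand <- cand[!near, , drop = FALSE]
  }
  rownames(leads) <- NULL
  leads
}

#' Shared regions around cross-trait lead pairs
#'
#' For every pair of leads (one per trait) on the same chromosome with
#' positions closer than `window`, a candidate region
#' `[min(pos) - window, max(pos) + window]` is formed; overlapping regions
#' are merged. Coordinates are 1-based inclusive and the start is floored
#' at 1.
#'
#' @param leads1,leads2 lead-variant data frames from [find_lead_snps()].
#' @param window separation / padding distance in base pairs (strict `<`).
#' @return data frame `chr, start, end` (possibly empty).
#' @export
define_shared_regions <- function(leads1, leads2, window = 250000) {
  empty <- data.frame(chr = integer(0), start = integer(0), end = integer(0))
  if (nrow(leads1) == 0 || nrow(leads2) == 0) return(empty)
  regs <- list()
  for (i in seq_len(nrow(leads1))) for (j in seq_len(nrow(leads2))) {
    if (leads1$CHR[i] == leads2$CHR[j] &&
        abs(leads1$BP[i] - leads2$BP[j]) < window) {
      lo <- min(leads1$BP[i], leads2$BP[j]) - window
      hi <- max(leads1$BP[i], leads2$BP[j]) + window
      regs[[length(regs) + 1L]] <- data.frame(chr = leads1$CHR[i],
                                              start = max(1, lo), end = hi)
    }
  }
  if (length(regs) == 0) return(empty)
  r <- do.call(rbind, regs)
  r <- r[order(r$chr, r$start), , drop = FALSE]
  merged <- r[1, , drop = FALSE]
  if (nrow(r) > 1) for (i in 2:nrow(r)) {
    last <- nrow(merged)
    if (r$chr[i] == merged$chr[last] && r$start[i] <= merged$end[last]) {
      merged$end[last] <- max(merged$end[last], r$end[i])
    } else {
      merged <- rbind(merged, r[i, , drop = FALSE])
    }
  }
  rownames(merged) <- NULL
  merged
}

#' Wakefield log approximate Bayes factor
#'
#' For one variant with estimate `beta`, standard error `se` and prior
#' effect standard deviation `prior_sd`: with `V = se^2`, `W = prior_sd^2`,
#' `r = W / (V + W)` and `z = beta / se`, the log approximate Bayes factor
#' of association versus null is `0.5 * (log(1 - r) + r * z^2)`.
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), all > 0.
#' @param prior_sd prior effect standard deviation.
#' @return numeric vector of log-ABFs.
#' @export
log_abf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stop("standard errors must be positive")
  V <- se^2
  r <- prior_sd^2 / (V + prior_sd^2)
  z <- beta / se
  0.5 * (log(1 - r) + r * z^2)
}

#' Posterior probabilities of the five colocalisation hypotheses
#'
#' Single-causal-variant model over an aligned region: with per-variant
#' log-ABFs for the two traits, the hypothesis sums are
#' `S1 = sum(exp(labf1))`, `S2 = sum(exp(labf2))`,
#' `S12 = sum(exp(labf1 + labf2))` and the distinct-causal sum
#' `Scross = S1 * S2 - S12` (same-variant configurations excluded). The
#' unnormalized hypothesis masses `(1, p1 S1, p2 S2, p1 p2 Scross,
#' p12 S12)` are normalized to PP0..PP4. All sums run in log space
#' (log-sum-exp). The per-variant shared-causal posterior is
#' proportional to `exp(labf1 + labf2)`.
#'
#' @param labf1,labf2 equal-length aligned log-ABF vectors (>= 1 variant).
#' @param config a [coloc_config()].
#' @return list of class `coloc_posteriors`: `pp` (named PP0..PP4),
#'   `variant_pp4` (per-variant shared posterior), `n_variants`.
#'   Single-variant regions have a structurally zero H3 term.
#' @export
coloc_posteriors <- function(labf1, labf2, config = coloc_config()) {
  n <- length(labf1)
  if (n < 1 || length(labf2) != n) {
    stop("labf1 and labf2 must be equal-length vectors with >= 1 variant")
  }
  lS1 <- logsumexp(labf1)
  lS2 <- logsumexp(labf2)
  lS12 <- logsumexp(labf1 + labf2)
  # Scross = S1 * S2 - S12, in log space with guarded cancellation
  lprod <- lS1 + lS2
  lScross <- if (n == 1 || lS12 >= lprod) -Inf else
    lprod + log1p(-exp(lS12 - lprod))
  lh <- c(H0 = 0,
          H1 = log(config$p1) + lS1,
          H2 = log(config$p2) + lS2,
          H3 = log(config$p1) + log(config$p2) + lScross,
          H4 = log(config$p12) + lS12)
  lz <- logsumexp(lh)
  pp <- exp(lh - lz)
  names(pp) <- paste0("PP", 0:4)
  v <- exp(labf1 + labf2 - lS12)
  structure(list(pp = pp, variant_pp4 = v, n_variants = n),
            class = "coloc_posteriors")
}

#' @export
print.coloc_posteriors <- function(x, ...) {
  cat("colocalisation posteriors over", x$n_variants, "variants:\n")
  print(round(x$pp, 4))
  invisible(x)
}

#' Full colocalisation triage of a condition pair
#'
#' Finds lead variants in both traits, forms shared regions, and runs the
#' approximate-Bayes-factor colocalisation in each region on the variants
#' shared by both tables.
#'
#' @param ss1,ss2 summary-statistics data frames.
#' @param config a [coloc_config()].
#' @return data frame, one row per region: `chr, start, end, n_variants,
#'   PP0..PP4, top_variant, top_variant_pp, pp4_above_threshold`; attribute
#'   `details` holds the per-region `coloc_posteriors` objects.
#' @export
coloc_pair <- function(ss1, ss2, config = coloc_config()) {
  l1 <- find_lead_snps(ss1, config$p_threshold, config$window)
  l2 <- find_lead_snps(ss2, config$p_threshold, config$window)
  regions <- define_shared_regions(l1, l2, config$window)
  cols <- c("chr", "start", "end", "n_variants", paste0("PP", 0:4),
            "top_variant", "top_variant_pp", "pp4_above_threshold")
  if (nrow(regions) == 0) {
    out <- stats::setNames(data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
    attr(out, "details") <- list()
    return(out)
  }
  details <- vector("list", nrow(regions))
  rows <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    rg <- regions[i, ]
    in1 <- ss1[ss1$CHR == rg$chr & ss1$BP >= rg$start & ss1$BP <= rg$end, ]
    shared <- intersect(in1$SNP, ss2$SNP)
    a <- ss1[match(shared, ss1$SNP), ]
    b <- ss2[match(shared, ss2$SNP), ]
    la <- log_abf(a$BETA, a$SE, config$prior_sd1)
    lb <- log_abf(b$BETA, b$SE, config$prior_sd2)
    post <- coloc_posteriors(la, lb, config)
    details[[i]] <- post
    top <- which.max(post$variant_pp4)
    rows[[i]] <- data.frame(
      chr = rg$chr, start = rg$start, end = rg$end,
      n_variants = length(shared),
      t(post$pp),
      top_variant = a$SNP[top], top_variant_pp = post$variant_pp4[top],
      pp4_above_threshold = unname(post$pp["PP4"] > config$pp4_threshold),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "details") <- details
  out
}
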
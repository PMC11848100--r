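#' Inverse-variance fixed-effects meta-analysis with Cochran's Q
#'
#' Weights `w_i = 1/se_i^2`; pooled estimate `sum(w b) / sum(w)`; pooled
#' standard error `sum(w)^(-1/2)`; heterogeneity `Q = sum(w (b - est)^2)`
#' against chi-square with `k - 1` degrees of freedom. With a single input
#' the estimate passes through and Q is reported missing. The same engine
#' pools per-pair log odds ratios across databases and per-variant GWAS
#' effects across sources.
#'
#' @param estimates numeric vector of input effect estimates.
#' @param ses matching standard errors (all > 0).
#' @return list of class `meta_result`: `estimate, se, z, p, q_stat, q_df,
#'   q_p, k`.
#' @export
meta_fixed <- function(estimates, ses) {
  k <- length(estimates)
  if (k < 1) stop("need at least one estimate")
  if (length(ses) != k) stop("estimates and ses must have equal length")
  if (any(is.na(ses)) || any(ses <= 0)) stop("standard errors must be positive")
  w <- 1 / ses^2
  est <- sum(w * estimates) / sum(w)
  se <- 1 / sqrt(sum(w))
  if (k == 1) {
    q <- NA_real_; q_p <- NA_real_
  } else {
    q <- sum(w * (estimates - est)^2)
    q_p <- stats::pchisq(q, df = k - 1, lower.tail = FALSE)
  }
  structure(list(estimate = est, se = se, z = est / se, p = p_from_z(est / se),
                 q_stat = q, q_df = k - 1L, q_p = q_p, k = k),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("fixed-effects meta (k = %d): estimate %.4f (se %.4f), p = %.3g\n",
              x$k, x$estimate, x$se, x$p))
  if (x$k > 1) cat(sprintf("  Cochran's Q = %.3f on %d df (p = %.3g)\n",
                           x$q_stat, x$q_df, x$q_p))
  invisible(x)
}

.PALINDROMIC <- c("A|T", "T|A", "C|G", "G|C")

#' Harmonise effect alleles between two summary-statistics tables
#'
#' Matches variants by id and aligns the second table's effect allele to
#' the first: identical allele pairs pass through; swapped `A1/A2` flip the
#' sign of `BETA` and `Z`; strand-ambiguous palindromic variants (A/T, C/G)
#' and incompatible allele sets are dropped and counted.
#'
#' @param ss_ref reference summary statistics (defines allele orientation).
#' @param ss_other table to align.
#' @return list with `ref` and `other` (matched, aligned, same row order)
#'   and `drops`: counts of `palindromic`, `mismatch`, `unmatched_id`.
#' @export
harmonise_alleles <- function(ss_ref, ss_other) {
  shared <- intersect(ss_ref$SNP, ss_other$SNP)
  n_unmatched <- (nrow(ss_ref) - length(shared)) + (nrow(ss_other) - length(shared))
  r <- ss_ref[match(shared, ss_ref$SNP), , drop = FALSE]
  o <- ss_other[match(shared, ss_other$SNP), , drop = FALSE]
  pal <- paste(r$A1, r$A2, sep = "|") %in% .PALINDROMIC |
    paste(o$A1, o$A2, sep = "|") %in% .PALINDROMIC
  same <- r$A1 == o$A1 & r$A2 == o$A2
  swapped <- r$A1 == o$A2 & r$A2 == o$A1
  keep <- !pal & (same | swapped)
  n_pal <- sum(pal)
  n_mismatch <- sum(!pal & !(same | swapped))
  r <- r[keep, , drop = FALSE]
  o <- o[keep, , drop = FALSE]
  flip <- swapped[keep]
  o$BETA[flip] <- -o$BETA[flip]
  if ("Z" %in% names(o)) o$Z[flip] <- -o$Z[flip]
  tmp <- o$A1[flip]; o$A1[flip] <- o$A2[flip]; o$A2[flip] <- tmp
  rownames(r) <- rownames(o) <- NULL
  list(ref = r, other = o,
       drops = c(palindromic = n_pal, mismatch = n_mismatch,
                 unmatched_id = n_unmatched))
}

#' Select non-overlapping GWAS sources for one condition
#'
#' Applies the source-selection policy for combining up to three genetic
#' data sources (a biobank reference, a national biobank, a disease
#' consortium): (1) drop candidates whose within-condition genetic
#' correlation with the reference is not strictly greater than the gate
#' (or is missing); (2) if a retained consortium source overlaps the
#' reference and/or the other biobank, keep the consortium (it has the
#' larger case count) and drop the overlapped sources; (3) the retained,
#' mutually disjoint set is what the meta-analysis pools. If no candidate
#' survives, the reference alone is used.
#'
#' @param sources data frame with columns `source_id`,
#'   `type` (`"reference"`, `"biobank"`, `"consortium"`), `n_cases`,
#'   `rg_vs_ref` (NA for the reference itself), `overlaps_ref`,
#'   `overlaps_biobank` (logical).
#' @param rg_threshold within-condition gate, strict `>` (default 0.8).
#' @return list with `chosen` (source ids) and `rationale` (named character
#'   vector of per-source codes: `reference_default`, `rg_pass`, `rg_fail`,
#'   `rg_missing`, `overlap_dropped`).
#' @export
select_sources <- function(sources, rg_threshold = 0.8) {
  if (sum(sources$type == "reference") != 1) {
    stop("exactly one reference source required")
  }
  rat <- stats::setNames(rep(NA_character_, nrow(sources)), sources$source_id)
  ref <- sources$source_id[sources$type == "reference"]
  rat[ref] <- "reference_default"
  keep <- stats::setNames(sources$type == "reference", sources$source_id)
  for (i in seq_len(nrow(sources))) {
    if (sources$type[i] == "reference") next
    sid <- sources$source_id[i]
    rg <- sources$rg_vs_ref[i]
    if (is.na(rg)) {
      rat[sid] <- "rg_missing"
    } else if (rg > rg_threshold) {
      keep[sid] <- TRUE
      rat[sid] <- "rg_pass"
    } else {
      rat[sid] <- "rg_fail"
    }
  }
  cons <- sources$source_id[sources$type == "consortium"]
  for (sid in cons[keep[cons]]) {
    row <- sources[sources$source_id == sid, ]
    if (isTRUE(row$overlaps_ref)) {
      keep[ref] <- FALSE
      rat[ref] <- "overlap_dropped"
    }
    if (isTRUE(row$overlaps_biobank)) {
      bb <- sources$source_id[sources$type == "biobank"]
      keep[bb] <- FALSE
      rat[bb] <- "overlap_dropped"
    }
  }
  if (!any(keep)) {
    keep[ref] <- TRUE
    rat[ref] <- "reference_default"
  }
  list(chosen = names(keep)[keep], rationale = rat)
}

#' Meta-analyse two harmonised GWAS summary-statistics tables per variant
#'
#' Applies [harmonise_alleles()] then [meta_fixed()] variant by variant.
#' The output's per-variant effective sample size is the sum of the input
#' sizes, for downstream LD-score regression.
#'
#' @param ss_list list of >= 1 summary-statistics data frames; the first is
#'   the allele reference.
#' @return one summary-statistics data frame with meta-analysed `BETA, SE,
#'   Z, P` and summed `N`, plus `Q_STAT, Q_P` heterogeneity columns.
#' @export
meta_gwas <- function(ss_list) {
  if (length(ss_list) == 1) return(ss_list[[1]])
  out <- ss_list[[1]]
  for (j in 2:length(ss_list)) {
    h <- harmonise_alleles(out, ss_list[[j]])
    r <- h$ref; o <- h$other
    w1 <- 1 / r$SE^2; w2 <- 1 / o$SE^2
    sw <- w1 + w2
    beta <- (w1 * r$BETA + w2 * o$BETA) / sw
    se <- 1 / sqrt(sw)
    q <- w1 * (r$BETA - beta)^2 + w2 * (o$BETA - beta)^2
    out <- r
    out$BETA <- beta; out$SE <- se; out$Z <- beta / se
    out$P <- p_from_z(out$Z)
    out$N <- r$N + o$N
    out$Q_STAT <- q
    out$Q_P <- stats::pchisq(q, df = 1, lower.tail = FALSE)
  }
  out
}
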
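#' Tercile cutoffs anchored on a basis subset of pairs
#'
#' Cutpoints are the 1/3 and 2/3 empirical quantiles (default quantile
#' definition, type 7) of the basis subset's point estimates — odds ratios
#' for the observational axis, rg for the genetic axis. Class membership is
#' boundary-inclusive downwards: weak `<=` lower cut, intermediate
#' `(lower, upper]`, strong `> upper`.
#'
#' @param pairs data frame of pairs with `domain_relation` and the axis
#'   estimate columns `log_or` / `rg` (and q-value columns `or_q` / `rg_q`).
#' @param axis `"observational_or"` or `"genetic_rg"`.
#' @param basis subset defining the anchor distribution:
#'   `"within_domain"` (default; significant within-domain pairs),
#'   `"all"` (all significant pairs).
#' @param alpha significance level for the basis restriction (default 0.05).
#' @return list of class `tercile_cutoffs`: `axis, lower, upper, basis,
#'   n_basis`.
#' @export
tercile_cutoffs <- function(pairs, axis = c("observational_or", "genetic_rg"),
                            basis = c("within_domain", "all"), alpha = 0.05) {
  axis <- match.arg(axis)
  basis <- match.arg(basis)
  est <- if (axis == "observational_or") exp(pairs$log_or) else pairs$rg
  q <- if (axis == "observational_or") pairs$or_q else pairs$rg_q
  keep <- !is.na(est) & !is.na(q) & q < alpha
  if (basis == "within_domain") keep <- keep & pairs$domain_relation == "within"
  vals <- est[keep]
  if (length(vals) < 3) stop("need at least 3 basis pairs with estimates on axis ", axis)
  if (max(vals) - min(vals) < 1e-12) {
    stop("degenerate basis distribution: identical values on axis ", axis)
  }
  cuts <- unname(stats::quantile(vals, c(1 / 3, 2 / 3)))
  structure(list(axis = axis, lower = cuts[1], upper = cuts[2],
                 basis = paste0(basis, " pairs significant at q < ", alpha),
                 n_basis = length(vals)),
            class = "tercile_cutoffs")
}

#' Preset tercile cutoffs
#'
#' Fixed cutpoint presets for exact reproduction of published class
#' boundaries: odds ratio (1.46, 1.90) and genetic correlation
#' (0.25, 0.48).
#'
#' @param axis `"observational_or"` or `"genetic_rg"`.
#' @return a `tercile_cutoffs` object.
#' @export
preset_cutoffs <- function(axis = c("observational_or", "genetic_rg")) {
  axis <- match.arg(axis)
  cuts <- if (axis == "observational_or") c(1.46, 1.90) else c(0.25, 0.48)
  structure(list(axis = axis, lower = cuts[1], upper = cuts[2],
                 basis = "published preset", n_basis = NA_integer_),
            class = "tercile_cutoffs")
}

.tercile_class <- function(est, q, cutoffs, alpha) {
  ifelse(is.na(est) | is.na(q), NA_character_,
    ifelse(q >= alpha, "not_significant",
      ifelse(est <= cutoffs$lower, "weak",
        ifelse(est <= cutoffs$upper, "intermediate", "strong"))))
}

#' Classify pairs on both axes and assign concordance quadrants
#'
#' Each axis class is `not_significant` when the pair's q-value is at or
#' above `alpha`, otherwise the tercile of its point estimate (OR scale
#' observationally, rg genetically). The quadrant joins the two axes:
#' `concordant_positive` (both significant, OR > 1 and rg > 0),
#' `concordant_negative` (both significant, OR < 1 and rg < 0),
#' `genetic_only` (rg significant and positive while the OR is not
#' significant or significantly below 1), `observational_only` (OR
#' significant and > 1, rg not significant), `null` otherwise. Pairs
#' missing an estimate on either axis are reported `unclassified`.
#'
#' @param pairs data frame with `pair_id, domain_relation, log_or, or_q,
#'   rg, rg_q`.
#' @param obs_cutoffs,rg_cutoffs `tercile_cutoffs` for the two axes.
#' @param alpha FDR significance level (default 0.05).
#' @return the input with `obs_class`, `rg_class`, `quadrant` columns.
#' @export
classify_pairs <- function(pairs, obs_cutoffs, rg_cutoffs, alpha = 0.05) {
  or <- exp(pairs$log_or)
  pairs$obs_class <- .tercile_class(or, pairs$or_q, obs_cutoffs, alpha)
  pairs$rg_class <- .tercile_class(pairs$rg, pairs$rg_q, rg_cutoffs, alpha)
  obs_sig <- !is.na(pairs$or_q) & pairs$or_q < alpha
  rg_sig <- !is.na(pairs$rg_q) & pairs$rg_q < alpha
  quad <- rep("null", nrow(pairs))
  quad[obs_sig & rg_sig & or > 1 & pairs$rg > 0] <- "concordant_positive"
  quad[obs_sig & rg_sig & or < 1 & pairs$rg < 0] <- "concordant_negative"
  quad[rg_sig & pairs$rg > 0 & (!obs_sig | (obs_sig & or < 1))] <- "genetic_only"
  quad[obs_sig & or > 1 & !rg_sig] <- "observational_only"
  quad[is.na(pairs$log_or) | is.na(pairs$rg)] <- "unclassified"
  pairs$quadrant <- quad
  pairs
}

.CLASS_LEVELS <- c("not_significant", "weak", "intermediate", "strong")

#' Cross-tabulate genetic by observational classes
#'
#' 4 x 4 count table (genetic class rows by observational class columns)
#' with row/column marginals and percentages of the panel total rounded to
#' one decimal.
#'
#' @param classified output of [classify_pairs()].
#' @param panel `"all"`, `"within"` or `"across"` domain panel.
#' @return list of class `pair_crosstab`: `counts` (5 x 5 matrix with
#'   `Total` margins), `percent`, `panel`, `n`.
#' @export
crosstab <- function(classified, panel = c("all", "within", "across")) {
  panel <- match.arg(panel)
  d <- classified
  if (panel != "all") d <- d[d$domain_relation == panel, , drop = FALSE]
  d <- d[!is.na(d$obs_class) & !is.na(d$rg_class), , drop = FALSE]
  tab <- table(factor(d$rg_class, levels = .CLASS_LEVELS),
               factor(d$obs_class, levels = .CLASS_LEVELS))
  counts <- matrix(as.integer(tab), 4, 4, dimnames = dimnames(tab))
  counts <- rbind(counts, Total = colSums(counts))
  counts <- cbind(counts, Total = rowSums(counts))
  n <- counts["Total", "Total"]
  pct <- if (n > 0) round(100 * counts / n, 1) else counts * 0
  structure(list(counts = counts, percent = pct, panel = panel, n = n),
            class = "pair_crosstab")
}

#' @export
print.pair_crosstab <- function(x, ...) {
  cat("Genetic (rows) x observational (columns) classes,", x$panel,
      "panel, n =", x$n, "\n")
  print(x$counts)
  invisible(x)
}

#' Marginal arithmetic of a 4 x 4 class count table
#'
#' Inclusion-exclusion summaries from raw counts (rows = genetic class,
#' columns = observational class, both ordered not_significant / weak /
#' intermediate / strong): the number of pairs significant on both axes is
#' `total - rg_ns_row - obs_ns_col + ns_ns_cell`.
#'
#' @param counts 4 x 4 numeric matrix of counts.
#' @return list: `total`, `both_significant`, `rg_row_totals`,
#'   `obs_col_totals`, `percent` (function mapping a count to the
#'   one-decimal percentage of the total).
#' @export
crosstab_summary <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(4, 4))) stop("counts must be a 4 x 4 matrix")
  total <- sum(counts)
  both <- total - sum(counts[1, ]) - sum(counts[, 1]) + counts[1, 1]
  list(total = total,
       both_significant = both,
       rg_row_totals = rowSums(counts),
       obs_col_totals = colSums(counts),
       percent = function(k) round(100 * k / total, 1))
}

#' Regression of observed co-occurrence on genetic correlation
#'
#' Ordinary least squares of the per-pair meta log odds ratio on rg
#' (default direction: odds as response). The slope is also reported as
#' the percent change in the odds of co-occurrence per 0.01 increase in
#' rg, `100 * (exp(0.01 * slope) - 1)`, with a normal-approximation 95%
#' confidence interval transformed monotonically.
#'
#' @param pairs data frame with `log_or` and `rg`.
#' @param subset optional logical vector restricting the pairs.
#' @param direction `"or_on_rg"` (default, odds as response) or
#'   `"rg_on_or"`.
#' @return list: `slope, se, ci` (95%), `percent_odds_per_0.01_rg` and its
#'   `percent_ci`, `n`, `direction`.
#' @export
regress_obs_on_rg <- function(pairs, subset = NULL,
                              direction = c("or_on_rg", "rg_on_or")) {
  direction <- match.arg(direction)
  d <- pairs
  if (!is.null(subset)) d <- d[subset, , drop = FALSE]
  d <- d[!is.na(d$log_or) & !is.na(d$rg), , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 pairs with both estimates")
  x <- if (direction == "or_on_rg") d$rg else d$log_or
  y <- if (direction == "or_on_rg") d$log_or else d$rg
  if (stats::var(x) < 1e-12) stop("degenerate regressor: constant values")
  fit <- stats::lm(y ~ x)
  co <- summary(fit)$coefficients
  slope <- co["x", "Estimate"]; se <- co["x", "Std. Error"]
  ci <- slope + c(-1, 1) * stats::qnorm(0.975) * se
  pct <- function(b) 100 * (exp(0.01 * b) - 1)
  list(slope = slope, se = se, ci = ci,
       percent_odds_per_0.01_rg = if (direction == "or_on_rg") pct(slope) else NA_real_,
       percent_ci = if (direction == "or_on_rg") pct(ci) else c(NA_real_, NA_real_),
       n = nrow(d), direction = direction)
}
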
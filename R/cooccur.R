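#' Per-database logistic co-occurrence model for one condition pair
#'
#' Fits, within each database, a logistic regression of the less prevalent
#' condition (`outcome`) on the indicator of the more prevalent condition
#' (`exposure`), adjusted for centred age (linear, centred at 65) and sex.
#' The log odds ratio is the exposure coefficient, with the Wald standard
#' error from the observed information and a two-sided normal p-value.
#' Fitting is maximum likelihood by iteratively reweighted least squares
#' (stats::glm); separation (fitted probabilities at 0/1) or hitting the
#' iteration cap is reported as `converged = FALSE` with the estimate left
#' missing rather than a silent number.
#'
#' @param cohort cohort data frame (see [simulate_cohort()]).
#' @param pair list or one-row data frame with `a` (exposure, more
#'   prevalent) and `b` (outcome, less prevalent) condition column names.
#' @param covariates character vector of adjustment covariates; default
#'   `c("age", "sex")`. Use `character(0)` for a crude 2x2 fit.
#' @param maxit IRLS iteration cap (default 50).
#' @return data frame with one row per database: `pair_id, database,
#'   log_or, se, wald_z, p, n_cases, converged`.
#' @export
fit_pair_logistic <- function(cohort, pair, covariates = c("age", "sex"),
                              maxit = 50) {
  a <- as.character(pair$a); b <- as.character(pair$b)
  if (!all(c(a, b) %in% names(cohort))) {
    stop("pair conditions not found in cohort: ", a, ", ", b)
  }
  dbs <- unique(cohort$database)
  rows <- lapply(dbs, function(d) {
    sub <- cohort[cohort$database == d, , drop = FALSE]
    y <- sub[[b]]
    if (sum(y) == 0 || sum(y) == nrow(sub)) {
      stop("outcome '", b, "' has no cases or no non-cases in database ", d)
    }
    dat <- data.frame(y = y, exposure = sub[[a]])
    if ("age" %in% covariates) dat$age_c <- sub$age - 65
    if ("sex" %in% covariates) dat$sex <- factor(sub$sex)
    extra <- setdiff(covariates, c("age", "sex"))
    for (v in extra) dat[[v]] <- sub[[v]]
    rhs <- c("exposure",
             if ("age" %in% covariates) "age_c",
             if ("sex" %in% covariates) "sex", extra)
    form <- stats::reformulate(rhs, response = "y")
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(form, family = stats::binomial(), data = dat,
                 control = stats::glm.control(maxit = maxit)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
            grepl("algorithm did not converge", conditionMessage(w))) {
          sep <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    # separation: fitted probabilities pinned to the boundary
    if (any(fit$fitted.values < 1e-8) || any(fit$fitted.values > 1 - 1e-8)) {
      sep <- TRUE
    }
    ok <- fit$converged && !sep
    est <- if (ok) summary(fit)$coefficients["exposure", ] else
      c(NA_real_, NA_real_, NA_real_, NA_real_)
    data.frame(pair_id = paste(a, b, sep = "__"), database = d,
               log_or = unname(est[1]), se = unname(est[2]),
               wald_z = unname(est[1] / est[2]),
               p = if (ok) p_from_z(est[1] / est[2]) else NA_real_,
               n_cases = sum(y), converged = ok,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment
#' `q_(i) = min_{j >= i} (m * p_(j) / j)`, clipped at 1 and mapped back to
#' input order (stats::p.adjust, method "BH", after validating the inputs).
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}
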
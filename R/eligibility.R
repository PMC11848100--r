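#' Per-database and pooled prevalence of a condition
#'
#' Prevalence is affected / eligible persons within each database, pooled
#' over all databases. An optional `filter` hook restricts general cohort
#' tables to the eligible population (alive, registered, aged >= 65 at the
#' index date); synthetic cohorts satisfy this by construction.
#'
#' @param cohort cohort data frame (see [simulate_cohort()]).
#' @param condition condition column name.
#' @param filter optional function `cohort -> logical` selecting eligible rows.
#' @return data frame with one row per database plus a `pooled` row:
#'   `database, n, affected, prevalence`.
#' @export
compute_prevalence <- function(cohort, condition, filter = NULL) {
  if (!condition %in% names(cohort)) {
    stop("condition '", condition, "' not found in cohort")
  }
  if (!is.null(filter)) cohort <- cohort[filter(cohort), , drop = FALSE]
  if (nrow(cohort) == 0) stop("empty denominator: no eligible persons")
  agg <- stats::aggregate(cohort[[condition]],
                          by = list(database = cohort$database),
                          FUN = function(x) c(n = length(x), affected = sum(x)))
  out <- data.frame(database = agg$database,
                    n = agg$x[, "n"], affected = agg$x[, "affected"],
                    stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(database = "pooled", n = sum(out$n),
                               affected = sum(out$affected)))
  out$prevalence <- out$affected / out$n
  out
}

#' Three-step condition selection
#'
#' A condition is included iff it is chronic, its maximum per-database
#' prevalence meets the threshold, and its heritability z-score `h2 / h2_se`
#' exceeds the z threshold — unless a manual override flips the verdict
#' (recorded with reason `manual`). Excluded conditions carry exactly one
#' exclusion reason, assessed in step order: `not_chronic`,
#' `low_prevalence`, `low_heritability`.
#'
#' @param descriptors data frame with columns `id`, `chronic` (logical),
#'   one or more `prev_*` prevalence columns (or a single `prevalence`),
#'   `h2`, `h2_se`.
#' @param prevalence_threshold minimum prevalence (proportion), default 0.005.
#' @param h2_z_threshold heritability z-score gate (strict `>`), default 4.
#' @param manual_overrides optional data frame `id, include` forcing a
#'   verdict.
#' @return the descriptors with `included`, `exclusion_reason`, `h2_z`,
#'   `max_prevalence` columns. Conditions passing the prevalence gate but
#'   lacking an h2 estimate are flagged (`h2_missing`), never silently
#'   dropped.
#' @export
select_conditions <- function(descriptors, prevalence_threshold = 0.005,
                              h2_z_threshold = 4, manual_overrides = NULL) {
  d <- descriptors
  prev_cols <- grep("^prev", names(d), value = TRUE)
  if (length(prev_cols) == 0) stop("no prevalence column(s) found")
  d$max_prevalence <- do.call(pmax, d[prev_cols])
  if (any(d$max_prevalence < 0 | d$max_prevalence > 1)) {
    stop("prevalences must lie in [0, 1]")
  }
  d$h2_z <- d$h2 / d$h2_se
  d$h2_missing <- FALSE
  d$included <- FALSE
  d$exclusion_reason <- NA_character_
  for (i in seq_len(nrow(d))) {
    if (!isTRUE(d$chronic[i])) {
      d$exclusion_reason[i] <- "not_chronic"
    } else if (d$max_prevalence[i] < prevalence_threshold) {
      d$exclusion_reason[i] <- "low_prevalence"
    } else if (is.na(d$h2_z[i])) {
      d$h2_missing[i] <- TRUE
      d$exclusion_reason[i] <- "low_heritability"
      warning("condition '", d$id[i],
              "' passes the prevalence gate but has no heritability estimate")
    } else if (d$h2_z[i] <= h2_z_threshold) {
      d$exclusion_reason[i] <- "low_heritability"
    } else {
      d$included[i] <- TRUE
    }
  }
  if (!is.null(manual_overrides) && nrow(manual_overrides) > 0) {
    for (i in seq_len(nrow(manual_overrides))) {
      j <- match(manual_overrides$id[i], d$id)
      if (is.na(j)) stop("manual override references unknown condition '",
                         manual_overrides$id[i], "'")
      want <- isTRUE(manual_overrides$include[i])
      if (want != d$included[j]) {
        d$included[j] <- want
        d$exclusion_reason[j] <- if (want) NA_character_ else "manual"
      }
    }
  }
  d
}

#' Enumerate analysable condition pairs
#'
#' All unordered pairs of the included conditions, minus an exclusion list
#' of code-list-overlapping pairs. Within each pair, `a` is the more
#' prevalent condition by pooled prevalence (ties broken lexicographically
#' by id); `domain_relation` is `"within"` iff the two conditions share an
#' ICD-10 chapter.
#'
#' @param included data frame of included conditions with columns `id`,
#'   `icd10_chapter`, `pooled_prevalence`.
#' @param overlap_exclusions optional data frame `a, b` of excluded pairs
#'   (unordered).
#' @return data frame `pair_id, a, b, domain_relation` with attribute
#'   `n_excluded`.
#' @export
enumerate_pairs <- function(included, overlap_exclusions = NULL) {
  if (nrow(included) < 2) stop("need at least two included conditions")
  ids <- as.character(included$id)
  if (anyDuplicated(ids)) stop("duplicate condition ids")
  prev <- stats::setNames(included$pooled_prevalence, ids)
  chap <- stats::setNames(as.character(included$icd10_chapter), ids)
  cmb <- utils::combn(sort(ids), 2)
  a <- cmb[1, ]; b <- cmb[2, ]
  # order within pair: a = more prevalent (pooled), tie -> lexicographic id
  swap <- prev[b] > prev[a]
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "|")
  keep <- rep(TRUE, length(a))
  n_excl <- 0L
  if (!is.null(overlap_exclusions) && nrow(overlap_exclusions) > 0) {
    ex_ids <- unique(c(as.character(overlap_exclusions$a),
                       as.character(overlap_exclusions$b)))
    unknown <- setdiff(ex_ids, ids)
    if (length(unknown) > 0) {
      stop("exclusion list references unknown conditions: ",
           paste(unknown, collapse = ", "))
    }
    ex_key <- key(as.character(overlap_exclusions$a),
                  as.character(overlap_exclusions$b))
    keep <- !(key(a, b) %in% ex_key)
    n_excl <- sum(!keep)
  }
  out <- data.frame(
    pair_id = paste(a, b, sep = "__"),
    a = a, b = b,
    domain_relation = ifelse(chap[a] == chap[b], "within", "across"),
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excl
  out
}
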
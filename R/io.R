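# Tabular interchange formats. All tabular artifacts are tab- or
# comma-separated text with named headers; every writer stamps a schema
# version comment-free via a sidecar-free convention: readers validate the
# expected column set and reject unknown layouts.

.SS_COLS <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P", "N")

#' Write / read GWAS summary statistics (TSV)
#'
#' Columns: `SNP, CHR, BP, A1, A2, BETA, SE, P, N`. On read, the z-score is
#' recomputed as `BETA / SE`.
#'
#' @param ss summary-statistics data frame.
#' @param path file path.
#' @return `read_sumstats` returns the data frame with a `Z` column.
#' @export
write_sumstats <- function(ss, path) {
  utils::write.table(ss[, .SS_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(.SS_COLS, names(ss))
  if (length(missing) > 0) {
    stop("summary-statistics file lacks columns: ", paste(missing, collapse = ", "))
  }
  if (any(ss$SE <= 0)) stop("non-positive standard errors in ", path)
  ss$Z <- ss$BETA / ss$SE
  ss
}

#' Write / read LD scores (TSV, `.l2.ldscore` layout)
#'
#' Columns: `CHR, SNP, BP, L2`. The panel variant count M is not part of
#' this file (as in the conventional layout) and travels separately.
#'
#' @param panel an `ld_panel` or a data frame with the four columns.
#' @param path file path.
#' @export
write_ldscores <- function(panel, path) {
  v <- if (inherits(panel, "ld_panel")) panel$variants else panel
  utils::write.table(v[, c("CHR", "SNP", "BP", "L2")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ldscores
#' @export
read_ldscores <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("CHR", "SNP", "BP", "L2"), names(x))
  if (length(missing) > 0) {
    stop("LD-score file lacks columns: ", paste(missing, collapse = ", "))
  }
  x
}

#' Write / read a person-level cohort table (CSV)
#'
#' Columns: `person_id, database, age, sex`, then one 0/1 column per
#' condition.
#'
#' @param cohort cohort data frame.
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("person_id", "database", "age", "sex"), names(x))
  if (length(missing) > 0) {
    stop("cohort file lacks columns: ", paste(missing, collapse = ", "))
  }
  x
}

#' Write / read a ground-truth JSON
#'
#' @param truth a list (e.g. [sim_truth()]) of generating parameters.
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
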
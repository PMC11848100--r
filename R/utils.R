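#' Derive a deterministic substream seed
#'
#' All randomness in the package flows from a single user-supplied seed.
#' Generators draw from per-stage substreams so that adding or reordering
#' stages does not perturb the streams of the others. The substream is a
#' fixed arithmetic hash of (seed, stage code, index), kept below 2^31.
#'
#' Stage codes: ld_panel = 1, gwas = 2, cohort = 3, locus = 4, pipeline = 5.
#'
#' @param seed integer master seed.
#' @param stage character stage name (one of the codes above).
#' @param index integer replicate index within the stage (default 0).
#' @return an integer seed suitable for [set.seed()].
#' @export
substream_seed <- function(seed, stage, index = 0L) {
  codes <- c(ld_panel = 1L, gwas = 2L, cohort = 3L, locus = 4L, pipeline = 5L)
  if (!stage %in% names(codes)) {
    stop("unknown stage '", stage, "'; expected one of: ",
         paste(names(codes), collapse = ", "))
  }
  s <- as.numeric(seed) %% 1048576
  as.integer((s * 2039 + codes[[stage]] * 7919 + as.numeric(index) * 104729) %%
               2147483647)
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# two-sided normal p-value from a z-score, kept strictly inside (0, 1]
p_from_z <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmax(p, .Machine$double.xmin)
}

stopifnot_scalar_prob <- function(x, name, open_left = FALSE, open_right = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(name, " must be a single non-missing number")
  }
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!lo_ok || !hi_ok) stop(name, " = ", x, " is outside the valid range")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
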
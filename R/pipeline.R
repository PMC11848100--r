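# Pipeline orchestration: a validated run configuration drives the stages
# synth -> eligibility -> cooccur -> rg -> classify -> coloc -> report.
# Every tabular artifact is tab-separated text with a named header; the
# manifest records inputs, digests, seeds and per-stage row counts. All
# randomness flows from config$seed via substream_seed(), so two runs with
# an identical configuration are byte-identical.

.CONFIG_KEYS <- list(
  top = c("seed", "out_dir", "stages", "cutoff_preset", "thresholds",
          "cohort", "gwas", "coloc"),
  thresholds = c("prevalence", "h2_z", "rg_gate", "fdr_alpha"),
  cohort = c("n_per_database", "conditions", "pair_ors", "age_coef",
             "sex_coef", "age_range", "sex_prob"),
  gwas = c("n_blocks", "block_size", "corr", "n", "h2", "rg_matrix",
           "jackknife_blocks"),
  coloc = c("enabled", "n_variants", "ld_corr", "hypothesis",
            "effect_sizes", "n1", "n2")
)

.check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s) in ", where, ": ",
         paste(unknown, collapse = ", "))
  }
}

#' Validate a pipeline run configuration
#'
#' Rejects unknown keys (at the top level and within each section) and
#' checks that every threshold lies in its documented range.
#'
#' @param config a run-configuration list (see [demo_config()]).
#' @return the config, invisibly, with class `run_config`.
#' @export
validate_run_config <- function(config) {
  .check_keys(config, .CONFIG_KEYS$top, "top level")
  for (sec in c("thresholds", "cohort", "gwas", "coloc")) {
    if (!is.null(config[[sec]])) .check_keys(config[[sec]], .CONFIG_KEYS[[sec]], sec)
  }
  th <- config$thresholds
  if (th$prevalence < 0 || th$prevalence > 1) stop("prevalence threshold outside [0, 1]")
  if (th$h2_z < 0) stop("h2 z threshold must be non-negative")
  if (th$rg_gate < -1 || th$rg_gate > 1) stop("rg gate outside [-1, 1]")
  if (th$fdr_alpha <= 0 || th$fdr_alpha >= 1) stop("FDR alpha outside (0, 1)")
  if (!config$cutoff_preset %in% c("computed", "published")) {
    stop("cutoff_preset must be 'computed' or 'published'")
  }
  invisible(structure(config, class = "run_config"))
}

#' Demonstration run configuration
#'
#' A compact six-condition synthetic study: two ICD-10 chapters of three
#' conditions each (6 within-domain and 9 across-domain pairs), two
#' primary-care databases, a shared LD panel, and one colocalisation
#' locus. Problem sizes are chosen so a full run finishes in a few minutes
#' while every stage still has estimable signal.
#'
#' @param seed master seed.
#' @param out_dir output directory.
#' @return a validated `run_config`.
#' @export
demo_config <- function(seed = 1L, out_dir = tempfile("ltcpairs_run_")) {
  conditions <- data.frame(
    id = paste0("cond", 1:6),
    chronic = TRUE,
    icd10_chapter = rep(c("IX", "XIII"), each = 3),
    prevalence = c(0.30, 0.15, 0.10, 0.20, 0.12, 0.08),
    stringsAsFactors = FALSE
  )
  pair_ors <- data.frame(
    a = c("cond1", "cond1", "cond2", "cond4", "cond4"),
    b = c("cond2", "cond3", "cond4", "cond5", "cond6"),
    or = c(3.0, 2.2, 1.4, 2.6, 1.8),
    stringsAsFactors = FALSE
  )
  h2 <- c(0.25, 0.20, 0.30, 0.20, 0.25, 0.15)
  rg_mat <- matrix(0.15, 6, 6)
  rg_mat[1:3, 1:3] <- 0.5
  rg_mat[4:6, 4:6] <- 0.5
  diag(rg_mat) <- 1
  validate_run_config(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = c("synth", "eligibility", "cooccur", "rg", "classify",
               "coloc", "report"),
    cutoff_preset = "published",
    thresholds = list(prevalence = 0.005, h2_z = 4, rg_gate = 0.8,
                      fdr_alpha = 0.05),
    cohort = list(
      n_per_database = c(cprd_like = 20000L, sidiap_like = 15000L),
      conditions = conditions, pair_ors = pair_ors,
      age_coef = 0.03, sex_coef = 0.2, age_range = c(65, 90),
      sex_prob = 0.457),
    gwas = list(n_blocks = 200L, block_size = 20L,
                corr = seq(0, 0.9, length.out = 200),
                n = 100000L, h2 = h2, rg_matrix = rg_mat,
                jackknife_blocks = 200L),
    coloc = list(enabled = TRUE, n_variants = 50L, ld_corr = 0.3,
                 hypothesis = "H4", effect_sizes = c(0.06, 0.06),
                 n1 = 20000L, n2 = 20000L)
  ))
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.stage_record <- function(outputs, rows, out_dir, cache_hit = FALSE) {
  md5 <- as.list(unname(tools::md5sum(outputs)))
  rel <- sub(paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", out_dir), "/?"),
             "", outputs)
  names(md5) <- rel
  list(outputs = md5, rows = rows, complete = TRUE, cache_hit = cache_hit)
}

.stage_cached <- function(manifest_prev, stage, out_dir) {
  rec <- manifest_prev$stages[[stage]]
  if (is.null(rec) || !isTRUE(rec$complete)) return(FALSE)
  files <- file.path(out_dir, names(rec$outputs))
  if (!all(file.exists(files))) return(FALSE)
  all(unname(tools::md5sum(files)) == unlist(rec$outputs, use.names = FALSE))
}

#' Run the full synthetic pipeline
#'
#' Executes the configured stages in dependency order, writing every
#' artifact under `config$out_dir` and a `manifest.json` recording the
#' configuration digest, seeds, output digests and per-stage row counts.
#' Re-running with an unchanged configuration skips stages whose recorded
#' outputs are intact (noted as cache hits) unless `force = TRUE`.
#'
#' @param config a `run_config` (see [demo_config()]).
#' @param force re-run all stages even when cached.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, force = FALSE) {
  config <- validate_run_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out, "sumstats"), showWarnings = FALSE)
  cfg_path <- file.path(out, "config.json")
  cfg_canon <- unclass(config)
  cfg_canon$out_dir <- NULL   # digest is location-independent
  jsonlite::write_json(cfg_canon, cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  digest <- unname(tools::md5sum(cfg_path))
  man_path <- file.path(out, "manifest.json")
  prev <- NULL
  if (!force && file.exists(man_path)) {
    prev <- jsonlite::read_json(man_path, simplifyVector = FALSE)
    if (!identical(prev$config_digest, digest)) prev <- NULL
  }
  manifest <- list(schema_version = "1", config_digest = digest,
                   seed = config$seed, stages = list())
  seed <- config$seed
  th <- config$thresholds
  conds <- config$cohort$conditions
  ids <- conds$id
  paths <- list(
    cohort = file.path(out, "cohort.csv"),
    ldscore = file.path(out, "ldscore.tsv"),
    sumstats = file.path(out, "sumstats", paste0(ids, ".tsv")),
    truth = file.path(out, "truth.json"),
    conditions = file.path(out, "conditions.tsv"),
    pairs = file.path(out, "pairs.tsv"),
    cooccur = file.path(out, "cooccur.tsv"),
    rg = file.path(out, "rg.tsv"),
    merged = file.path(out, "pairs_classified.tsv"),
    crosstab = file.path(out, paste0("crosstab_", c("all", "within", "across"), ".tsv")),
    regression = file.path(out, "regression.json"),
    coloc = file.path(out, "coloc.tsv"),
    report = file.path(out, "report.md")
  )

  run_stage <- function(stage, outputs, fn) {
    if (!stage %in% config$stages) return(invisible(NULL))
    if (!is.null(prev) && !force && .stage_cached(prev, stage, out)) {
      rec <- prev$stages[[stage]]
      rec$cache_hit <- TRUE
      manifest$stages[[stage]] <<- rec
      return(invisible(NULL))
    }
    rows <- fn()
    manifest$stages[[stage]] <<- .stage_record(outputs, rows, out)
    invisible(NULL)
  }

  panel <- NULL
  get_panel <- function() {
    if (is.null(panel)) {
      panel <<- simulate_ld_panel(config$gwas$n_blocks, config$gwas$block_size,
                                  corr = config$gwas$corr,
                                  seed = substream_seed(seed, "ld_panel"))
    }
    panel
  }

  # ---- synth ----------------------------------------------------------
  run_stage("synth", c(paths$cohort, paths$ldscore, paths$sumstats, paths$truth), function() {
    cohort <- simulate_cohort(config$cohort$n_per_database, conds,
                              pair_ors = config$cohort$pair_ors,
                              age_coef = config$cohort$age_coef,
                              sex_coef = config$cohort$sex_coef,
                              age_range = config$cohort$age_range,
                              sex_prob = config$cohort$sex_prob,
                              seed = substream_seed(seed, "cohort"))
    write_cohort(cohort, paths$cohort)
    pnl <- get_panel()
    write_ldscores(pnl, paths$ldscore)
    ss <- simulate_gwas_set(pnl, h2 = config$gwas$h2, rg = config$gwas$rg_matrix,
                            n = config$gwas$n,
                            seed = substream_seed(seed, "gwas"),
                            condition_ids = ids)
    for (i in seq_along(ids)) write_sumstats(ss[[i]], paths$sumstats[i])
    write_truth_json(list(h2 = config$gwas$h2, rg_matrix = config$gwas$rg_matrix,
                          pair_ors = config$cohort$pair_ors,
                          prevalence = conds$prevalence),
                     paths$truth)
    c(cohort = nrow(cohort), variants = pnl$M)
  })

  # ---- eligibility ----------------------------------------------------
  run_stage("eligibility", c(paths$conditions, paths$pairs), function() {
    cohort <- read_cohort(paths$cohort)
    pnl <- get_panel()
    desc <- conds
    prev_tabs <- lapply(ids, function(cid) compute_prevalence(cohort, cid))
    for (d in unique(cohort$database)) {
      desc[[paste0("prev_", d)]] <- vapply(prev_tabs, function(pt) {
        pt$prevalence[pt$database == d]
      }, numeric(1))
    }
    desc$pooled_prevalence <- vapply(prev_tabs, function(pt) {
      pt$prevalence[pt$database == "pooled"]
    }, numeric(1))
    h2s <- lapply(seq_along(ids), function(i) {
      estimate_h2(read_sumstats(paths$sumstats[i]), pnl,
                  n_blocks = config$gwas$jackknife_blocks)
    })
    desc$h2 <- vapply(h2s, `[[`, numeric(1), "h2")
    desc$h2_se <- vapply(h2s, `[[`, numeric(1), "se")
    sel <- select_conditions(desc, prevalence_threshold = th$prevalence,
                             h2_z_threshold = th$h2_z)
    .write_tsv(sel, paths$conditions)
    pairs <- enumerate_pairs(sel[sel$included, , drop = FALSE])
    .write_tsv(pairs, paths$pairs)
    c(conditions = nrow(sel), included = sum(sel$included), pairs = nrow(pairs))
  })

  # ---- cooccur --------------------------------------------------------
  run_stage("cooccur", paths$cooccur, function() {
    cohort <- read_cohort(paths$cohort)
    pairs <- utils::read.delim(paths$pairs, stringsAsFactors = FALSE)
    res <- lapply(seq_len(nrow(pairs)), function(i) {
      per_db <- fit_pair_logistic(cohort, pairs[i, ])
      ok <- per_db[per_db$converged, , drop = FALSE]
      meta <- meta_fixed(ok$log_or, ok$se)
      rbind(per_db,
            data.frame(pair_id = pairs$pair_id[i], database = "meta",
                       log_or = meta$estimate, se = meta$se, wald_z = meta$z,
                       p = meta$p, n_cases = sum(per_db$n_cases),
                       converged = TRUE, stringsAsFactors = FALSE))
    })
    res <- do.call(rbind, res)
    # FDR within each analysis family (each database, and the meta level)
    res$q <- NA_real_
    for (d in unique(res$database)) {
      sel <- res$database == d & !is.na(res$p)
      res$q[sel] <- bh_fdr(res$p[sel])
    }
    .write_tsv(res, paths$cooccur)
    c(rows = nrow(res))
  })

  # ---- rg -------------------------------------------------------------
  run_stage("rg", paths$rg, function() {
    pairs <- utils::read.delim(paths$pairs, stringsAsFactors = FALSE)
    pnl <- get_panel()
    ss <- lapply(seq_along(ids), function(i) read_sumstats(paths$sumstats[i]))
    names(ss) <- ids
    res <- lapply(seq_len(nrow(pairs)), function(i) {
      r <- estimate_rg(ss[[pairs$a[i]]], ss[[pairs$b[i]]], pnl,
                       n_blocks = config$gwas$jackknife_blocks)
      data.frame(pair_id = pairs$pair_id[i], rg = r$rg, rg_se = r$se,
                 rg_p = r$p, gencov = r$gencov, intercept = r$intercept,
                 clipped = r$clipped, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    ok <- !is.na(res$rg_p)
    res$rg_q <- NA_real_
    res$rg_q[ok] <- bh_fdr(res$rg_p[ok])
    .write_tsv(res, paths$rg)
    c(rows = nrow(res))
  })

  # ---- classify -------------------------------------------------------
  run_stage("classify", c(paths$merged, paths$crosstab, paths$regression), function() {
    pairs <- utils::read.delim(paths$pairs, stringsAsFactors = FALSE)
    co <- utils::read.delim(paths$cooccur, stringsAsFactors = FALSE)
    co <- co[co$database == "meta", c("pair_id", "log_or", "se", "p", "q")]
    names(co) <- c("pair_id", "log_or", "or_se", "or_p", "or_q")
    rg <- utils::read.delim(paths$rg, stringsAsFactors = FALSE)
    m <- merge(merge(pairs, co, by = "pair_id"), rg, by = "pair_id")
    if (config$cutoff_preset == "published") {
      obs_cut <- preset_cutoffs("observational_or")
      rg_cut <- preset_cutoffs("genetic_rg")
    } else {
      obs_cut <- tercile_cutoffs(m, "observational_or", alpha = th$fdr_alpha)
      rg_cut <- tercile_cutoffs(m, "genetic_rg", alpha = th$fdr_alpha)
    }
    cl <- classify_pairs(m, obs_cut, rg_cut, alpha = th$fdr_alpha)
    cl <- cl[order(cl$pair_id), , drop = FALSE]
    .write_tsv(cl, paths$merged)
    for (i in seq_along(c("all", "within", "across"))) {
      p <- c("all", "within", "across")[i]
      ct <- crosstab(cl, p)
      .write_tsv(cbind(rg_class = rownames(ct$counts), as.data.frame(ct$counts)),
                 paths$crosstab[i])
    }
    reg <- regress_obs_on_rg(cl)
    jsonlite::write_json(reg[c("slope", "se", "ci", "percent_odds_per_0.01_rg",
                               "percent_ci", "n", "direction")],
                         paths$regression, auto_unbox = TRUE, digits = NA)
    c(pairs = nrow(cl))
  })

  # ---- coloc ----------------------------------------------------------
  if (isTRUE(config$coloc$enabled)) {
    run_stage("coloc", paths$coloc, function() {
      cc <- config$coloc
      locus <- simulate_coloc_locus(cc$n_variants, cc$ld_corr, cc$hypothesis,
                                    cc$effect_sizes, cc$n1, cc$n2,
                                    seed = substream_seed(seed, "locus"))
      res <- coloc_pair(locus[[1]], locus[[2]])
      .write_tsv(res, paths$coloc)
      c(regions = nrow(res))
    })
  }

  # ---- report ---------------------------------------------------------
  run_stage("report", paths$report, function() {
    render_report(out, paths$report)
    c(files = 1)
  })

  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Render the static run report
#'
#' Emits a markdown report with the class cross-tabulations (all, within-
#' and across-domain panels), the quadrant tallies, the rg-versus-odds
#' regression summary and the colocalisation table, all read back from the
#' completed stage artifacts so report and stage outputs cannot disagree.
#'
#' @param out_dir a completed run directory.
#' @param path report file path (default `report.md` inside `out_dir`).
#' @return the report path, invisibly.
#' @export
render_report <- function(out_dir, path = file.path(out_dir, "report.md")) {
  merged_path <- file.path(out_dir, "pairs_classified.tsv")
  if (!file.exists(merged_path)) {
    stop("classify stage outputs not found in ", out_dir)
  }
  cl <- utils::read.delim(merged_path, stringsAsFactors = FALSE)
  lines <- c("# Long-term condition pair atlas (synthetic run)", "")
  for (p in c("all", "within", "across")) {
    ct <- crosstab(cl, p)
    lines <- c(lines, paste0("## Crosstab (", p, " pairs, n = ", ct$n, ")"), "")
    tb <- ct$counts
    hdr <- paste(c("genetic \\ observational", colnames(tb)), collapse = " | ")
    sep <- paste(rep("---", ncol(tb) + 1), collapse = " | ")
    body <- vapply(seq_len(nrow(tb)), function(i) {
      paste(c(rownames(tb)[i], tb[i, ]), collapse = " | ")
    }, character(1))
    lines <- c(lines, hdr, sep, body, "")
  }
  quad <- sort(table(cl$quadrant), decreasing = TRUE)
  lines <- c(lines, "## Concordance quadrants", "",
             paste0("- ", names(quad), ": ", as.integer(quad)), "")
  reg_path <- file.path(out_dir, "regression.json")
  if (file.exists(reg_path)) {
    reg <- jsonlite::read_json(reg_path, simplifyVector = TRUE)
    lines <- c(lines, "## Genetic correlation versus co-occurrence", "",
               sprintf("- slope (log-OR per unit rg): %.4f [%.4f, %.4f]",
                       reg$slope, reg$ci[1], reg$ci[2]),
               sprintf("- odds change per 0.01 rg: %.3f%% [%.3f%%, %.3f%%]",
                       reg$percent_odds_per_0.01_rg, reg$percent_ci[1],
                       reg$percent_ci[2]), "")
  }
  coloc_path <- file.path(out_dir, "coloc.tsv")
  lines <- c(lines, "## Colocalisation", "")
  if (file.exists(coloc_path)) {
    colo <- utils::read.delim(coloc_path, stringsAsFactors = FALSE)
    if (nrow(colo) == 0) {
      lines <- c(lines, "No shared regions found.", "")
    } else {
      lines <- c(lines, vapply(seq_len(nrow(colo)), function(i) {
        sprintf("- chr%s:%d-%d PP4 = %.4f (top variant %s)",
                colo$chr[i], colo$start[i], colo$end[i], colo$PP4[i],
                colo$top_variant[i])
      }, character(1)), "")
    }
  } else {
    lines <- c(lines, "Stage not run.", "")
  }
  writeLines(lines, path)
  invisible(path)
}
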
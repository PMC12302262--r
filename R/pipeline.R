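#' Pipeline configuration
#'
#' Describes one end-to-end run: input mode per database (a CSV path or
#' `"synthetic"`), the simulation configuration when synthetic, the
#' vocabulary, trimming and qualification thresholds, the subgroup term
#' count, output directory and seed.
#'
#' @param output_dir directory for the report bundle (created if absent).
#' @param db1,db2 CSV path, `"synthetic"`, or `NULL` (database absent;
#'   stages needing it abort).
#' @param sim a [sim_config()]; required when either database is
#'   synthetic (default: [default_sim_config()] scaled to 200,000 reports
#'   per database for tractable runs).
#' @param term_frame an [ae_term_frame()]; default the packaged
#'   vocabulary.
#' @param min_trim minimum db1 case count below which a term is trimmed.
#' @param min_covid,min_comparator qualification thresholds, see
#'   [qualify()].
#' @param top_k number of top terms carried into subgroup and regression
#'   stages.
#' @param scope term-counting scope, see [term_case_count()].
#' @param seed master seed; all stage randomness derives from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir, db1 = "synthetic", db2 = "synthetic",
                            sim = NULL, term_frame = NULL, min_trim = 3L,
                            min_covid = 3L, min_comparator = 1L, top_k = 20L,
                            scope = "any_position", seed = 1L) {
  if (is.null(sim) && (identical(db1, "synthetic") || identical(db2, "synthetic")))
    sim <- default_sim_config(200000L, 200000L, seed = seed)
  for (db in list(db1, db2))
    if (!is.null(db) && !(is.character(db) && length(db) == 1L))
      stop_domain("db inputs must be a path, \"synthetic\", or NULL")
  cfg <- list(output_dir = output_dir, db1 = db1, db2 = db2, sim = sim,
              term_frame = term_frame, min_trim = as.integer(min_trim),
              min_covid = as.integer(min_covid),
              min_comparator = as.integer(min_comparator),
              top_k = as.integer(top_k), scope = scope, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full screening pipeline
#'
#' Executes, in order: load or generate both databases, merge duplicates,
#' classify the term universe against the vocabulary, per-term ARR table
#' with rare-term trimming (on db1 counts; db2 rows for trimmed terms are
#' dropped alongside), cross-database OR table, disproportionality screen
#' on db2, subgroup tables and per-term logistic regressions on db1 for
#' the top terms. Writes six CSVs (`term_rates.csv`,
#' `cross_database.csv`, `disproportionality.csv`, `subgroup.csv`,
#' `subgroup_forest.csv`, `regression.csv`) plus `manifest.json` with the
#' configuration echo and per-stage record counts. Deterministic given
#' the configuration and seed; any stage failure aborts with the stage
#' name and removes partial outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  fail <- function(stage, e) {
    unlink(written)
    stop_domain(sprintf("stage %s failed: %s", stage, conditionMessage(e)))
  }
  stage <- function(name, expr)
    tryCatch(expr, error = function(e) fail(name, e))
  emit <- function(df, file) {
    path <- file.path(cfg$output_dir, file)
    write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
    path
  }
  manifest <- list(seed = cfg$seed, scope = cfg$scope,
                   min_trim = cfg$min_trim, min_covid = cfg$min_covid,
                   min_comparator = cfg$min_comparator, top_k = cfg$top_k)

  db1 <- stage("load_db1", {
    if (is.null(cfg$db1)) NULL
    else if (identical(cfg$db1, "synthetic"))
      generate_database(cfg$sim, "db1", seed = cfg$seed)
    else read_icsr_table(cfg$db1, "single_term")
  })
  db2 <- stage("load_db2", {
    if (is.null(cfg$db2)) NULL
    else if (identical(cfg$db2, "synthetic"))
      generate_database(cfg$sim, "db2", seed = cfg$seed)
    else read_icsr_table(cfg$db2, "multi_term")
  })
  if (is.null(db1)) stage("load_db1", stop("db1 input is required"))
  manifest$n_db1_raw <- nrow(db1)
  manifest$n_db2_raw <- if (is.null(db2)) 0L else nrow(db2)

  db1 <- stage("merge_duplicates", merge_duplicates(db1))
  if (!is.null(db2)) db2 <- stage("merge_duplicates", merge_duplicates(db2))
  manifest$n_db1 <- nrow(db1)
  manifest$n_db2 <- if (is.null(db2)) 0L else nrow(db2)
  manifest$n_dropped_duplicates <-
    (manifest$n_db1_raw - manifest$n_db1) + (manifest$n_db2_raw - manifest$n_db2)

  frame <- cfg$term_frame %||% oral_term_frame()
  oral <- stage("classify_terms", {
    uni <- union(term_universe(db1),
                 if (is.null(db2)) character() else term_universe(db2))
    classify_oral_terms(uni, frame)
  })
  manifest$n_frame_terms <- nrow(frame)
  manifest$n_oral_terms_observed <- nrow(oral)

  rates <- stage("reporting_rates", {
    t1 <- arr_table(db1, frame, scope = cfg$scope)
    tr <- trim_rare(t1, cfg$min_trim)
    list(table = t1, kept = tr$kept, trimmed = tr$trimmed)
  })
  manifest$n_kept_terms <- nrow(rates$kept)
  manifest$n_trimmed_terms <- nrow(rates$trimmed)

  cross <- stage("cross_database", {
    if (is.null(db2)) stop("db2 input is required for the cross-database stage")
    t2 <- arr_table(db2, frame, scope = cfg$scope)
    t2 <- t2[t2$term %in% rates$kept$term, ]
    class(t2) <- class(rates$kept)
    cross_db_table(rates$kept, t2)
  })
  tr_out <- merge(
    setNames(as.data.frame(rates$kept)[c("term", "group", "n_cases", "arr")],
             c("term", "group", "n_db1", "arr_db1")),
    setNames(cross[, c("term", "n2", "arr2")], c("term", "n_db2", "arr_db2")),
    by = "term", sort = FALSE)
  tr_out$arr_db1 <- round(tr_out$arr_db1, 3)
  tr_out$arr_db2 <- round(tr_out$arr_db2, 3)
  emit(tr_out, "term_rates.csv")
  cross_out <- cross
  for (col in c("arr1", "arr2")) cross_out[[col]] <- round(cross_out[[col]], 3)
  for (col in c("or", "ci_low", "ci_high")) cross_out[[col]] <- round(cross_out[[col]], 2)
  emit(cross_out, "cross_database.csv")

  screen <- stage("disproportionality", {
    sdr_screen(db2, rates$kept$term, scope = cfg$scope,
               min_covid = cfg$min_covid, min_comparator = cfg$min_comparator)
  })
  screen_out <- as.data.frame(screen)
  num <- vapply(screen_out, is.numeric, logical(1))
  screen_out[num] <- lapply(screen_out[num], round, 2)
  emit(screen_out, "disproportionality.csv")
  manifest$n_sdr <- sum(screen$sdr == "yes")
  manifest$n_disqualified <- sum(screen$sdr == "disqualified")

  top <- top_terms(rates$kept, cfg$top_k)
  sub <- stage("subgroup_analysis", subgroup_tables(db1, top, scope = cfg$scope))
  sub_out <- sub
  sub_out$arr <- round(sub_out$arr, 3)
  sub_out$ci_low <- round(sub_out$ci_low, 3)
  sub_out$ci_high <- round(sub_out$ci_high, 3)
  emit(sub_out, "subgroup.csv")
  emit(sub_out[, c("term", "variable", "stratum", "arr", "ci_low", "ci_high")],
       "subgroup_forest.csv")

  reg <- stage("regression", {
    fits <- list()
    for (tm in top) {
      d <- build_design(db1, tm, scope = cfg$scope)
      if (sum(d$y) >= 1L && sum(d$y) < length(d$y))
        fits[[tm]] <- fit_logistic(d)
    }
    aor_table(fits)
  })
  reg_out <- reg
  for (col in c("aor", "ci_low", "ci_high"))
    reg_out[[col]] <- round(reg_out[[col]], 2)
  emit(reg_out, "regression.csv")
  manifest$n_regression_terms <- length(unique(reg$term))
  manifest$top_terms <- top

  stage("manifest", {
    path <- file.path(cfg$output_dir, "manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
    written <<- c(written, path)
  })
  invisible(list(db1 = db1, db2 = db2, rates = rates, cross = cross,
                 screen = screen, subgroup = sub, regression = reg,
                 manifest = manifest))
}
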
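#' Build an ICSR collection from a data frame
#'
#' An `icsr_collection` holds one row per individual case safety report
#' (ICSR) with the covariates `sex`, `age_group`, `vaccine_type`,
#' `schedule`, `year`, `vaccine_class`, and up to five preferred terms in
#' `term1..term5` (first term = primary symptom). Two dialects are
#' supported: `single_term` (PEI-style chief complaint, exactly one term
#' per report) and `multi_term` (VAERS-style, one to five terms).
#'
#' @param data data frame. Required: `report_id` and `term1` (or a `term`
#'   column, taken as `term1`). Missing covariate columns are filled with
#'   the `missing` category; `vaccine_class` defaults to `covid19`.
#' @param dialect `"single_term"` or `"multi_term"`.
#' @return an object of classes `icsr_collection` and `data.frame`, with
#'   the dialect stored in `attr(, "dialect")`.
#' @seealso [read_icsr_table()], [merge_duplicates()], [term_case_count()]
#' @export
icsr_collection <- function(data, dialect = c("single_term", "multi_term")) {
  dialect <- match.arg(dialect)
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!"report_id" %in% names(data)) stop_domain("missing column: report_id")
  if ("term" %in% names(data) && !"term1" %in% names(data))
    names(data)[names(data) == "term"] <- "term1"
  if (!"term1" %in% names(data)) stop_domain("missing column: term1 (or term)")
  for (col in setdiff(TERM_COLS, names(data))) data[[col]] <- NA_character_
  defaults <- list(sex = "missing", age_group = "missing",
                   vaccine_type = "missing", schedule = "missing")
  for (col in names(defaults))
    if (!col %in% names(data)) data[[col]] <- defaults[[col]]
  if (!"year" %in% names(data)) data$year <- NA_integer_
  if (!"vaccine_class" %in% names(data)) data$vaccine_class <- "covid19"

  data$report_id <- as.character(data$report_id)
  for (col in TERM_COLS) {
    v <- as.character(data[[col]])
    v[!is.na(v) & !nzchar(trimws(v))] <- NA_character_
    data[[col]] <- ifelse(is.na(v), NA_character_, normalize_term(v))
  }
  data$sex <- check_enum(data$sex, SEX_LEVELS, "sex")
  data$age_group <- check_enum(data$age_group, AGE_LEVELS, "age_group")
  data$vaccine_type <- check_enum(data$vaccine_type, VACCINE_TYPE_LEVELS, "vaccine_type")
  data$schedule <- check_enum(data$schedule, SCHEDULE_LEVELS, "schedule")
  data$vaccine_class <- check_enum(data$vaccine_class, VACCINE_CLASS_LEVELS, "vaccine_class")
  data$year <- suppressWarnings(as.integer(data$year))

  if (any(is.na(data$term1)))
    stop_domain("every record needs a non-empty primary term")
  extra <- !is.na(as.matrix(data[TERM_COLS[-1]]))
  if (dialect == "single_term" && any(extra))
    stop_domain("single_term dialect admits exactly one term per record")

  out <- data[, c("report_id", "sex", "age_group", "vaccine_type",
                  "schedule", "year", "vaccine_class", TERM_COLS)]
  rownames(out) <- NULL
  attr(out, "dialect") <- dialect
  class(out) <- c("icsr_collection", "data.frame")
  out
}

check_enum <- function(x, levels, what) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x) | !nzchar(x)] <- "missing"
  bad <- !(x %in% levels)
  if (any(bad)) stop_domain("invalid ", what, " value(s): ",
                            paste(unique(x[bad]), collapse = ", "))
  x
}

#' @export
print.icsr_collection <- function(x, ...) {
  cat(sprintf("ICSR collection (%s dialect): %d reports\n",
              attr(x, "dialect"), nrow(x)))
  cls <- table(x$vaccine_class)
  if (length(cls) > 1L)
    cat(sprintf("  vaccine class: %s\n",
                paste(sprintf("%s=%d", names(cls), cls), collapse = ", ")))
  invisible(x)
}

#' Number of reports in a collection
#' @param c an `icsr_collection`.
#' @return integer count of records.
#' @export
n_total <- function(c) {
  stopifnot(inherits(c, "icsr_collection"))
  nrow(c)
}

#' Dialect of a collection
#' @param c an `icsr_collection`.
#' @return `"single_term"` or `"multi_term"`.
#' @export
icsr_dialect <- function(c) attr(c, "dialect")

#' Read an ICSR table from CSV
#'
#' Reads the flat CSV layouts used by the package. Single-term layout:
#' `report_id, sex, age_group, vaccine_type, schedule, year, term`.
#' Multi-term layout: `report_id, sex, age_group, vaccine_type, schedule,
#' year, vaccine_class, term1..term5` (blank-padded). Unknown enum values
#' are mapped to the `missing` category with a warning; rows without a
#' usable `report_id` or primary term are rejected, with their row numbers
#' reported in a warning.
#'
#' @param path CSV file path (UTF-8, header required).
#' @param dialect `"single_term"` or `"multi_term"`.
#' @return an [icsr_collection].
#' @export
read_icsr_table <- function(path, dialect = c("single_term", "multi_term")) {
  dialect <- match.arg(dialect)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop_domain("empty ICSR file: ", path)
  required <- c("report_id", "sex", "age_group", "vaccine_type", "schedule", "year",
                if (dialect == "single_term") "term"
                else c("vaccine_class", TERM_COLS))
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_domain("missing required column(s): ", paste(miss, collapse = ", "))
  if (dialect == "multi_term") {
    stray <- grep("^term[0-9]+$", names(df), value = TRUE)
    over <- setdiff(stray, TERM_COLS)
    if (length(over))
      stop_domain("multi_term dialect admits at most 5 term columns; found: ",
                  paste(over, collapse = ", "))
  }

  if (dialect == "single_term") names(df)[names(df) == "term"] <- "term1"
  term1 <- trimws(df$term1)
  bad_rows <- which(!nzchar(trimws(df$report_id)) | is.na(term1) | !nzchar(term1))
  if (length(bad_rows)) {
    warning(sprintf("rejected %d malformed row(s): %s", length(bad_rows),
                    paste(bad_rows, collapse = ", ")), call. = FALSE)
    df <- df[-bad_rows, , drop = FALSE]
    if (nrow(df) == 0L) stop_domain("no valid rows in ", path)
  }

  # unknown enum values fall back to the missing category, with a warning
  for (col in c("sex", "age_group", "vaccine_type", "schedule")) {
    levels <- switch(col, sex = SEX_LEVELS, age_group = AGE_LEVELS,
                     vaccine_type = VACCINE_TYPE_LEVELS, schedule = SCHEDULE_LEVELS)
    v <- tolower(trimws(df[[col]]))
    unknown <- nzchar(v) & !is.na(v) & !(v %in% levels)
    if (any(unknown)) {
      warning(sprintf("%s: %d unknown value(s) mapped to missing (e.g. \"%s\")",
                      col, sum(unknown), v[unknown][1]), call. = FALSE)
      v[unknown] <- "missing"
    }
    df[[col]] <- v
  }
  if (dialect == "multi_term") {
    v <- tolower(trimws(df$vaccine_class))
    unknown <- !(v %in% VACCINE_CLASS_LEVELS)
    if (any(unknown)) {
      warning(sprintf("vaccine_class: %d unknown value(s) treated as covid19",
                      sum(unknown)), call. = FALSE)
      v[unknown] <- "covid19"
    }
    df$vaccine_class <- v
  }
  yr <- suppressWarnings(as.integer(df$year))
  if (anyNA(yr) && any(nzchar(trimws(df$year)) & is.na(yr)))
    warning("year: non-integer values treated as missing", call. = FALSE)
  df$year <- yr
  icsr_collection(df, dialect)
}

#' Write an ICSR collection to CSV
#'
#' Inverse of [read_icsr_table()]: writes the dialect-specific flat CSV.
#'
#' @param c an [icsr_collection].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_icsr_table <- function(c, path) {
  stopifnot(inherits(c, "icsr_collection"))
  df <- as.data.frame(c)
  if (icsr_dialect(c) == "single_term") {
    df <- df[, c("report_id", "sex", "age_group", "vaccine_type", "schedule",
                 "year", "term1")]
    names(df)[names(df) == "term1"] <- "term"
  } else {
    df <- df[, c("report_id", "sex", "age_group", "vaccine_type", "schedule",
                 "year", "vaccine_class", TERM_COLS)]
    for (col in TERM_COLS) df[[col]][is.na(df[[col]])] <- ""
  }
  write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Merge duplicate reports
#'
#' Records sharing a `report_id` are collapsed to one. Covariate conflicts
#' resolve to the first non-missing value, else the first occurrence; term
#' lists are unioned preserving first-seen order and truncated to the
#' dialect bound (primary term kept). Idempotent.
#'
#' @param c an [icsr_collection].
#' @return an [icsr_collection] with unique `report_id`s.
#' @export
merge_duplicates <- function(c) {
  stopifnot(inherits(c, "icsr_collection"))
  dialect <- icsr_dialect(c)
  if (!anyDuplicated(c$report_id)) return(c)
  dup_ids <- unique(c$report_id[duplicated(c$report_id)])
  is_dup <- c$report_id %in% dup_ids
  keep <- as.data.frame(c)[!is_dup, , drop = FALSE]

  max_terms <- if (dialect == "single_term") 1L else 5L
  pick <- function(v) { nm <- v[v != "missing"]; if (length(nm)) nm[1] else v[1] }
  merged <- lapply(split(as.data.frame(c)[is_dup, , drop = FALSE],
                         factor(c$report_id[is_dup], levels = dup_ids)),
                   function(g) {
    terms <- unique(stats::na.omit(unlist(g[TERM_COLS], use.names = FALSE)))
    terms <- head(terms, max_terms)
    row <- g[1, , drop = FALSE]
    for (col in c("sex", "age_group", "vaccine_type", "schedule"))
      row[[col]] <- pick(g[[col]])
    yr <- g$year[!is.na(g$year)]
    row$year <- if (length(yr)) yr[1] else NA_integer_
    row[TERM_COLS] <- as.list(c(terms, rep(NA_character_, 5L - length(terms))))
    row
  })
  out <- rbind(keep, do.call(rbind, merged))
  out <- out[order(match(out$report_id, c$report_id)), , drop = FALSE]
  icsr_collection(out, dialect)
}

#' Count reports mentioning a term
#'
#' Counts records whose term list contains `term` (`any_position`) or
#' whose primary (first) term equals `term` (`primary_only`); in the
#' single-term dialect the two scopes coincide. In multi-term data the
#' primary term approximates the chief complaint of single-term systems.
#'
#' @param c an [icsr_collection].
#' @param term preferred term (normalised internally).
#' @param scope `"any_position"` or `"primary_only"`.
#' @return integer count.
#' @export
term_case_count <- function(c, term, scope = c("any_position", "primary_only")) {
  scope <- match.arg(scope)
  stopifnot(inherits(c, "icsr_collection"))
  term <- normalize_term(term)
  if (scope == "primary_only") return(sum(c$term1 == term, na.rm = TRUE))
  m <- as.matrix(as.data.frame(c)[TERM_COLS])
  sum(rowSums(m == term, na.rm = TRUE) > 0L)
}

# counts for many terms in one pass; returns named integer vector
term_counts <- function(c, terms, scope = "any_position") {
  terms <- normalize_term(terms)
  if (scope == "primary_only") {
    tab <- table(factor(c$term1, levels = terms))
  } else {
    m <- as.data.frame(c)[TERM_COLS]
    long <- data.frame(rec = rep(seq_len(nrow(c)), 5L),
                       term = unlist(m, use.names = FALSE))
    long <- long[!is.na(long$term) & long$term %in% terms, , drop = FALSE]
    long <- unique(long)  # a term repeated within one report counts once
    tab <- table(factor(long$term, levels = terms))
  }
  setNames(as.integer(tab), terms)
}

#' Term universe of a collection
#'
#' All distinct preferred terms appearing in any term position.
#'
#' @param c an [icsr_collection].
#' @return character vector, sorted.
#' @export
term_universe <- function(c) {
  stopifnot(inherits(c, "icsr_collection"))
  sort(unique(stats::na.omit(unlist(as.data.frame(c)[TERM_COLS], use.names = FALSE))))
}
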
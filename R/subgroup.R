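#' Top reported terms
#'
#' The `k` terms with the largest case counts, ties broken by term name
#' (lexicographically earlier term kept).
#'
#' @param rows a `term_rate_table` (see [arr_table()]).
#' @param k number of terms (default 20).
#' @return character vector of terms, most reported first.
#' @export
top_terms <- function(rows, k = 20L) {
  if (nrow(rows) == 0L) stop_domain("rows must be non-empty")
  ord <- order(-rows$n_cases, rows$term)
  head(rows$term[ord], k)
}

# three-level age regrouping used by all subgroup and regression analyses
age3_of <- function(age_group) {
  ifelse(age_group %in% c("under2", "2to6", "7to17"), "minors",
  ifelse(age_group == "18to59", "adults",
  ifelse(age_group == "over59", "seniors", "missing")))
}

#' Stratified reporting rates for one term
#'
#' Splits the collection by a stratification variable, excluding records
#' with the variable missing from both numerators and denominators, and
#' computes per-stratum case counts, denominators and ARRs with exact
#' binomial 95% CIs (per 1000). Homogeneity across strata is tested on
#' the strata x (case, non-case) table with Pearson's chi-squared test;
#' when any expected cell is below 5 the test switches to Fisher's exact
#' test (exact for 2 x 2; simulated p-value under a fixed internal seed
#' for wider tables). Age uses the three-level regrouping minors (<18),
#' adults (18-59), seniors (>59); for vaccine type, strata without any
#' case are excluded from the test (but kept in the table) to avoid
#' degenerate zero rows.
#'
#' @param c an [icsr_collection].
#' @param term preferred term.
#' @param variable one of `sex`, `age3`, `year`, `vaccine_type`,
#'   `schedule`.
#' @param scope term-counting scope, see [term_case_count()].
#' @param years calendar years retained as strata when
#'   `variable = "year"` (default 2021-2023; years outside the set are
#'   treated as missing).
#' @return a `stratum_table`: list with `term`, `variable`, `strata` (data
#'   frame `label`, `n_cases`, `n_denominator`, `arr`, `ci_low`,
#'   `ci_high`), `p_value`, `method`, `tested` (labels entering the test).
#' @export
stratify <- function(c, term,
                     variable = c("sex", "age3", "year", "vaccine_type", "schedule"),
                     scope = c("any_position", "primary_only"),
                     years = c(2021L, 2022L, 2023L)) {
  variable <- match.arg(variable)
  scope <- match.arg(scope)
  stopifnot(inherits(c, "icsr_collection"))
  term <- normalize_term(term)

  lab <- switch(variable,
    sex = c$sex,
    age3 = age3_of(c$age_group),
    year = ifelse(!is.na(c$year) & c$year %in% years, as.character(c$year), "missing"),
    vaccine_type = c$vaccine_type,
    schedule = c$schedule)
  levels <- switch(variable,
    sex = c("female", "male"),
    age3 = c("minors", "adults", "seniors"),
    year = as.character(sort(years)),
    vaccine_type = setdiff(VACCINE_TYPE_LEVELS, "missing"),
    schedule = c("primer", "booster"))

  keep <- lab != "missing"
  lab <- factor(lab[keep], levels = levels)
  has <- if (scope == "primary_only") {
    (!is.na(c$term1) & c$term1 == term)[keep]
  } else {
    m <- as.matrix(as.data.frame(c)[TERM_COLS])
    (rowSums(m == term, na.rm = TRUE) > 0L)[keep]
  }

  den <- as.integer(table(lab))
  cases <- as.integer(table(lab[has]))
  present <- den > 0L
  if (sum(present) < 2L)
    stop_domain("need >= 2 informative strata for ", variable)
  strata <- data.frame(label = levels[present],
                       n_cases = cases[present],
                       n_denominator = den[present],
                       stringsAsFactors = FALSE)
  strata$arr <- arr(strata$n_cases, strata$n_denominator)
  ci <- t(vapply(seq_len(nrow(strata)), function(i) {
    stats::binom.test(strata$n_cases[i], strata$n_denominator[i])$conf.int * 1000
  }, numeric(2)))
  strata$ci_low <- ci[, 1]; strata$ci_high <- ci[, 2]

  test_rows <- if (variable == "vaccine_type") strata$n_cases >= 1L
               else rep(TRUE, nrow(strata))
  if (sum(test_rows) >= 2L) {
    m <- rbind(case = strata$n_cases[test_rows],
               noncase = strata$n_denominator[test_rows] - strata$n_cases[test_rows])
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    if (any(expected < 5)) {
      method <- "fisher"
      p <- if (ncol(m) == 2L) fisher.test(m)$p.value
           else with_local_seed(104729L,
                  fisher.test(m, simulate.p.value = TRUE, B = 20000L)$p.value)
    } else {
      method <- "chi_square"
      p <- suppressWarnings(chisq.test(m, correct = FALSE))$p.value
    }
  } else {
    method <- "none"; p <- NA_real_
  }

  structure(list(term = term, variable = variable, strata = strata,
                 p_value = p, method = method,
                 tested = strata$label[test_rows]),
            class = "stratum_table")
}

#' @export
print.stratum_table <- function(x, ...) {
  cat(sprintf("'%s' by %s (%s test, p = %s)\n", x$term, x$variable, x$method,
              if (is.na(x$p_value)) "NA" else format(x$p_value, digits = 3)))
  df <- x$strata
  df$arr <- round(df$arr, 3)
  df$ci_low <- round(df$ci_low, 3); df$ci_high <- round(df$ci_high, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Subgroup tables for several terms and variables
#'
#' Long-format assembly of [stratify()] across terms and stratification
#' variables; one row per term x stratum, suitable for CSV export and
#' forest plotting.
#'
#' @param c an [icsr_collection].
#' @param terms character vector of preferred terms.
#' @param variables stratification variables (default all five).
#' @inheritParams stratify
#' @return data frame: `term`, `variable`, `stratum`, `n_cases`,
#'   `n_denominator`, `arr`, `ci_low`, `ci_high`, `p_value`, `method`.
#' @export
subgroup_tables <- function(c, terms,
                            variables = c("sex", "age3", "year",
                                          "vaccine_type", "schedule"),
                            scope = "any_position",
                            years = c(2021L, 2022L, 2023L)) {
  rows <- list()
  for (tm in terms) for (v in variables) {
    st <- stratify(c, tm, v, scope = scope, years = years)
    rows[[length(rows) + 1L]] <- data.frame(
      term = st$term, variable = v, stratum = st$strata$label,
      n_cases = st$strata$n_cases, n_denominator = st$strata$n_denominator,
      arr = st$strata$arr, ci_low = st$strata$ci_low,
      ci_high = st$strata$ci_high,
      p_value = st$p_value, method = st$method, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
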
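#' Cross-database odds ratio for one term
#'
#' Odds ratio of a term being reported in database 1 versus database 2:
#' `OR = (a/(n1-a)) / (b/(n2-b))`, with a Woolf (log-normal) 95% CI using
#' `SE = sqrt(1/a + 1/(n1-a) + 1/b + 1/(n2-b))` and a 1.96 multiplier.
#' Zero cells are reported as-is rather than continuity-corrected: `b = 0`
#' with `a > 0` gives an infinite OR with undefined CI bounds, `a = 0`
#' with `b > 0` gives OR 0, matching how all-or-nothing contrasts are
#' printed in surveillance tables.
#'
#' @param a,b case counts in databases 1 and 2.
#' @param n1,n2 total reports in databases 1 and 2.
#' @return an `or_estimate`: list with `or`, `ci_low`, `ci_high`,
#'   `ci_defined`, and the inputs.
#' @export
#' @examples
#' est <- odds_ratio(481, 974931, 296, 1016024)
#' round(c(est$or, est$ci_low, est$ci_high), 2)  # 1.69 1.47 1.96
odds_ratio <- function(a, n1, b, n2) {
  stopifnot(is_count(a), is_count(b), is_count(n1), is_count(n2))
  if (n1 < 1 || n2 < 1) stop_domain("database totals must be >= 1")
  if (a > n1 || b > n2) stop_domain("case count exceeds database total")
  if (a == n1 || b == n2)
    stop_domain("degenerate denominator: every report is a case")
  if (a == 0 && b == 0) {
    or <- NaN; ci <- c(NA_real_, NA_real_); defined <- FALSE
  } else if (b == 0) {
    or <- Inf; ci <- c(NA_real_, NA_real_); defined <- FALSE
  } else if (a == 0) {
    or <- 0; ci <- c(NA_real_, NA_real_); defined <- FALSE
  } else {
    or <- (a / (n1 - a)) / (b / (n2 - b))
    se <- sqrt(1/a + 1/(n1 - a) + 1/b + 1/(n2 - b))
    ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
    defined <- TRUE
  }
  structure(list(or = or, ci_low = ci[1], ci_high = ci[2],
                 ci_defined = defined, a = a, b = b, n1 = n1, n2 = n2),
            class = "or_estimate")
}

#' @export
print.or_estimate <- function(x, ...) {
  if (x$ci_defined)
    cat(sprintf("OR %.2f (95%% CI %.2f-%.2f)  [a=%d/n1=%d vs b=%d/n2=%d]\n",
                x$or, x$ci_low, x$ci_high, x$a, x$n1, x$b, x$n2))
  else
    cat(sprintf("OR %s (CI undefined)  [a=%d/n1=%d vs b=%d/n2=%d]\n",
                format(x$or), x$a, x$n1, x$b, x$n2))
  invisible(x)
}

#' Cross-database comparison table
#'
#' Joins two per-term rate tables (same kept term set) and computes the
#' database-1 vs database-2 odds ratio per term, tagging each term as
#' `db1_dominant` (CI lower bound > 1), `db2_dominant` (CI upper bound
#' < 1), or `indeterminate` (CI spans 1, or undefined because of a zero
#' cell).
#'
#' @param rows1,rows2 `term_rate_table`s for the two databases, aligned on
#'   the same term set.
#' @return data frame: `term`, `n1`, `arr1`, `n2`, `arr2`, `or`,
#'   `ci_low`, `ci_high`, `dominance`.
#' @export
cross_db_table <- function(rows1, rows2) {
  if (!setequal(rows1$term, rows2$term))
    stop_domain("rows1 and rows2 must cover the same term set")
  rows2 <- rows2[match(rows1$term, rows2$term), ]
  out <- data.frame(term = rows1$term,
                    n1 = rows1$n_cases, arr1 = rows1$arr,
                    n2 = rows2$n_cases, arr2 = rows2$arr,
                    or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    dominance = "indeterminate", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    est <- odds_ratio(out$n1[i], rows1$n_total[i], out$n2[i], rows2$n_total[i])
    out$or[i] <- est$or
    out$ci_low[i] <- est$ci_low
    out$ci_high[i] <- est$ci_high
    if (est$ci_defined) {
      if (est$ci_low > 1) out$dominance[i] <- "db1_dominant"
      else if (est$ci_high < 1) out$dominance[i] <- "db2_dominant"
    }
  }
  rownames(out) <- NULL
  out
}

#' Compare covariate distributions between two databases
#'
#' Builds the 2 x k table of a covariate over its non-missing categories
#' (the `missing` category is excluded from both margins, as in published
#' characteristic tables) and tests homogeneity with Pearson's chi-squared
#' test without continuity correction. When any expected cell is below 5
#' the test switches to Fisher's exact test for 2 x 2 tables; larger
#' sparse tables keep the chi-squared statistic with a warning.
#'
#' @param c1,c2 [icsr_collection]s.
#' @param variable one of `sex`, `age_group`, `vaccine_type`, `schedule`,
#'   `year`.
#' @return a `characteristic_test`: list with `variable`, `counts1`,
#'   `counts2`, `statistic`, `df`, `p_value`, `method`.
#' @export
compare_characteristics <- function(c1, c2,
    variable = c("sex", "age_group", "vaccine_type", "schedule", "year")) {
  variable <- match.arg(variable)
  stopifnot(inherits(c1, "icsr_collection"), inherits(c2, "icsr_collection"))
  res <- compare_category_counts(covariate_counts(c1, variable),
                                 covariate_counts(c2, variable))
  res$variable <- variable
  res
}

covariate_counts <- function(c, variable) {
  v <- if (variable == "year") as.character(c$year) else c[[variable]]
  v <- v[!is.na(v) & v != "missing"]
  tab <- table(v)
  setNames(as.integer(tab), names(tab))
}

#' Homogeneity test on two category-count vectors
#'
#' Core of [compare_characteristics()], usable directly on published
#' summary counts. Categories absent from both vectors are dropped.
#'
#' @param counts1,counts2 named integer vectors of category counts
#'   (missing already excluded).
#' @return a `characteristic_test` (see [compare_characteristics()]).
#' @export
compare_category_counts <- function(counts1, counts2) {
  cats <- union(names(counts1), names(counts2))
  x1 <- setNames(rep(0L, length(cats)), cats)
  x1[names(counts1)] <- counts1
  x2 <- setNames(rep(0L, length(cats)), cats)
  x2[names(counts2)] <- counts2
  keep <- (x1 + x2) > 0L
  x1 <- x1[keep]; x2 <- x2[keep]
  if (length(x1) < 2L)
    stop_domain("need at least 2 non-missing categories")
  m <- rbind(db1 = x1, db2 = x2)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  method <- "chi_square"
  if (any(expected < 5)) {
    if (ncol(m) == 2L) {
      method <- "fisher"
      ft <- fisher.test(m)
      return(structure(list(variable = NA_character_, counts1 = x1, counts2 = x2,
                            statistic = NA_real_, df = NA_integer_,
                            p_value = ft$p.value, method = method),
                       class = "characteristic_test"))
    }
    warning("expected cell < 5 in a table wider than 2x2; keeping chi-squared",
            call. = FALSE)
  }
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  structure(list(variable = NA_character_, counts1 = x1, counts2 = x2,
                 statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value, method = method),
            class = "characteristic_test")
}

#' @export
print.characteristic_test <- function(x, ...) {
  cat(sprintf("Characteristic comparison%s: %s test, p = %.3g\n",
              if (!is.na(x$variable)) paste0(" (", x$variable, ")") else "",
              x$method, x$p_value))
  print(rbind(db1 = x$counts1, db2 = x$counts2))
  invisible(x)
}
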
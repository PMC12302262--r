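#' Absolute reporting ratio (cases per 1000 ICSRs)
#'
#' The absolute reporting ratio (ARR) of a term is the number of reported
#' cases per 1000 individual case safety reports in the database:
#' `1000 * n_cases / n_total`. Reporting layers round to 3 decimals.
#'
#' @param n_cases number of reports mentioning the term (vectorised).
#' @param n_total total reports in the database (must be >= 1).
#' @return numeric ARR per 1000 reports (unrounded).
#' @export
#' @examples
#' round(arr(481, 974931), 3)  # 0.493
arr <- function(n_cases, n_total) {
  if (any(n_total < 1)) stop_domain("n_total must be >= 1")
  if (any(n_cases < 0) || any(n_cases > n_total))
    stop_domain("n_cases must lie in [0, n_total]")
  1000 * n_cases / n_total
}

#' Per-term reporting-rate table
#'
#' One row per vocabulary term with its case count (under the chosen
#' counting scope) and ARR against the collection's full denominator.
#' Rows are sorted by descending case count, ties broken by term name.
#'
#' @param c an [icsr_collection].
#' @param frame an [ae_term_frame].
#' @param scope term-counting scope, see [term_case_count()].
#' @return a `term_rate_table`: data frame with columns `term`, `group`,
#'   `n_cases`, `n_total`, `arr`.
#' @export
arr_table <- function(c, frame, scope = c("any_position", "primary_only")) {
  scope <- match.arg(scope)
  stopifnot(inherits(c, "icsr_collection"), inherits(frame, "ae_term_frame"))
  if (nrow(frame) == 0L) {
    out <- data.frame(term = character(), group = character(),
                      n_cases = integer(), n_total = integer(), arr = numeric())
  } else {
    counts <- term_counts(c, frame$term, scope)
    out <- data.frame(term = frame$term, group = frame$group,
                      n_cases = as.integer(counts[frame$term]),
                      n_total = nrow(c),
                      arr = arr(as.integer(counts[frame$term]), nrow(c)),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$n_cases, out$term), ]
  }
  rownames(out) <- NULL
  class(out) <- c("term_rate_table", "data.frame")
  out
}

#' @export
print.term_rate_table <- function(x, ...) {
  cat(sprintf("Term reporting rates: %d terms, N = %s ICSRs\n", nrow(x),
              format(if (nrow(x)) x$n_total[1] else 0, big.mark = ",")))
  df <- as.data.frame(x)
  df$arr <- round(df$arr, 3)
  print(head(df, 10), ...)
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Trim rarely reported terms
#'
#' Splits a rate table into terms with at least `min_count` reports and
#' the trimmed remainder, both preserving input order. In the published
#' screen, terms with fewer than three reports in the single-term (PEI)
#' database were trimmed before any comparative analysis.
#'
#' @param rows a `term_rate_table` (or compatible data frame with an
#'   `n_cases` column).
#' @param min_count minimum case count to keep (default 3).
#' @return list with components `kept` and `trimmed`.
#' @export
trim_rare <- function(rows, min_count = 3L) {
  if (!is_count(min_count) || min_count < 1) stop_domain("min_count must be >= 1")
  stopifnot("n_cases" %in% names(rows))
  keep <- rows$n_cases >= min_count
  list(kept = rows[keep, , drop = FALSE],
       trimmed = rows[!keep, , drop = FALSE])
}
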
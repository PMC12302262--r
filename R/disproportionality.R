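#' 2x2 reporting table for one term
#'
#' Counts, within a multi-term collection, reports of the exposure class
#' (COVID-19 vaccines) and the comparator class with and without the term:
#' `a` = term & covid19, `b` = no term & covid19, `c` = term & comparator,
#' `d` = no term & comparator.
#'
#' @param c a multi-term [icsr_collection].
#' @param term preferred term.
#' @param scope term-counting scope, see [term_case_count()].
#' @return a `contingency_2x2` (list `a`, `b`, `c`, `d`).
#' @export
build_2x2 <- function(c, term, scope = c("any_position", "primary_only")) {
  scope <- match.arg(scope)
  stopifnot(inherits(c, "icsr_collection"))
  if (icsr_dialect(c) != "multi_term")
    stop_domain("disproportionality needs the multi_term dialect")
  term <- normalize_term(term)
  has <- if (scope == "primary_only") {
    !is.na(c$term1) & c$term1 == term
  } else {
    m <- as.matrix(as.data.frame(c)[TERM_COLS])
    rowSums(m == term, na.rm = TRUE) > 0L
  }
  covid <- c$vaccine_class == "covid19"
  contingency_2x2(sum(has & covid), sum(!has & covid),
                  sum(has & !covid), sum(!has & !covid))
}

#' Construct a 2x2 reporting table from counts
#' @param a,b,c,d non-negative integer cell counts (see [build_2x2()]).
#' @return a `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  for (x in list(a, b, c, d))
    if (!is_count(x)) stop_domain("cells must be non-negative integers")
  structure(list(a = as.integer(a), b = as.integer(b),
                 c = as.integer(c), d = as.integer(d)),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2,
              dimnames = list(c("covid19", "comparator"), c("term", "no term")))
  print(m)
  invisible(x)
}

#' Proportional reporting ratio
#'
#' `PRR = (a/(a+b)) / (c/(c+d))` with a log-scale normal 95% CI,
#' `SE = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`. Undefined (with
#' `defined = FALSE`) when `a = 0` or `c = 0`.
#'
#' @param t a `contingency_2x2`.
#' @return list `estimate`, `ci_low`, `ci_high`, `defined`.
#' @export
prr <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  if (t$a == 0 || t$c == 0 || (t$a + t$b) == 0 || (t$c + t$d) == 0)
    return(list(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                defined = FALSE))
  est <- (t$a / (t$a + t$b)) / (t$c / (t$c + t$d))
  se <- sqrt(1/t$a - 1/(t$a + t$b) + 1/t$c - 1/(t$c + t$d))
  ci <- exp(log(est) + c(-1, 1) * 1.96 * se)
  list(estimate = est, ci_low = ci[1], ci_high = ci[2], defined = TRUE)
}

#' Reporting odds ratio
#'
#' `ROR = (a d)/(b c)` with a log-scale normal 95% CI,
#' `SE = sqrt(1/a + 1/b + 1/c + 1/d)`. Undefined on any zero cell.
#'
#' @param t a `contingency_2x2`.
#' @return list `estimate`, `ci_low`, `ci_high`, `defined`.
#' @export
ror <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  if (t$a == 0 || t$b == 0 || t$c == 0 || t$d == 0)
    return(list(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                defined = FALSE))
  est <- (t$a * t$d) / (t$b * t$c)
  se <- sqrt(1/t$a + 1/t$b + 1/t$c + 1/t$d)
  ci <- exp(log(est) + c(-1, 1) * 1.96 * se)
  list(estimate = est, ci_low = ci[1], ci_high = ci[2], defined = TRUE)
}

#' Shrinkage information component
#'
#' Bayesian observed-vs-expected measure on the log2 scale with +0.5
#' continuity shrinkage: `IC = log2((a + 0.5)/(E + 0.5))`, where the
#' expected count uses the within-database margins of the 2x2,
#' `E = (a+c)(a+b)/N`. The lower 2.5th-percentile credibility bound is
#' the standard two-term approximation
#' `IC025 = IC - 3.3 (a+0.5)^(-1/2) - 2 (a+0.5)^(-3/2)`, which tracks the
#' 2.5th percentile of a gamma posterior for the observed-to-expected
#' ratio.
#'
#' @param t a `contingency_2x2` with at least one report.
#' @return list `ic`, `ic025`, `expected`.
#' @export
information_component <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  n <- t$a + t$b + t$c + t$d
  if (n == 0) stop_domain("empty 2x2 table")
  e <- (t$a + t$c) * (t$a + t$b) / n
  ic <- log2((t$a + 0.5) / (e + 0.5))
  ic025 <- ic - 3.3 * (t$a + 0.5)^(-0.5) - 2 * (t$a + 0.5)^(-1.5)
  list(ic = ic, ic025 = ic025, expected = e)
}

#' Qualification for disproportionality analysis
#'
#' A term qualifies when the exposure arm has at least `min_covid` reports
#' and the comparator arm at least `min_comparator`, and all three metrics
#' (PRR, ROR, IC) are computable (no disqualifying zero cell). Terms
#' failing qualification are reported as `disqualified`, mirroring the NA
#' rows of published screens.
#'
#' @param t a `contingency_2x2`.
#' @param min_covid minimum exposure-arm case count (default 3).
#' @param min_comparator minimum comparator-arm case count (default 1).
#' @return logical.
#' @export
qualify <- function(t, min_covid = 3L, min_comparator = 1L) {
  stopifnot(inherits(t, "contingency_2x2"))
  t$a >= min_covid && t$c >= min_comparator && t$b >= 1L && t$d >= 1L
}

#' Composite SDR classification
#'
#' Applies the hybrid signal-of-disproportionate-reporting rule: a
#' qualified term is a signal (`yes`) iff (i) PRR >= 2 with 95% CI lower
#' bound >= 1, (ii) ROR >= 2 with 95% CI lower bound >= 1, and (iii) both
#' the IC point estimate and IC025 are > 0; otherwise `no`. Unqualified
#' terms are `disqualified`.
#'
#' @param metrics data frame (or coercible list) with columns `prr`,
#'   `prr_low`, `ror`, `ror_low`, `ic`, `ic025` and optionally
#'   `qualified` (default: rows with a non-missing PRR are qualified).
#' @return character vector of `"yes"`, `"no"`, `"disqualified"`.
#' @export
#' @examples
#' classify_sdr(data.frame(prr = 17.57, prr_low = 10.28, ror = 17.57,
#'                         ror_low = 10.28, ic = 4.14, ic025 = 3.60))
classify_sdr <- function(metrics) {
  metrics <- as.data.frame(metrics)
  qualified <- metrics$qualified %||% !is.na(metrics$prr)
  hit <- metrics$prr >= 2 & metrics$prr_low >= 1 &
         metrics$ror >= 2 & metrics$ror_low >= 1 &
         metrics$ic > 0 & metrics$ic025 > 0
  ifelse(!qualified, "disqualified", ifelse(!is.na(hit) & hit, "yes", "no"))
}

#' Disproportionality screen over a term set
#'
#' Builds the 2x2 table for every term, computes PRR, ROR and IC with
#' their interval bounds, applies qualification and the composite SDR
#' rule.
#'
#' @param c a multi-term [icsr_collection] containing both vaccine
#'   classes.
#' @param terms character vector of preferred terms to screen.
#' @inheritParams build_2x2
#' @inheritParams qualify
#' @return an `sdr_screen`: data frame with the 2x2 cells, all metrics and
#'   the `sdr` status per term.
#' @export
sdr_screen <- function(c, terms, scope = c("any_position", "primary_only"),
                       min_covid = 3L, min_comparator = 1L) {
  scope <- match.arg(scope)
  terms <- normalize_term(terms)
  rows <- lapply(terms, function(tm) {
    t <- build_2x2(c, tm, scope)
    p <- prr(t); r <- ror(t)
    q <- qualify(t, min_covid, min_comparator)
    ic <- if (t$a + t$b + t$c + t$d > 0) information_component(t)
          else list(ic = NA_real_, ic025 = NA_real_)
    data.frame(term = tm, a = t$a, b = t$b, c = t$c, d = t$d,
               prr = p$estimate, prr_low = p$ci_low, prr_high = p$ci_high,
               ror = r$estimate, ror_low = r$ci_low, ror_high = r$ci_high,
               ic = ic$ic, ic025 = ic$ic025, qualified = q,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$sdr <- classify_sdr(out)
  rownames(out) <- NULL
  class(out) <- c("sdr_screen", "data.frame")
  out
}

#' @export
print.sdr_screen <- function(x, ...) {
  cat(sprintf("Disproportionality screen: %d terms (%d signals, %d no-signal, %d disqualified)\n",
              nrow(x), sum(x$sdr == "yes"), sum(x$sdr == "no"),
              sum(x$sdr == "disqualified")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 2)
  print(head(df[, c("term", "a", "c", "prr", "prr_low", "ror", "ic", "ic025", "sdr")], 12), ...)
  if (nrow(x) > 12) cat("... and", nrow(x) - 12, "more rows\n")
  invisible(x)
}

#' @export
summary.sdr_screen <- function(object, ...) {
  out <- list(n_terms = nrow(object),
              n_signal = sum(object$sdr == "yes"),
              n_no_signal = sum(object$sdr == "no"),
              n_disqualified = sum(object$sdr == "disqualified"),
              signals = object$term[object$sdr == "yes"])
  class(out) <- "summary.sdr_screen"
  out
}

#' @export
print.summary.sdr_screen <- function(x, ...) {
  cat(sprintf("%d terms screened: %d SDRs, %d below threshold, %d disqualified\n",
              x$n_terms, x$n_signal, x$n_no_signal, x$n_disqualified))
  if (length(x$signals)) cat("signals:", paste(x$signals, collapse = ", "), "\n")
  invisible(x)
}
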
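#' Design matrix for a per-term logistic regression
#'
#' Binary outcome: term reported (under the chosen scope) vs not.
#' Predictors are dummy-coded with references male, adults (18-59), mRNA,
#' primer series: `female`, `minors`, `seniors`, `viral_vector`,
#' `protein_subunit`, `inactivated`, `booster`. Comparator-class records
#' are excluded (the model concerns COVID-19 vaccine reports), records
#' missing any predictor are dropped listwise, and non-reference levels
#' with zero cases are recorded as suppressed and dropped from the design
#' (published tables print NA for such cells).
#'
#' @param c an [icsr_collection].
#' @param term preferred term.
#' @param scope term-counting scope, see [term_case_count()].
#' @return list with `term`, `x` (model matrix without intercept), `y`
#'   (0/1 outcome), `n_used`, `suppressed` (character vector of dropped
#'   levels).
#' @export
build_design <- function(c, term, scope = c("any_position", "primary_only")) {
  scope <- match.arg(scope)
  stopifnot(inherits(c, "icsr_collection"))
  term <- normalize_term(term)

  covid <- c$vaccine_class == "covid19"
  age3 <- age3_of(c$age_group)
  complete <- covid & c$sex != "missing" & age3 != "missing" &
    c$vaccine_type != "missing" & c$schedule != "missing"

  has <- if (scope == "primary_only") {
    !is.na(c$term1) & c$term1 == term
  } else {
    m <- as.matrix(as.data.frame(c)[TERM_COLS])
    rowSums(m == term, na.rm = TRUE) > 0L
  }

  y <- as.integer(has[complete])
  cols <- cbind(female = c$sex[complete] == "female",
                minors = age3[complete] == "minors",
                seniors = age3[complete] == "seniors",
                viral_vector = c$vaccine_type[complete] == "viral_vector",
                protein_subunit = c$vaccine_type[complete] == "protein_subunit",
                inactivated = c$vaccine_type[complete] == "inactivated",
                booster = c$schedule[complete] == "booster")
  storage.mode(cols) <- "double"

  # levels with zero cases (or absent levels) cannot be estimated
  suppressed <- colnames(cols)[colSums(cols * y) == 0]
  x <- cols[, setdiff(colnames(cols), suppressed), drop = FALSE]
  list(term = term, x = x, y = y, n_used = length(y), suppressed = suppressed)
}

#' Fit the per-term logistic regression
#'
#' Maximum-likelihood logistic fit (binomial IRLS via [stats::glm()],
#' tolerance 1e-8, at most 100 iterations) of the design from
#' [build_design()], with Wald 95% confidence intervals on the adjusted
#' odds ratios. Quasi-complete separation is detected from runaway
#' coefficients or standard errors and flagged: the fit is marked
#' non-converged and the affected contrasts are reported as unavailable
#' rather than penalised.
#'
#' @param design a design list from [build_design()].
#' @return an `ae_logit`: list with `term`, `coefficients` (data frame
#'   `level`, `estimate`, `se`), `aor` (data frame `level`, `point`,
#'   `ci_low`, `ci_high`, `available`), `n_used`, `converged`,
#'   `suppressed`, and the underlying `glm` fit in `$fit`.
#' @export
fit_logistic <- function(design) {
  y <- design$y
  if (sum(y) == 0L) stop_domain("zero cases: nothing to model")
  if (all(y == 1L)) stop_domain("zero non-cases: nothing to model")
  df <- data.frame(y = y, design$x, check.names = FALSE)
  fml <- if (ncol(design$x))
    stats::as.formula(paste("y ~", paste(sprintf("`%s`", colnames(design$x)),
                                         collapse = " + ")))
  else stats::as.formula("y ~ 1")
  fit <- glm(fml, family = binomial(), data = df,
             control = glm.control(epsilon = 1e-8, maxit = 100))
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  levels <- setdiff(names(est), "(Intercept)")
  levels_clean <- gsub("`", "", levels)

  runaway <- abs(est[levels]) > 15 | se[levels] > 15
  converged <- fit$converged && !any(runaway)

  coefs <- data.frame(level = levels_clean,
                      estimate = unname(est[levels]),
                      se = unname(se[levels]), stringsAsFactors = FALSE)
  aor <- data.frame(level = levels_clean,
                    point = exp(coefs$estimate),
                    ci_low = exp(coefs$estimate - 1.96 * coefs$se),
                    ci_high = exp(coefs$estimate + 1.96 * coefs$se),
                    available = !runaway, stringsAsFactors = FALSE)
  aor[!aor$available, c("point", "ci_low", "ci_high")] <- NA_real_
  structure(list(term = design$term, coefficients = coefs, aor = aor,
                 n_used = design$n_used, converged = converged,
                 suppressed = design$suppressed, fit = fit),
            class = "ae_logit")
}

#' Per-term multivariable logistic regression
#'
#' Convenience wrapper: [build_design()] then [fit_logistic()].
#'
#' @inheritParams build_design
#' @return an `ae_logit` (see [fit_logistic()]).
#' @export
fit_term_logistic <- function(c, term, scope = "any_position") {
  fit_logistic(build_design(c, term, scope))
}

#' @export
print.ae_logit <- function(x, ...) {
  cat(sprintf("Logistic regression for '%s' (n = %s%s)\n", x$term,
              format(x$n_used, big.mark = ","),
              if (!x$converged) ", NOT converged/separated" else ""))
  df <- x$aor
  df$point <- round(df$point, 2)
  df$ci_low <- round(df$ci_low, 2); df$ci_high <- round(df$ci_high, 2)
  print(df, row.names = FALSE)
  if (length(x$suppressed))
    cat("suppressed (zero cases):", paste(x$suppressed, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.ae_logit <- function(object, ...) {
  z <- object$coefficients$estimate / object$coefficients$se
  out <- cbind(object$coefficients,
               z = z, p_value = 2 * stats::pnorm(-abs(z)),
               object$aor[c("point", "ci_low", "ci_high")])
  names(out)[names(out) == "point"] <- "aor"
  out
}

#' @export
coef.ae_logit <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$level)
}

#' Adjusted odds-ratio report over several fits
#'
#' Long-format report with one row per term x contrast: the adjusted OR,
#' its Wald 95% CI, and a significance flag (1 outside the CI). Contrasts
#' suppressed for zero cases, or unavailable due to separation, appear
#' with NA estimates.
#'
#' @param fits list of `ae_logit` objects.
#' @return data frame: `term`, `contrast`, `aor`, `ci_low`, `ci_high`,
#'   `significant`, `available`.
#' @export
aor_table <- function(fits) {
  contrasts <- c("female", "minors", "seniors", "viral_vector",
                 "protein_subunit", "inactivated", "booster")
  rows <- lapply(fits, function(f) {
    stopifnot(inherits(f, "ae_logit"))
    idx <- match(contrasts, f$aor$level)
    data.frame(term = f$term, contrast = contrasts,
               aor = f$aor$point[idx],
               ci_low = f$aor$ci_low[idx], ci_high = f$aor$ci_high[idx],
               significant = !is.na(f$aor$ci_low[idx]) &
                 (f$aor$ci_low[idx] > 1 | f$aor$ci_high[idx] < 1),
               available = !is.na(f$aor$point[idx]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(term = character(), contrast = character(),
                      aor = numeric(), ci_low = numeric(), ci_high = numeric(),
                      significant = logical(), available = logical())
  rownames(out) <- NULL
  out
}
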
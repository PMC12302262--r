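#' Packaged reference summary tables
#'
#' Transcriptions of the published summary tables of the PEI (Germany,
#' December 2020 - December 2023) and VAERS (United States, December 2020 -
#' October 2024) COVID-19 vaccine oral adverse-event surveillance
#' analysis. `reference_characteristics()` returns the per-database
#' covariate counts with the printed percentages;
#' `reference_term_counts()` the per-term case counts, printed ARRs,
#' cross-database ORs and disproportionality metrics (PRR/ROR/IC with
#' bounds and the printed SDR status); `reference_subgroup_counts()` the
#' stratified case counts for the top-20 terms with printed stratum ARRs.
#'
#' These tables serve two purposes: they parameterise
#' [default_sim_config()], and they let the published headline numbers be
#' recomputed from counts alone via [validate_reference_tables()].
#'
#' @return a data frame (see Details).
#' @export
reference_characteristics <- function() {
  read.csv(pkg_extdata("pei_vaers_characteristics.csv"), stringsAsFactors = FALSE,
           colClasses = c(category = "character"))
}

#' @rdname reference_characteristics
#' @export
reference_term_counts <- function() {
  read.csv(pkg_extdata("pei_vaers_term_counts.csv"), stringsAsFactors = FALSE)
}

#' @rdname reference_characteristics
#' @export
reference_subgroup_counts <- function() {
  read.csv(pkg_extdata("pei_subgroup_counts.csv"), stringsAsFactors = FALSE,
           colClasses = c(stratum = "character"))
}

#' Reference database totals
#'
#' Total ICSR counts of the two reference databases, derived from the
#' packaged year counts (the one variable without a missing share).
#'
#' @return named numeric vector with elements `pei` and `vaers`.
#' @export
reference_db_totals <- function() {
  ch <- reference_characteristics()
  vapply(c(pei = "pei", vaers = "vaers"), function(db)
    sum(ch$n[ch$database == db & ch$variable == "year"]), numeric(1))
}

#' Reference stratum denominators (PEI)
#'
#' Denominators for the stratified (subgroup) ARRs of the single-term
#' reference database: sex, three-level age (minors = the three under-18
#' brackets combined), calendar year, vaccine type and schedule, all
#' excluding the missing category.
#'
#' @return named numeric vector keyed by stratum label.
#' @export
reference_stratum_denominators <- function() {
  ch <- reference_characteristics()
  s <- ch[ch$database == "pei" & !ch$is_missing, ]
  pick <- function(variable, category)
    sum(s$n[s$variable == variable & s$category %in% category])
  c(female = pick("sex", "female"), male = pick("sex", "male"),
    minors = pick("age_group", c("under2", "2to6", "7to17")),
    adults = pick("age_group", "18to59"), seniors = pick("age_group", "over59"),
    "2021" = pick("year", "2021"), "2022" = pick("year", "2022"),
    "2023" = pick("year", "2023"),
    mrna = pick("vaccine_type", "mrna"),
    viral_vector = pick("vaccine_type", "viral_vector"),
    protein_subunit = pick("vaccine_type", "protein_subunit"),
    inactivated = pick("vaccine_type", "inactivated"),
    primer = pick("schedule", "primer"), booster = pick("schedule", "booster"))
}

#' Recompute the published headline numbers from packaged counts
#'
#' Re-derives, from the packaged reference counts alone and the package's
#' own estimators, every quantity the published screen prints: per-term
#' ARRs for both databases (3-decimal rounding), cross-database ORs with
#' Woolf CIs (2-decimal rounding, infinite where the comparator count is
#' zero), the SDR classification of the printed PRR/ROR/IC values, the
#' covariate percentages under the missing-excluded convention (2
#' decimals), and the stratified subgroup ARRs. Each component reports
#' the computed value next to the printed one with a match flag.
#'
#' @return a `reference_validation`: list of data frames `arr`, `or`,
#'   `sdr`, `characteristics`, `subgroup`, plus a `summary` data frame of
#'   match counts.
#' @export
validate_reference_tables <- function() {
  counts <- reference_term_counts()
  totals <- reference_db_totals()

  arr_df <- rbind(
    data.frame(term = counts$term, database = "pei",
               computed = round(arr(counts$n_pei, totals[["pei"]]), 3),
               printed = counts$arr_pei, stringsAsFactors = FALSE),
    data.frame(term = counts$term, database = "vaers",
               computed = round(arr(counts$n_vaers, totals[["vaers"]]), 3),
               printed = counts$arr_vaers, stringsAsFactors = FALSE))
  arr_df$match <- arr_df$computed == arr_df$printed

  or_df <- counts[, c("term", "n_pei", "n_vaers", "or")]
  names(or_df)[4] <- "printed"
  ests <- lapply(seq_len(nrow(counts)), function(i)
    odds_ratio(counts$n_pei[i], as.integer(totals[["pei"]]),
               counts$n_vaers[i], as.integer(totals[["vaers"]])))
  or_df$computed <- round(vapply(ests, `[[`, numeric(1), "or"), 2)
  or_df$computed_low <- round(vapply(ests, `[[`, numeric(1), "ci_low"), 2)
  or_df$computed_high <- round(vapply(ests, `[[`, numeric(1), "ci_high"), 2)
  or_df$match <- (is.infinite(or_df$printed) & is.infinite(or_df$computed)) |
    (is.finite(or_df$printed) & or_df$computed == or_df$printed)

  sdr_df <- counts[, c("term", "prr", "prr_low", "ror", "ror_low", "ic", "ic025")]
  sdr_df$printed <- counts$sdr
  sdr_df$computed <- classify_sdr(sdr_df)
  sdr_df$match <- sdr_df$computed == sdr_df$printed

  ch <- reference_characteristics()
  pct <- do.call(rbind, lapply(split(ch, list(ch$database, ch$variable)),
    function(sv) {
      nonmiss <- sum(sv$n[!sv$is_missing])
      total <- reference_db_totals()[[sv$database[1]]]
      data.frame(database = sv$database, variable = sv$variable,
                 category = sv$category,
                 computed = round(100 * sv$n / ifelse(sv$is_missing, total, nonmiss), 2),
                 printed = sv$printed_pct, stringsAsFactors = FALSE)
    }))
  rownames(pct) <- NULL
  pct$match <- is.na(pct$printed) | pct$computed == pct$printed

  sg <- reference_subgroup_counts()
  den <- reference_stratum_denominators()
  sg$computed <- round(arr(sg$n_cases, den[sg$stratum]), 3)
  sg$match <- sg$computed == sg$printed_arr

  out <- list(arr = arr_df, or = or_df, sdr = sdr_df,
              characteristics = pct, subgroup = sg)
  out$summary <- data.frame(
    component = names(out),
    n = vapply(out, nrow, integer(1)),
    n_match = vapply(out, function(d) sum(d$match), integer(1)))
  class(out) <- "reference_validation"
  out
}

#' @export
print.reference_validation <- function(x, ...) {
  cat("Recomputation of published summary tables from packaged counts:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
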
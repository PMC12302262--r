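# small in-code fixtures shared across tests

toy_frame <- function() {
  ae_term_frame(
    data.frame(term = c("taste disorder", "ageusia", "oral herpes", "lip swelling"),
               group = c("taste", "taste", "oral_mucosa", "lips")),
    exclusion_keywords = c("contracept", "cancer"))
}

# single-term collection with explicit covariates; extra columns pass through
toy_single <- function(n = 6, term = "taste disorder", ...) {
  df <- data.frame(report_id = sprintf("r%03d", seq_len(n)),
                   sex = rep(c("female", "male"), length.out = n),
                   age_group = "18to59", vaccine_type = "mrna",
                   schedule = "primer", year = 2021L,
                   term = term, stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  icsr_collection(df, "single_term")
}

toy_multi <- function(terms_list, vaccine_class = "covid19", ...) {
  n <- length(terms_list)
  tm <- t(vapply(terms_list, function(x) c(x, rep(NA_character_, 5 - length(x))),
                 character(5)))
  df <- data.frame(report_id = sprintf("m%03d", seq_len(n)),
                   sex = "female", age_group = "18to59", vaccine_type = "mrna",
                   schedule = "primer", year = 2021L,
                   vaccine_class = rep(vaccine_class, length.out = n),
                   stringsAsFactors = FALSE)
  df[paste0("term", 1:5)] <- as.data.frame(tm, stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  icsr_collection(df, "multi_term")
}

# minimal one-term simulation config for generator tests
mini_sim_config <- function(rate = 1, n = 10000, effects = list(),
                            comparator_fraction = 0.3, comparator_rate = rate,
                            seed = 1L) {
  marg <- list(sex = c(female = 0.6, male = 0.38, missing = 0.02),
               age_group = c(under2 = 0.01, `2to6` = 0.01, `7to17` = 0.03,
                             `18to59` = 0.7, over59 = 0.2, missing = 0.05),
               vaccine_type = c(mrna = 0.8, viral_vector = 0.15,
                                protein_subunit = 0.03, inactivated = 0.01,
                                missing = 0.01),
               schedule = c(primer = 0.9, booster = 0.08, missing = 0.02),
               year = c(`2021` = 0.5, `2022` = 0.4, `2023` = 0.1))
  sim_config(n, n, covariate_marginals = list(db1 = marg, db2 = marg),
             term_rates = c("test term" = rate),
             covariate_effects = effects,
             comparator_fraction = comparator_fraction,
             comparator_term_rates = c("test term" = comparator_rate),
             seed = seed)
}

write_tmp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
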
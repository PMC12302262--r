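#' Configuration for the synthetic ICSR generator
#'
#' Bundles every ground-truth parameter of the paired synthetic databases:
#' db1 is a single-term "chief complaint" database (PEI-like), db2 a
#' multi-term database with a comparator-vaccine arm (VAERS-like).
#'
#' @param n_reports_db1,n_reports_db2 number of reports per database.
#' @param covariate_marginals list with components `db1` and `db2`, each a
#'   list of named probability vectors over `sex`, `age_group`,
#'   `vaccine_type`, `schedule` (each including a `missing` share) and
#'   `year`; every vector must sum to 1 within 1e-9.
#' @param term_rates named vector of baseline per-report oral-term
#'   reporting rates for db1, in cases per 1000 reports.
#' @param term_rates_db2 rates for the COVID-19 arm of db2 (default: same
#'   as `term_rates`).
#' @param covariate_effects named list, term -> named vector of log-odds
#'   offsets for any of `female`, `minors`, `seniors`, `viral_vector`,
#'   `protein_subunit`, `booster` (references: male, adults, mRNA, primer).
#' @param comparator_fraction fraction of db2 reports carrying the
#'   comparator vaccine class, in `[0, 1)`.
#' @param comparator_term_rates per-1000 term rates within the comparator
#'   arm (no covariate effects applied there; default: `term_rates_db2`).
#' @param max_terms_db2 term-list bound for db2 (default 5).
#' @param seed default RNG seed used by [generate_database()].
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_reports_db1, n_reports_db2, covariate_marginals,
                       term_rates, term_rates_db2 = NULL,
                       covariate_effects = list(),
                       comparator_fraction = 0.3,
                       comparator_term_rates = NULL,
                       max_terms_db2 = 5L, seed = 1L) {
  cfg <- list(n_reports_db1 = as.integer(n_reports_db1),
              n_reports_db2 = as.integer(n_reports_db2),
              covariate_marginals = covariate_marginals,
              term_rates = unlist(term_rates),
              term_rates_db2 = if (is.null(term_rates_db2)) unlist(term_rates)
                               else unlist(term_rates_db2),
              covariate_effects = covariate_effects,
              comparator_fraction = comparator_fraction,
              comparator_term_rates = if (is.null(comparator_term_rates)) {
                if (is.null(term_rates_db2)) unlist(term_rates)
                else unlist(term_rates_db2)
              } else unlist(comparator_term_rates),
              max_terms_db2 = as.integer(max_terms_db2),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks report counts, probability ranges, marginal normalisation and
#' the comparator fraction; called by [sim_config()] and again by
#' [generate_database()] before any sampling.
#'
#' @param cfg a `sim_config`.
#' @return `cfg`, invisibly, or an error describing the violation.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_reports_db1 < 1L || cfg$n_reports_db2 < 1L)
    stop_domain("n_reports must be >= 1")
  if (!all(c("db1", "db2") %in% names(cfg$covariate_marginals)))
    stop_domain("covariate_marginals needs components db1 and db2")
  for (db in c("db1", "db2")) {
    marg <- cfg$covariate_marginals[[db]]
    need <- c("sex", "age_group", "vaccine_type", "schedule", "year")
    miss <- setdiff(need, names(marg))
    if (length(miss))
      stop_domain(db, " marginals missing: ", paste(miss, collapse = ", "))
    for (v in need) {
      p <- marg[[v]]
      if (any(p < 0) || any(p > 1))
        stop_domain(db, " ", v, " probabilities outside [0,1]")
      if (abs(sum(p) - 1) > 1e-9)
        stop_domain(db, " ", v, " marginal does not sum to 1 (", sum(p), ")")
    }
  }
  for (nm in c("term_rates", "term_rates_db2", "comparator_term_rates")) {
    r <- cfg[[nm]]
    if (length(r) && (any(r < 0) || any(r > 1000)))
      stop_domain(nm, " must lie in [0, 1000] per 1000 reports")
  }
  if (cfg$comparator_fraction < 0 || cfg$comparator_fraction >= 1)
    stop_domain("comparator_fraction must lie in [0, 1)")
  if (cfg$max_terms_db2 < 1L || cfg$max_terms_db2 > 5L)
    stop_domain("max_terms_db2 must lie in 1..5")
  bad <- setdiff(unlist(lapply(cfg$covariate_effects, names)),
                 c("female", "minors", "seniors", "viral_vector",
                   "protein_subunit", "booster"))
  if (length(bad))
    stop_domain("unknown covariate effect name(s): ", paste(bad, collapse = ", "))
  invisible(cfg)
}

#' Default simulation configuration
#'
#' Reproduces the study conditions of the packaged reference tables:
#' covariate marginals equal to the published PEI and VAERS category
#' shares (the `missing` share uses the full-database denominator,
#' category shares are conditional on non-missing, so the plain
#' count/total fractions are used directly); db1 term rates equal to the
#' published PEI ARRs and db2 COVID-arm rates to the published VAERS
#' ARRs; comparator-arm rates derived as the VAERS rate divided by the
#' published PRR where one was printed (terms without a printed PRR get
#' the COVID rate, i.e. no signal), so the synthetic screen carries the
#' published disproportionality pattern; and covariate effects at the
#' magnitudes of the published adjusted ORs for a set of headline terms.
#'
#' @param n_reports_db1,n_reports_db2 database sizes; default to the
#'   published totals (974,931 and 1,016,024). Pass smaller values for
#'   quick experiments.
#' @param seed default seed stored in the configuration.
#' @return a `sim_config`.
#' @export
default_sim_config <- function(n_reports_db1 = 974931L,
                               n_reports_db2 = 1016024L, seed = 1L) {
  ch <- reference_characteristics()
  marg <- function(db) {
    s <- ch[ch$database == db, ]
    total <- sum(s$n[s$variable == "year"])  # year has no missing share
    out <- lapply(split(s, s$variable), function(sv)
      setNames(sv$n / total, sv$category))
    # year carries no explicit missing share; others sum to the total
    out[c("sex", "age_group", "vaccine_type", "schedule", "year")]
  }
  counts <- reference_term_counts()
  rates1 <- setNames(counts$arr_pei, counts$term)
  rates2 <- setNames(counts$arr_vaers, counts$term)
  comp <- ifelse(is.na(counts$prr), rates2, rates2 / counts$prr)
  comp <- setNames(pmin(comp, 1000), counts$term)

  effects <- list(
    "taste disorder" = c(seniors = log(1.64), booster = log(2.19)),
    "ageusia" = c(minors = log(2.04), seniors = log(2.99), booster = log(3.00)),
    "oral herpes" = c(female = log(1.39), minors = log(1.95),
                      seniors = log(1.73), protein_subunit = log(2.96)),
    "paraesthesia oral" = c(female = log(2.71), viral_vector = log(1.54),
                            booster = log(3.16)),
    "hypoaesthesia oral" = c(female = log(2.04)),
    "swollen tongue" = c(female = log(2.08), seniors = log(2.87),
                         viral_vector = log(0.72)))

  sim_config(n_reports_db1, n_reports_db2,
             covariate_marginals = list(db1 = marg("pei"), db2 = marg("vaers")),
             term_rates = rates1, term_rates_db2 = rates2,
             covariate_effects = effects,
             comparator_fraction = 0.3,
             comparator_term_rates = comp,
             seed = seed)
}

#' Generate a synthetic ICSR database
#'
#' Draws covariates independently from the configured marginals, then, for
#' each oral term, includes the term with probability
#' `logistic(logit(rate/1000) + covariate offsets)` in the COVID-19 arm
#' and with the flat comparator rate in the comparator arm (db2 only).
#' db1 keeps one term per record: the first included oral term in
#' configuration order, else a generic non-oral filler, so every record
#' has exactly one term. db2 keeps up to `max_terms_db2` terms, with one
#' filler appended after the oral terms. Deterministic given
#' `(cfg, which, seed)`.
#'
#' @param cfg a [sim_config()].
#' @param which `"db1"` (single-term) or `"db2"` (multi-term with
#'   comparator arm).
#' @param seed integer seed (default `cfg$seed`).
#' @return an [icsr_collection].
#' @export
generate_database <- function(cfg, which = c("db1", "db2"), seed = cfg$seed) {
  which <- match.arg(which)
  validate_sim_config(cfg)
  n <- if (which == "db1") cfg$n_reports_db1 else cfg$n_reports_db2
  marg <- cfg$covariate_marginals[[which]]
  rates <- if (which == "db1") cfg$term_rates else cfg$term_rates_db2
  eff_seed <- (as.integer(seed) + if (which == "db2") 1000003L else 0L) %%
    .Machine$integer.max

  with_local_seed(eff_seed, {
    draw <- function(p) sample(names(p), n, replace = TRUE, prob = p)
    sex <- draw(marg$sex)
    age_group <- draw(marg$age_group)
    vaccine_type <- draw(marg$vaccine_type)
    schedule <- draw(marg$schedule)
    year_chr <- draw(marg$year)
    year <- suppressWarnings(as.integer(year_chr))
    vaccine_class <- rep("covid19", n)
    if (which == "db2" && cfg$comparator_fraction > 0)
      vaccine_class[runif(n) < cfg$comparator_fraction] <- "comparator"
    comp <- vaccine_class == "comparator"
    age3 <- age3_of(age_group)

    terms <- names(rates)
    incl <- vector("list", length(terms))
    for (j in seq_along(terms)) {
      base <- rates[[j]] / 1000
      e <- cfg$covariate_effects[[terms[j]]]
      if (is.null(e) || base %in% c(0, 1)) {
        p <- rep(base, n)
      } else {
        off <- function(nm) { v <- e[nm]; if (is.na(v)) 0 else unname(v) }
        eta <- qlogis(base) +
          (sex == "female") * off("female") +
          (age3 == "minors") * off("minors") +
          (age3 == "seniors") * off("seniors") +
          (vaccine_type == "viral_vector") * off("viral_vector") +
          (vaccine_type == "protein_subunit") * off("protein_subunit") +
          (schedule == "booster") * off("booster")
        p <- plogis(eta)
      }
      if (any(comp)) p[comp] <- (cfg$comparator_term_rates[terms[j]] %||% 0) / 1000
      incl[[j]] <- which(runif(n) < p)
    }
    fillers <- sample(FILLER_TERMS, n, replace = TRUE)

    tm <- matrix(NA_character_, n, 5L,
                 dimnames = list(NULL, TERM_COLS))
    if (which == "db1") {
      assigned <- rep(NA_character_, n)
      for (j in seq_along(terms)) {
        idx <- incl[[j]]
        idx <- idx[is.na(assigned[idx])]
        assigned[idx] <- terms[j]
      }
      tm[, 1L] <- ifelse(is.na(assigned), fillers, assigned)
    } else {
      rec <- unlist(incl, use.names = FALSE)
      term_of <- rep(terms, lengths(incl))
      if (length(rec)) {
        ord <- order(rec, method = "radix")  # stable: keeps term order per record
        rec <- rec[ord]; term_of <- term_of[ord]
        lists <- split(term_of, rec)
        recs <- as.integer(names(lists))
        for (i in seq_along(recs)) {
          tl <- head(c(lists[[i]], fillers[recs[i]]), cfg$max_terms_db2)
          tm[recs[i], seq_along(tl)] <- tl
        }
      }
      empty <- is.na(tm[, 1L])
      tm[empty, 1L] <- fillers[empty]
    }

    df <- data.frame(report_id = sprintf("%s-%08d", which, seq_len(n)),
                     sex = sex, age_group = age_group,
                     vaccine_type = vaccine_type, schedule = schedule,
                     year = year, vaccine_class = vaccine_class,
                     stringsAsFactors = FALSE)
    df[TERM_COLS] <- as.data.frame(tm, stringsAsFactors = FALSE)
    icsr_collection(df, if (which == "db1") "single_term" else "multi_term")
  })
}

#' Write / read a simulation configuration as YAML
#'
#' @param cfg a [sim_config()].
#' @param path YAML file path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns a validated `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  obj <- unclass(cfg)
  for (nm in c("term_rates", "term_rates_db2", "comparator_term_rates"))
    obj[[nm]] <- as.list(obj[[nm]])
  obj$covariate_effects <- lapply(obj$covariate_effects, as.list)
  obj$covariate_marginals <- lapply(obj$covariate_marginals,
                                    function(m) lapply(m, as.list))
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  obj <- yaml::read_yaml(path)
  relist <- function(x) unlist(x)
  sim_config(obj$n_reports_db1, obj$n_reports_db2,
             covariate_marginals = lapply(obj$covariate_marginals,
                                          function(m) lapply(m, relist)),
             term_rates = relist(obj$term_rates),
             term_rates_db2 = relist(obj$term_rates_db2),
             covariate_effects = lapply(obj$covariate_effects, relist),
             comparator_fraction = obj$comparator_fraction,
             comparator_term_rates = relist(obj$comparator_term_rates),
             max_terms_db2 = obj$max_terms_db2, seed = obj$seed)
}
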
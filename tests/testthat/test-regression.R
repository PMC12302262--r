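test_that("the design matrix dummy-codes against the stated references", {
  df <- data.frame(report_id = c("r1", "r2", "r3"),
                   sex = c("female", "male", "male"),
                   age_group = c("over59", "18to59", "18to59"),
                   vaccine_type = c("viral_vector", "mrna", "mrna"),
                   schedule = c("booster", "primer", "primer"),
                   year = 2021L,
                   term = c("ageusia", "ageusia", "other"))
  d <- build_design(icsr_collection(df, "single_term"), "ageusia")
  expect_equal(d$n_used, 3L)
  # (female, senior, vector, booster) -> indicators 1,0,1,1,0,1 over the
  # female/minors/seniors/vector/protein/booster contrasts (minors,
  # protein, inactivated suppressed here for zero cases)
  expect_setequal(d$suppressed, c("minors", "protein_subunit", "inactivated"))
  expect_equal(unname(d$x[1, ]), c(1, 1, 1, 1))
  expect_equal(colnames(d$x), c("female", "seniors", "viral_vector", "booster"))
})

test_that("records with missing predictors or comparator class are dropped", {
  df <- data.frame(report_id = sprintf("r%d", 1:4),
                   sex = c("female", "missing", "female", "female"),
                   age_group = c("18to59", "18to59", "missing", "18to59"),
                   vaccine_type = "mrna", schedule = "primer", year = 2021L,
                   vaccine_class = c("covid19", "covid19", "covid19", "comparator"),
                   term1 = c("ageusia", "ageusia", "other", "other"))
  d <- build_design(icsr_collection(df, "multi_term"), "ageusia")
  expect_equal(d$n_used, 1L)
})

test_that("levels without cases are suppressed and printed as unavailable", {
  df <- data.frame(report_id = sprintf("r%02d", 1:30),
                   sex = rep(c("female", "male"), 15),
                   age_group = c(rep("7to17", 6), rep("18to59", 24)),
                   vaccine_type = "mrna", schedule = "primer", year = 2021L,
                   term = c(rep("other", 6),                      # no minor cases
                            rep(c("ageusia", "other"), 12)))
  d <- build_design(icsr_collection(df, "single_term"), "ageusia")
  expect_true("minors" %in% d$suppressed)
  fit <- fit_logistic(d)
  expect_false("minors" %in% fit$aor$level)
  tab <- aor_table(list(fit))
  expect_false(tab$available[tab$contrast == "minors"])
})

test_that("a single-predictor fit equals the closed-form 2x2 odds ratio", {
  counts <- c(f_case = 30L, f_non = 970L, m_case = 10L, m_non = 990L)
  df <- data.frame(report_id = sprintf("r%04d", 1:2000),
                   sex = rep(c("female", "male"), times = c(1000, 1000)),
                   age_group = "18to59", vaccine_type = "mrna",
                   schedule = "primer", year = 2021L,
                   term = c(rep("ageusia", 30), rep("other", 970),
                            rep("ageusia", 10), rep("other", 990)))
  fit <- fit_term_logistic(icsr_collection(df, "single_term"), "ageusia")
  closed_form <- (30 * 990) / (970 * 10)
  aor <- fit$aor$point[fit$aor$level == "female"]
  expect_equal(aor, closed_form, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("an independent predictor on a balanced design gives aOR 1", {
  df <- data.frame(report_id = sprintf("r%04d", 1:200),
                   sex = rep(c("female", "male"), each = 100),
                   age_group = "18to59", vaccine_type = "mrna",
                   schedule = "primer", year = 2021L,
                   term = rep(c(rep("ageusia", 20), rep("other", 80)), 2))
  fit <- fit_term_logistic(icsr_collection(df, "single_term"), "ageusia")
  expect_equal(fit$aor$point[fit$aor$level == "female"], 1, tolerance = 1e-6)
})

test_that("the fitted model never loses to the null (likelihood sanity)", {
  cfg <- mini_sim_config(rate = 10, n = 20000,
                         effects = list("test term" = c(female = log(1.5))))
  db1 <- generate_database(cfg, "db1", seed = 37)
  fit <- fit_term_logistic(db1, "test term")
  expect_lte(fit$fit$deviance, fit$fit$null.deviance + 1e-8)
  expect_equal(fit$n_used,
               sum(db1$sex != "missing" & db1$age_group != "missing" &
                     db1$vaccine_type != "missing" & db1$schedule != "missing"))
})

test_that("null data keep the female interval around one", {
  cfg <- mini_sim_config(rate = 5, n = 50000)
  db1 <- generate_database(cfg, "db1", seed = 41)
  fit <- fit_term_logistic(db1, "test term")
  f <- fit$aor[fit$aor$level == "female", ]
  expect_lt(f$ci_low, 1)
  expect_gt(f$ci_high, 1)
})

test_that("degenerate outcomes are refused", {
  df <- data.frame(report_id = c("r1", "r2"), sex = c("female", "male"),
                   age_group = "18to59", vaccine_type = "mrna",
                   schedule = "primer", year = 2021L, term = "other")
  d <- build_design(icsr_collection(df, "single_term"), "ageusia")
  expect_error(fit_logistic(d), "zero cases")
})

test_that("the aOR report flags significance by interval position", {
  fake <- structure(list(term = "t",
    coefficients = data.frame(level = c("female", "seniors"),
                              estimate = log(c(1.64, 1.0)), se = c(0.1, 0.1)),
    aor = data.frame(level = c("female", "seniors"),
                     point = c(1.64, 1.0), ci_low = c(1.31, 0.81),
                     ci_high = c(2.05, 1.22), available = TRUE),
    n_used = 100L, converged = TRUE, suppressed = character()),
    class = "ae_logit")
  tab <- aor_table(list(fake))
  expect_true(tab$significant[tab$contrast == "female"])
  expect_false(tab$significant[tab$contrast == "seniors"])
  empty <- aor_table(list())
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("term", "contrast", "aor") %in% names(empty)))
})
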